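test_that("embeddings equal the pooled vectors and ignore batch size", {
  tab <- small_table(seed = 71, n = 60)
  idx <- build_neighborhood_index(tab, neighborhood_config(box_width = 120))
  m <- tiny_model()
  emb <- compute_embeddings(m, tab, idx, batch_size = 13L)
  emb2 <- compute_embeddings(m, tab, idx, batch_size = 60L)
  expect_equal(emb[, ], emb2[, ], tolerance = 1e-12)
  one <- encode_and_pool(m, batch_neighborhoods(idx, 17L, tab), tab)
  expect_equal(emb[17, ], one[1, ], tolerance = 1e-12)
})

test_that("cells with identical neighbor sets embed identically", {
  tab <- small_table(seed = 72, n = 40)
  idx <- build_neighborhood_index(tab, neighborhood_config(box_width = 120))
  # hand-build an index where refs 1 and 2 share one neighbor multiset:
  # positions never enter the model, only the neighbor identities do
  idx$neighbors[[1]] <- idx$neighbors[[2]] <- sort(c(5L, 9L, 12L))
  m <- tiny_model()
  emb <- encode_and_pool(m, batch_neighborhoods(idx, 1:2, tab), tab)
  expect_identical(emb[1, ], emb[2, ])
})

test_that("Gaussian smoothing is an identity at sigma 0 and fixes constants", {
  tab <- small_table(seed = 73, n = 50)
  emb <- matrix(rnorm(50 * 4), 50, 4)
  expect_identical(smooth_embeddings(emb, tab, sigma = 0), emb)
  const <- matrix(rep(c(1, 2, 3, 4), each = 50), 50, 4)
  expect_equal(smooth_embeddings(const, tab, sigma = 12.01)[, ], const,
               tolerance = 1e-12)
  expect_error(smooth_embeddings(emb, tab, sigma = -1), "non-negative")
})

test_that("truncated smoothing matches the dense kernel average", {
  set.seed(74)
  n <- 50
  tab <- cell_table(
    data.frame(cell_id = sprintf("c%02d", 1:n),
               x = runif(n, 0, 100), y = runif(n, 0, 100),
               section_id = rep(c("s1", "s2"), each = n / 2), cell_type = 1L),
    matrix(0L, n, 1))
  emb <- matrix(rnorm(n * 3), n, 3)
  sig <- 30 # 5 sigma covers the whole section
  sm <- smooth_embeddings(emb, tab, sigma = sig, truncation = 5)
  # dense oracle: full kernel matrix, no truncation
  W <- exp(-as.matrix(dist(tab$obs[, c("x", "y")]))^2 / (2 * sig^2))
  same_sec <- outer(tab$obs$section_id, tab$obs$section_id, "==")
  W[!same_sec] <- 0
  oracle <- (W %*% emb) / rowSums(W)
  expect_lt(max(abs(sm - oracle)), 1e-8)

  # convex combination: each column bounded by the input column range
  expect_true(all(t(sm) <= apply(emb, 2, max) + 1e-12) &&
                all(t(sm) >= apply(emb, 2, min) - 1e-12))
})

test_that("k-means hits its closed-form extremes", {
  set.seed(75)
  X <- matrix(rnorm(40 * 3), 40, 3)
  one <- cluster_domains(X, 1, seed = 1)
  expect_true(all(one$labels == 0L))
  expect_equal(one$inertia, sum(scale(X, scale = FALSE)^2), tolerance = 1e-8)
  all_k <- cluster_domains(X, 40, seed = 1)
  expect_equal(all_k$inertia, 0, tolerance = 1e-10)
  expect_error(cluster_domains(X, 41, seed = 1), "exceeds")
})

test_that("k-means separates well-separated blobs and rivals stats::kmeans", {
  set.seed(76)
  truth <- rep(1:2, each = 60)
  X <- matrix(rnorm(120 * 2, sd = 0.3), 120, 2) + 5 * (truth - 1)
  dl <- cluster_domains(X, 2, seed = 2)
  expect_equal(clustering_agreement(dl$labels, truth)$ari, 1)

  km <- stats::kmeans(X, 2, nstart = 10)
  expect_lte(dl$inertia, km$tot.withinss * 1.01)

  # minibatch mode still recovers the blobs
  mb <- cluster_domains(X, 2, seed = 2, minibatch_size = 32, max_iter = 60)
  expect_equal(clustering_agreement(mb$labels, truth)$ari, 1)
})

test_that("Amari dissimilarity has its identities and matches Eq-style direct evaluation", {
  set.seed(77)
  D <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(amari_dissimilarity(D, D), 0, tolerance = 1e-12)
  Dp <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(amari_dissimilarity(D, Dp), amari_dissimilarity(Dp, D))

  # hand-built K = 2 with direct formula
  A <- rbind(c(1, 2, 3, 4), c(4, 1, 2, 2))
  B <- rbind(c(2, 4, 6, 8.5), c(1, -1, 2, 0))
  C <- cor(t(A), t(B))
  direct <- (2 * 2 - sum(apply(C, 1, max)) - sum(apply(C, 2, max))) / (2 * 2)
  expect_equal(amari_dissimilarity(A, B), direct, tolerance = 1e-12)

  # bounded in [0, 2] over random pairs
  for (r in 1:20) {
    d1 <- matrix(rnorm(3 * 5), 3); d2 <- matrix(rnorm(3 * 5), 3)
    v <- amari_dissimilarity(d1, d2)
    expect_gte(v, 0); expect_lte(v, 2)
  }

  expect_error(amari_dissimilarity(rbind(c(1, 1, 1, 1), c(1, 2, 3, 4)), B),
               "constant")
  expect_error(amari_dissimilarity(D, Dp[1:3, ]), "equal dimensions")
})

test_that("stability scan reports zero instability when replicates coincide", {
  set.seed(78)
  truth <- rep(1:2, each = 40)
  X <- matrix(rnorm(80 * 4, sd = 0.05), 80, 4) + 3 * (truth - 1)
  scan <- stability_scan(X, k_grid = c(2L, 3L, 4L, 5L), replicates = 4, seed = 3)
  expect_equal(scan$mean_diss[1], 0, tolerance = 1e-10)
  expect_true(all(diff(scan$mean_inertia) < 0))
  expect_error(stability_scan(X, 2:5, replicates = 1), "at least 2")
  expect_error(stability_scan(X, c(3L, 2L), replicates = 2), "increasing")
})

test_that("select_k finds the constructed inflection and warns without one", {
  kg <- 1:8
  f <- -(kg - 4.5)^3 # second derivative changes sign between nodes 4 and 5
  res <- structure(list(k_grid = kg, mean_inertia = f, mean_diss = f),
                   class = "stability_result")
  expect_equal(select_k(res), 5L)

  convex <- structure(list(k_grid = kg, mean_inertia = exp(-kg),
                           mean_diss = exp(-kg)),
                      class = "stability_result")
  expect_warning(k <- select_k(convex), "no second-derivative sign change")
  expect_true(is.na(k))
  expect_error(select_k(structure(list(k_grid = 1:3, mean_inertia = 1:3,
                                       mean_diss = 1:3),
                                  class = "stability_result")),
               "at least 4")
})

test_that("composition embeddings are row-stochastic neighbor summaries", {
  tab <- small_table(seed = 79, n = 80, types = 4)
  idx <- build_neighborhood_index(tab, neighborhood_config(box_width = 120))
  emb <- composition_embedding(tab, idx)
  expect_equal(rowSums(emb), rep(1, 80), tolerance = 1e-12)
  i <- which(tab$obs$cell_type[idx$neighbors[[5]]] == 2)
  expect_gt(idx$degree[5], 0)
  expect_equal(unname(emb[5, 2]), length(i) / idx$degree[5])
})
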