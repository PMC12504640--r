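test_that("spatial homogeneity matches brute force and its degenerate bounds", {
  set.seed(81)
  n <- 300
  tab <- cell_table(
    data.frame(cell_id = sprintf("c%03d", 1:n),
               x = runif(n, 0, 300), y = runif(n, 0, 300),
               section_id = rep(c("s1", "s2"), each = n / 2),
               cell_type = sample(1:3, n, TRUE)),
    matrix(0L, n, 2))
  lab <- sample(0:3, n, TRUE)
  res <- spatial_homogeneity(tab, lab, n_neighbors = 10)
  expect_equal(res$per_cell, brute_force_homogeneity(tab, lab, 10))
  expect_equal(res$dataset_mean, mean(res$per_cell))

  expect_true(all(spatial_homogeneity(tab, rep(0L, n), 10)$per_cell == 1))
  expect_true(all(spatial_homogeneity(tab, seq_len(n), 10)$per_cell == 0))
  expect_error(spatial_homogeneity(tab, lab[-1]), "misaligned")
})

test_that("per-domain means average the right cells and sections clamp", {
  tab <- cell_table(
    data.frame(cell_id = letters[1:6], x = c(0, 1, 2, 50, 51, 52), y = 0,
               section_id = "s1", cell_type = 1L),
    matrix(0L, 6, 1))
  lab <- c(0L, 0L, 1L, 1L, 1L, 1L)
  expect_message(res <- spatial_homogeneity(tab, lab, n_neighbors = 100),
                 "clamped")
  expect_named(res$per_domain_mean, c("0", "1"))
  expect_equal(res$per_domain_mean[["0"]], mean(res$per_cell[1:2]))
})

test_that("discreteness thresholds against the reference distribution", {
  ref <- seq(0.1, 1.0, by = 0.1)
  # identical parcellations: 20% of the reference sits below its own cutoff
  self <- discreteness(ref, ref, percentile = 20)
  expect_equal(self$proportion_discrete, 0.8)

  toy <- discreteness(c(0.15, 0.5, 0.9), ref, percentile = 20)
  expect_equal(unname(toy$discrete),
               c(0.15, 0.5, 0.9) >= quantile(ref, 0.2, names = FALSE))
  expect_equal(toy$proportion_discrete, 2 / 3)

  # percentile 0: threshold is the reference minimum
  allabove <- discreteness(c(0.2, 0.3), ref, percentile = 0)
  expect_equal(allabove$proportion_discrete, 1)
  expect_error(discreteness(numeric(0), ref), "non-empty")
})

test_that("composition matrices tally type fractions per domain", {
  tab <- cell_table(
    data.frame(cell_id = sprintf("c%02d", 1:20), x = runif(20), y = runif(20),
               section_id = "s1",
               cell_type = c(rep(1L, 6), rep(2L, 6), rep(3L, 8))),
    matrix(0L, 20, 1), type_levels = c("A", "B", "C"))
  lab <- c(rep(0L, 10), rep(1L, 10))
  M <- composition_matrix(lab, tab)
  expect_equal(M["0", ], c(A = 0.6, B = 0.4, C = 0))
  expect_equal(M["1", ], c(A = 0, B = 0.2, C = 0.8))
  expect_equal(rowSums(M), c("0" = 1, "1" = 1))

  sub <- tab[tab$obs$cell_type != 3]
  half <- composition_matrix(rep(0L, nrow(sub$obs)), sub)
  expect_equal(unname(half[1, ]), c(0.5, 0.5, 0))
})

test_that("composition matching: self-match, dominance, exhaustive oracle", {
  set.seed(82)
  A <- matrix(rgamma(5 * 7, 1), 5); A <- A / rowSums(A)
  B <- matrix(rgamma(5 * 7, 1), 5); B <- B / rowSums(B)
  rownames(A) <- paste0("a", 1:5); rownames(B) <- paste0("b", 1:5)

  self <- match_compositions(A, A, mode = "assignment")
  expect_equal(self$mean_r, 1, tolerance = 1e-12)
  expect_identical(self$matches$domain_b, rownames(A))
  expect_equal(match_compositions(A, A, mode = "max")$mean_r, 1)

  mx <- match_compositions(A, B, mode = "max")
  as <- match_compositions(A, B, mode = "assignment")
  expect_gte(mx$mean_r, as$mean_r)

  # exhaustive permutation oracle for the exclusive pairing
  R <- cor(t(A), t(B))
  P <- perms(5)
  best <- max(apply(P, 1, function(p) mean(R[cbind(1:5, p)])))
  expect_equal(as$mean_r, best, tolerance = 1e-12)

  # relabeling invariance: permuting rows of both inputs together
  p <- sample(5)
  expect_equal(match_compositions(A[p, ], B, mode = "assignment")$mean_r,
               as$mean_r, tolerance = 1e-12)

  Ac <- A; Ac[2, ] <- 1 / 7
  expect_error(match_compositions(Ac, B), "constant composition")
})

test_that("rectangular assignment pairs the smaller set", {
  set.seed(83)
  A <- matrix(rgamma(6 * 5, 1), 6); A <- A / rowSums(A)
  B <- matrix(rgamma(4 * 5, 1), 4); B <- B / rowSums(B)
  expect_message(res <- match_compositions(A, B, mode = "assignment"),
                 "rectangular")
  expect_equal(nrow(res$matches), 4)
  expect_false(any(duplicated(res$matches$domain_a)))
})

test_that("NMI and ARI agree with hand-computed contingency values", {
  a <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  b <- c(1, 1, 2, 2, 2, 3, 3, 3, 1)
  res <- clustering_agreement(a, b)
  expect_equal(res$nmi, oracle_nmi(a, b), tolerance = 1e-10)
  expect_equal(res$ari, oracle_ari(a, b), tolerance = 1e-10)

  same <- clustering_agreement(a, a)
  expect_equal(same$nmi, 1); expect_equal(same$ari, 1)

  const <- clustering_agreement(rep(1, 9), b)
  expect_equal(const$nmi, 0)
  expect_error(clustering_agreement(a, b[-1]), "differ in length")
})

test_that("ARI of independent labelings is centered at zero", {
  set.seed(84)
  aris <- replicate(200, {
    clustering_agreement(sample(1:4, 60, TRUE), sample(1:4, 60, TRUE))$ari
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("coordinate probing recovers exact and planted linear maps", {
  tab <- small_table(seed = 85, n = 100)
  # embeddings whose first two columns ARE the coordinates
  emb <- cbind(tab$obs$x, tab$obs$y, matrix(rnorm(100 * 3), 100, 3))
  res <- linear_probe(emb, tab, target = "coordinates")
  expect_lt(res$median_abs_error, 1e-8)

  # planted linear map + noise vs normal-equations oracle
  set.seed(85)
  E <- matrix(rnorm(200 * 8), 200, 8)
  beta <- matrix(rnorm(9 * 2), 9, 2)
  Y <- cbind(1, E) %*% beta + matrix(rnorm(400, sd = 0.01), 200, 2)
  tab2 <- cell_table(data.frame(cell_id = sprintf("c%03d", 1:200),
                                x = Y[, 1], y = Y[, 2], section_id = "s1",
                                cell_type = 1L),
                     matrix(0L, 200, 1))
  res2 <- linear_probe(E, tab2, target = "coordinates")
  X <- cbind(1, E)
  oracle <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(unname(res2$coefficients), unname(oracle), tolerance = 1e-6)
  expect_equal(unname(res2$coefficients), unname(beta), tolerance = 0.02)
})

test_that("donor probing is perfect on linearly separable animals", {
  set.seed(86)
  n <- 60
  donor <- rep(c("m1", "m2"), each = n / 2)
  emb <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  emb[donor == "m2", 1] <- emb[donor == "m2", 1] + 10
  tab <- cell_table(data.frame(cell_id = sprintf("c%02d", 1:n), x = 0, y = 0,
                               section_id = "s1", animal_id = donor,
                               cell_type = 1L),
                    matrix(0L, n, 1))
  res <- linear_probe(emb, tab, target = "donor")
  expect_equal(res$accuracy, 1)
  expect_equal(unname(res$per_donor_accuracy), c(1, 1))
})

test_that("spatial contribution reports zero delta for the baseline predictor", {
  tab <- small_table(seed = 87, n = 30)
  base <- colMeans(as.matrix(tab$counts))
  pred_base <- matrix(base, 30, length(base), byrow = TRUE)
  res <- spatial_contribution(tab, pred_base)
  expect_equal(res$delta_r, rep(0, nrow(res)), tolerance = 1e-12)

  perfect <- spatial_contribution(tab, as.matrix(tab$counts) + 0.0)
  expect_equal(perfect$r_model, rep(1, nrow(perfect)), tolerance = 1e-12)
  expect_equal(perfect$delta_r, 1 - perfect$r_baseline, tolerance = 1e-12)
})

test_that("spatial contribution averages within type as a hand tally", {
  counts <- rbind(c(5L, 1L, 0L), c(0L, 3L, 6L), c(2L, 2L, 5L), c(9L, 1L, 1L))
  pred <- rbind(c(4, 2, 1), c(1, 2, 7), c(1, 3, 4), c(8, 2, 0))
  tab <- cell_table(data.frame(cell_id = letters[1:4], x = 0, y = 0,
                               section_id = "s1",
                               cell_type = c(1L, 1L, 2L, 2L)),
                    counts, type_levels = c("T1", "T2"))
  res <- spatial_contribution(tab, pred)
  base <- colMeans(counts)
  hand_rm <- c(mean(c(cor(counts[1, ], pred[1, ]), cor(counts[2, ], pred[2, ]))),
               mean(c(cor(counts[3, ], pred[3, ]), cor(counts[4, ], pred[4, ]))))
  hand_rb <- c(mean(c(cor(counts[1, ], base), cor(counts[2, ], base))),
               mean(c(cor(counts[3, ], base), cor(counts[4, ], base))))
  expect_equal(res$r_model, hand_rm, tolerance = 1e-12)
  expect_equal(res$delta_r, hand_rm - hand_rb, tolerance = 1e-12)
})

test_that("marker ranking applies the log2 fold-change rule with pseudocount", {
  counts <- rbind(matrix(c(20L, 0L, 5L), 4, 3, byrow = TRUE),
                  matrix(c(0L, 8L, 5L), 4, 3, byrow = TRUE),
                  matrix(c(0L, 0L, 5L), 4, 3, byrow = TRUE))
  colnames(counts) <- c("gA", "gB", "gC")
  tab <- cell_table(data.frame(cell_id = sprintf("c%02d", 1:12), x = 0, y = 0,
                               section_id = "s1", cell_type = 1L),
                    counts)
  lab <- rep(0:2, each = 4)
  mk <- rank_domain_markers(tab, lab, min_log2fc = 1, pseudocount = 1)
  # hand computation: domain 0, gene gA: (20+1)/(0+1) -> log2 21
  expect_equal(mk[["0"]]$lfc[mk[["0"]]$gene == "gA"], log2(21))
  expect_equal(mk[["1"]]$gene, "gB")
  expect_equal(mk[["1"]]$lfc, log2(9 / 1))
  # uniform gene gC is never a marker
  expect_false("gC" %in% unlist(lapply(mk, `[[`, "gene")))
  # one-sided gene reported only for its domain
  expect_false("gA" %in% c(mk[["1"]]$gene, mk[["2"]]$gene))
  expect_error(rank_domain_markers(tab, rep(0L, 12)), "at least 2 domains")
})

test_that("cross-animal consistency counts presence with a cell threshold", {
  lab <- c(rep(0L, 30), rep(1L, 30), rep(2L, 30), rep(3L, 12))
  set.seed(88)
  animal <- sample(c("m1", "m2", "m3"), 102, TRUE)
  animal[lab == 3L] <- "m1" # domain 3 exclusive to one animal
  res <- cross_animal_consistency(lab, animal, min_cells = 3)
  expect_equal(dim(res$presence), c(4L, 3L))
  expect_equal(res$fraction_shared, 3 / 4)
  expect_equal(unname(res$presence["3", ]), c(TRUE, FALSE, FALSE))

  full <- cross_animal_consistency(lab[1:90], animal[1:90], min_cells = 1)
  expect_equal(full$fraction_shared, 1)
  expect_error(cross_animal_consistency(lab, rep("m1", 102)), "at least 2 animals")
})
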