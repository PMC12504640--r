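test_that("cell tokens concatenate expression and type channels", {
  m <- tiny_model()
  expr <- matrix(runif(3 * 7), 3, 7)
  expr[2, ] <- expr[1, ]
  tok <- encode_cell_tokens(m, expr, types = c(1L, 1L, 2L))
  expect_equal(dim(tok), c(3L, 8L))
  expect_identical(tok[1, ], tok[2, ]) # identical inputs, identical tokens

  tok2 <- encode_cell_tokens(m, expr[1, , drop = FALSE], types = 3L)
  de <- m$config$expr_token_dim
  expect_equal(tok2[1, 1:de], tok[1, 1:de], tolerance = 1e-12) # expression half unchanged
  expect_false(isTRUE(all.equal(tok2[1, -(1:de)], tok[1, -(1:de)])))

  expect_error(encode_cell_tokens(m, expr, types = c(1L, 9L, 2L)),
               "unknown cell type")
  expect_error(encode_cell_tokens(m, expr[, 1:5], types = c(1L, 1L, 2L)),
               "expects 7")
})

test_that("default architecture emits 384-dimensional tokens", {
  m <- nichescope_model(model_config(n_genes = 5, n_cell_types = 2,
                                     n_encoder_layers = 1, n_decoder_layers = 1),
                        seed = 1)
  tok <- encode_cell_tokens(m, matrix(0, 2, 5), c(1L, 2L))
  expect_equal(ncol(tok), 384L)
})

test_that("pooled neighborhood vectors ignore neighbor order and batch mates", {
  tab <- small_table(seed = 51, n = 70)
  idx <- build_neighborhood_index(tab, neighborhood_config(box_width = 170))
  m <- tiny_model()
  refs <- which(idx$degree >= 3)[1:4]
  batch <- batch_neighborhoods(idx, refs, tab)
  emb <- encode_and_pool(m, batch, tab)

  # permute the neighbor tokens inside neighborhood 1 (register stays first)
  permuted <- batch
  rows <- batch$groups[[1]]
  stopifnot(length(rows) >= 4)
  shuffled <- c(rows[1], rev(rows[-1]))
  permuted$flat_cells[rows] <- batch$flat_cells[shuffled]
  emb_p <- encode_and_pool(m, permuted, tab)
  expect_equal(emb_p, emb, tolerance = 1e-12)

  # batching invariance to machine precision: alone vs with others
  alone <- batch_neighborhoods(idx, refs[2], tab)
  expect_equal(encode_and_pool(m, alone, tab)[1, ], emb[2, ],
               tolerance = 1e-12)
})

test_that("zero-neighbor neighborhoods pool the register token alone", {
  tab <- cell_table(data.frame(cell_id = c("a", "b"), x = c(0, 1000), y = 0,
                               section_id = "s1", cell_type = c(1L, 2L)),
                    matrix(1L, 2, 7))
  idx <- build_neighborhood_index(tab, neighborhood_config(box_width = 85))
  expect_identical(idx$degree, c(0L, 0L))
  m <- tiny_model()
  emb <- encode_and_pool(m, batch_neighborhoods(idx, 1:2, tab), tab)
  expect_true(all(is.finite(emb)))
  # no cell input at all: both rows are the register-only representation
  expect_identical(emb[1, ], emb[2, ])
})

test_that("decoder emits valid type-conditioned ZINB parameters", {
  m <- tiny_model()
  z <- rnorm(8)
  p1 <- decode_masked_cell(m, z, ref_type = 1L)
  p2 <- decode_masked_cell(m, z, ref_type = 2L)
  expect_true(all(p1$mean > 0) && all(p1$dispersion > 0) && all(p1$scale > 0))
  expect_true(all(is.finite(p1$zero_inflation_logit)))
  expect_equal(rowSums(p1$mean), 1, tolerance = 1e-6)
  # type conditioning is live at random init
  expect_false(isTRUE(all.equal(p1$mu, p2$mu)))
  expect_error(decode_masked_cell(m, z, ref_type = 99L), "unknown reference")

  # batch invariance of the decoder path
  Z <- rbind(z, rnorm(8), rnorm(8))
  pb <- decode_masked_cell(m, Z, ref_type = c(1L, 2L, 3L))
  expect_equal(pb$mu[1, ], p1$mu[1, ], tolerance = 1e-12)
})

test_that("parameter count tracks the type-conditioning ablations", {
  base <- tiny_model(types = 5)
  no_dec <- tiny_model(types = 5, type_decoder = FALSE)
  no_type <- tiny_model(types = 5, type_encoder = FALSE, type_decoder = FALSE)
  d <- base$config$embed_dim; dt <- base$config$type_token_dim
  expect_equal(count_parameters(base) - count_parameters(no_dec), 4 * d)
  expect_equal(count_parameters(no_dec) - count_parameters(no_type), 4 * dt)
})

test_that("backpropagated gradients match finite differences", {
  tab <- small_table(seed = 52, n = 50)
  idx <- build_neighborhood_index(tab, neighborhood_config(box_width = 170))
  m <- tiny_model()
  batch <- batch_neighborhoods(idx, 1:10, tab)
  base <- nichescope:::model_loss_grads(m, batch, tab)
  expect_setequal(names(base$grads), names(m$params))

  set.seed(4)
  eps <- 1e-5
  for (chk in 1:40) {
    nm <- sample(names(base$grads), 1)
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    num <- (nichescope:::model_loss_grads(mp, batch, tab)$loss -
              nichescope:::model_loss_grads(mm, batch, tab)$loss) / (2 * eps)
    ana <- base$grads[[nm]][i]
    # denominator floor keeps finite-difference cancellation noise
    # (~1e-7 at this loss scale) from dominating near-zero gradients
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-4), 2e-3)
  }
})

test_that("neighborhood isolation: outside cells never affect loss or grads", {
  tab <- small_table(seed = 53, n = 60)
  idx <- build_neighborhood_index(tab, neighborhood_config(box_width = 120))
  m <- tiny_model()
  refs <- 1:8
  batch <- batch_neighborhoods(idx, refs, tab)
  inside <- unique(c(refs, unlist(idx$neighbors[refs])))
  outside <- setdiff(seq_len(nrow(tab$obs)), inside)[1]
  expect_false(is.na(outside)) # fixture leaves cells outside every neighborhood

  tab2 <- tab
  tab2$counts[outside, ] <- tab2$counts[outside, ] + 37
  a <- nichescope:::model_loss_grads(m, batch, tab)
  b <- nichescope:::model_loss_grads(m, batch, tab2)
  expect_identical(a$loss, b$loss)
  expect_identical(a$grads, b$grads)
})

test_that("checkpoints round-trip config and weights", {
  m <- tiny_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$params, m$params)
  expect_equal(unclass(back$config), unclass(m$config))
})
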