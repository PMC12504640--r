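#' Model architecture configuration
#'
#' The encoder-pool-decoder network. Each neighbor cell becomes a token by
#' concatenating a two-layer GELU perceptron of its log counts
#' (`expr_token_dim` dims) with a learned cell-type embedding
#' (`type_token_dim` dims). Tokens plus one learned register token per
#' neighborhood pass through `n_encoder_layers` pre-norm transformer
#' layers whose attention is restricted to the neighborhood, are collapsed
#' by learned-query attention pooling into one `embed_dim` vector, and a
#' two-token decoder (neighborhood vector + masked-cell type embedding)
#' emits zero-inflated negative binomial parameters for the reference
#' cell's counts. Defaults are the MERFISH-scale settings (384 dims, 4+4
#' layers, 8 heads, Q/K/V biases on, all other linear maps bias-free);
#' high-gene-count data benefits from `n_encoder_layers = 10`.
#'
#' @param n_genes number of genes g
#' @param n_cell_types number of cell-type codes C
#' @param embed_dim token/embedding dimension d (divisible by `n_heads`)
#' @param expr_token_dim,type_token_dim split of d between the expression
#'   and type halves of a cell token (must sum to d)
#' @param n_encoder_layers,n_decoder_layers transformer depth
#' @param n_heads attention heads
#' @param qkv_bias include bias terms in the query/key/value projections
#'   (stabilizes training)
#' @param mlp_ratio hidden width of transformer MLPs as a multiple of d
#' @param type_encoder,type_decoder ablation switches: `FALSE` replaces
#'   the respective cell-type embedding table with a single shared null
#'   embedding
#' @param zero_inflated model zero inflation; `FALSE` fixes `pi = 0`,
#'   giving a plain negative binomial likelihood
#' @return a `model_config` list
#' @export
model_config <- function(n_genes, n_cell_types, embed_dim = 384L,
                         expr_token_dim = embed_dim %/% 2L,
                         type_token_dim = embed_dim - expr_token_dim,
                         n_encoder_layers = 4L, n_decoder_layers = 4L,
                         n_heads = 8L, qkv_bias = TRUE, mlp_ratio = 4L,
                         type_encoder = TRUE, type_decoder = TRUE,
                         zero_inflated = TRUE) {
  if (expr_token_dim + type_token_dim != embed_dim) {
    stop2("expr_token_dim + type_token_dim must equal embed_dim")
  }
  if (embed_dim %% n_heads != 0) stop2("embed_dim must be divisible by n_heads")
  structure(list(n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 embed_dim = as.integer(embed_dim),
                 expr_token_dim = as.integer(expr_token_dim),
                 type_token_dim = as.integer(type_token_dim),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 n_heads = as.integer(n_heads), qkv_bias = qkv_bias,
                 mlp_ratio = as.integer(mlp_ratio),
                 type_encoder = type_encoder, type_decoder = type_decoder,
                 zero_inflated = zero_inflated),
            class = "model_config")
}

#' Initialize a neighborhood transformer
#'
#' Weights are drawn N(0, 0.02^2) (standard transformer init), layer-norm
#' gains start at 1, biases at 0.
#'
#' @param config a [model_config()]
#' @param seed integer seed for weight init
#' @return a `nichescope_model` (config + named parameter list)
#' @export
nichescope_model <- function(config, seed = 1L) {
  cfg <- config
  d <- cfg$embed_dim; g <- cfg$n_genes
  de <- cfg$expr_token_dim; dt <- cfg$type_token_dim
  hid <- d * cfg$mlp_ratio
  P <- with_seed(seed, {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    P <- list(
      expr_W1 = rn(g, de), expr_b1 = numeric(de),
      expr_W2 = rn(de, de), expr_b2 = numeric(de),
      type_embed = rn(if (cfg$type_encoder) cfg$n_cell_types else 1L, dt),
      cls = rn(1, d),
      pool_ln_g = rep(1, d), pool_ln_b = numeric(d),
      pool_q = rn(1, d),
      pool_Wk = rn(d, d), pool_bk = numeric(d),
      pool_Wv = rn(d, d), pool_bv = numeric(d),
      pool_Wo = rn(d, d),
      dec_type_embed = rn(if (cfg$type_decoder) cfg$n_cell_types else 1L, d),
      out_ln_g = rep(1, d), out_ln_b = numeric(d),
      head_mean_W = rn(d, g), head_mean_b = numeric(g),
      head_disp_W = rn(d, g), head_disp_b = numeric(g),
      head_pi_W = rn(d, g), head_pi_b = rep(-2, g),
      head_scale_W = rn(d, 1), head_scale_b = 0)
    layer_params <- function(prefix) {
      p <- list(rn(d, d), numeric(d), rn(d, d), numeric(d), rn(d, d),
                numeric(d), rn(d, d), rep(1, d), numeric(d), rep(1, d),
                numeric(d), rn(d, hid), rn(hid, d))
      names(p) <- paste0(prefix, c("_Wq", "_bq", "_Wk", "_bk", "_Wv", "_bv",
                                   "_Wo", "_ln1_g", "_ln1_b", "_ln2_g",
                                   "_ln2_b", "_mlp_W1", "_mlp_W2"))
      p
    }
    for (l in seq_len(cfg$n_encoder_layers)) P <- c(P, layer_params(paste0("enc", l)))
    for (l in seq_len(cfg$n_decoder_layers)) P <- c(P, layer_params(paste0("dec", l)))
    P
  })
  structure(list(config = cfg, params = P), class = "nichescope_model")
}

#' @export
print.nichescope_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<nichescope_model> d=%d | %d enc + %d dec layers, %d heads | %d genes, %d types | %s parameters\n",
    cfg$embed_dim, cfg$n_encoder_layers, cfg$n_decoder_layers, cfg$n_heads,
    cfg$n_genes, cfg$n_cell_types, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a [nichescope_model()]
#' @return integer parameter count
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# parameter-output floors keeping dispersion/scale strictly positive
.theta_floor <- 1e-4
.scale_floor <- 1e-4
.prop_floor <- 1e-10

#' Tokenize cells
#'
#' Row i is the concatenation of the expression perceptron applied to the
#' cell's log counts and its cell-type embedding.
#'
#' @param model a [nichescope_model()]
#' @param expr N x g matrix of log-transformed counts
#' @param types integer cell-type codes in `1..C`
#' @return N x d token matrix
#' @export
encode_cell_tokens <- function(model, expr, types) {
  cfg <- model$config; P <- model$params
  expr <- as.matrix(expr)
  if (ncol(expr) != cfg$n_genes) {
    stop2("expression has ", ncol(expr), " genes; model expects ", cfg$n_genes)
  }
  types <- as.integer(types)
  if (any(types < 1 | types > cfg$n_cell_types)) {
    stop2("unknown cell type id(s): ",
          paste(unique(types[types < 1 | types > cfg$n_cell_types]), collapse = ", "))
  }
  h <- gelu_fwd(sweep(expr %*% P$expr_W1, 2, P$expr_b1, "+"))$out
  e <- sweep(h %*% P$expr_W2, 2, P$expr_b2, "+")
  trow <- if (cfg$type_encoder) types else rep(1L, length(types))
  cbind(e, P$type_embed[trow, , drop = FALSE])
}

# Full forward pass over a neighborhood batch. Returns the pooled
# neighborhood vectors, the ZINB heads, and (optionally) every cache
# needed for the backward pass.
model_forward <- function(model, batch, table, keep_cache = FALSE) {
  cfg <- model$config; P <- model$params
  d <- cfg$embed_dim; de <- cfg$expr_token_dim
  H <- cfg$n_heads
  b <- length(batch$refs)

  cell_rows <- which(!batch$is_register)
  cells <- batch$flat_cells[cell_rows]
  X <- matrix(0, batch$n_tokens, d)
  X[batch$is_register, ] <- matrix(P$cls, sum(batch$is_register), d, byrow = TRUE)
  tok_cache <- NULL
  types <- integer(0)
  if (length(cells) > 0) {
    logX <- log_counts(table, cells)
    types <- table$obs$cell_type[cells]
    h1 <- linear_fwd(logX, P$expr_W1, P$expr_b1)
    act <- gelu_fwd(h1$out)
    h2 <- linear_fwd(act$out, P$expr_W2, P$expr_b2)
    trow <- if (cfg$type_encoder) types else rep(1L, length(types))
    X[cell_rows, ] <- cbind(h2$out, P$type_embed[trow, , drop = FALSE])
    tok_cache <- list(h1 = h1, act = act, h2 = h2, trow = trow)
  }

  enc_caches <- vector("list", cfg$n_encoder_layers)
  for (l in seq_len(cfg$n_encoder_layers)) {
    st <- encoder_layer_fwd(X, batch$groups, P, paste0("enc", l), H)
    X <- st$out
    enc_caches[[l]] <- st$cache
  }
  pool <- pool_fwd(X, batch$groups, P, H)
  Z <- pool$out # B x d neighborhood representations

  dtrow <- if (cfg$type_decoder) batch$ref_types else rep(1L, b)
  D <- matrix(0, 2L * b, d)
  odd <- seq(1L, 2L * b, by = 2L); even <- odd + 1L
  D[odd, ] <- Z
  D[even, ] <- P$dec_type_embed[dtrow, , drop = FALSE]
  dgroups <- lapply(seq_len(b), function(i) c(odd[i], even[i]))
  dec_caches <- vector("list", cfg$n_decoder_layers)
  for (l in seq_len(cfg$n_decoder_layers)) {
    st <- encoder_layer_fwd(D, dgroups, P, paste0("dec", l), H)
    D <- st$out
    dec_caches[[l]] <- st$cache
  }
  oln <- layernorm_fwd(D[even, , drop = FALSE], P$out_ln_g, P$out_ln_b)
  hm <- oln$out # B x d masked-cell representations

  mean_head <- linear_fwd(hm, P$head_mean_W, P$head_mean_b)
  disp_head <- linear_fwd(hm, P$head_disp_W, P$head_disp_b)
  pi_head <- linear_fwd(hm, P$head_pi_W, P$head_pi_b)
  scale_head <- linear_fwd(hm, P$head_scale_W, P$head_scale_b)
  p <- softmax_rows(mean_head$out) + .prop_floor
  theta <- softplus(disp_head$out) + .theta_floor
  s <- as.vector(softplus(scale_head$out)) + .scale_floor
  z <- if (cfg$zero_inflated) pi_head$out else
    matrix(-Inf, b, cfg$n_genes)
  out <- list(
    embeddings = Z,
    params = list(mean = p, dispersion = theta, zero_inflation_logit = z,
                  scale = s, mu = p * s))
  if (keep_cache) {
    out$cache <- list(tok = tok_cache, enc = enc_caches, pool = pool,
                      dec = dec_caches, oln = oln, dgroups = dgroups,
                      odd = odd, even = even, dtrow = dtrow,
                      mean_head = mean_head, disp_head = disp_head,
                      pi_head = pi_head, scale_head = scale_head,
                      p = p, theta = theta, s = s,
                      cell_rows = cell_rows, cells = cells, types = types)
  }
  out
}

# Loss (mean per-cell mean-over-genes ZINB NLL) and parameter gradients
# for one batch. Returns list(loss, grads).
model_loss_grads <- function(model, batch, table) {
  cfg <- model$config; P <- model$params
  fwd <- model_forward(model, batch, table, keep_cache = TRUE)
  ch <- fwd$cache
  b <- length(batch$refs); g <- cfg$n_genes
  Y <- as.matrix(table$counts[batch$refs, , drop = FALSE])
  mu <- fwd$params$mu; th <- fwd$params$dispersion
  z <- fwd$params$zero_inflation_logit
  ll <- zinb_loglik_elementwise(Y, mu, th, z)
  loss <- mean(-rowMeans(ll))

  gr <- zinb_nll_grad(Y, mu, th, z)
  w <- 1 / (b * g) # loss = sum(elementwise NLL) * w
  dmu <- gr$dmu * w; dth <- gr$dtheta * w
  dz <- if (cfg$zero_inflated) gr$dz * w else NULL

  G <- new_grad_acc()
  p <- ch$p; s <- ch$s
  ds <- rowSums(dmu * p)
  dp <- dmu * s
  dlogits <- (p - .prop_floor) * (dp - rowSums(dp * (p - .prop_floor)))
  draw_disp <- dth * sigmoid(ch$disp_head$out)
  draw_scale <- matrix(ds * sigmoid(as.vector(ch$scale_head$out)), b, 1)

  bm <- linear_bwd(dlogits, ch$mean_head$cache)
  gadd(G, "head_mean_W", bm$dW); gadd(G, "head_mean_b", bm$db)
  bd <- linear_bwd(draw_disp, ch$disp_head$cache)
  gadd(G, "head_disp_W", bd$dW); gadd(G, "head_disp_b", bd$db)
  bs <- linear_bwd(draw_scale, ch$scale_head$cache)
  gadd(G, "head_scale_W", bs$dW); gadd(G, "head_scale_b", bs$db)
  dhm <- bm$dX + bd$dX + bs$dX
  if (cfg$zero_inflated) {
    bp <- linear_bwd(dz, ch$pi_head$cache)
    gadd(G, "head_pi_W", bp$dW); gadd(G, "head_pi_b", bp$db)
    dhm <- dhm + bp$dX
  }

  boln <- layernorm_bwd(dhm, ch$oln$cache)
  gadd(G, "out_ln_g", boln$dg); gadd(G, "out_ln_b", boln$db)
  dD <- matrix(0, 2L * b, cfg$embed_dim)
  dD[ch$even, ] <- boln$dX
  for (l in rev(seq_len(cfg$n_decoder_layers))) {
    dD <- encoder_layer_bwd(dD, ch$dec[[l]], paste0("dec", l), G)
  }
  dZ <- dD[ch$odd, , drop = FALSE]
  dTypeDec <- rowsum(dD[ch$even, , drop = FALSE], ch$dtrow)
  gDec <- matrix(0, nrow(P$dec_type_embed), cfg$embed_dim)
  gDec[as.integer(rownames(dTypeDec)), ] <- dTypeDec
  gadd(G, "dec_type_embed", gDec)

  dX <- pool_bwd(dZ, ch$pool$cache, G)
  for (l in rev(seq_len(cfg$n_encoder_layers))) {
    dX <- encoder_layer_bwd(dX, ch$enc[[l]], paste0("enc", l), G)
  }
  gadd(G, "cls", matrix(colSums(dX[batch$is_register, , drop = FALSE]), 1))
  if (length(ch$cells) > 0) {
    de <- cfg$expr_token_dim
    dTok <- dX[ch$cell_rows, , drop = FALSE]
    dE <- dTok[, seq_len(de), drop = FALSE]
    dTy <- dTok[, (de + 1L):cfg$embed_dim, drop = FALSE]
    dTyAgg <- rowsum(dTy, ch$tok$trow)
    gTy <- matrix(0, nrow(P$type_embed), cfg$type_token_dim)
    gTy[as.integer(rownames(dTyAgg)), ] <- dTyAgg
    gadd(G, "type_embed", gTy)
    b2 <- linear_bwd(dE, ch$tok$h2$cache)
    gadd(G, "expr_W2", b2$dW); gadd(G, "expr_b2", b2$db)
    dact <- gelu_bwd(b2$dX, ch$tok$act$cache)
    b1 <- linear_bwd(dact, ch$tok$h1$cache)
    gadd(G, "expr_W1", b1$dW); gadd(G, "expr_b1", b1$db)
  }
  list(loss = loss, grads = G$g)
}

#' Encode and pool neighborhoods into embedding vectors
#'
#' The neighborhood representation: neighbor cell tokens plus the register
#' token pass through the encoder stack (attention restricted to the
#' neighborhood; the reference cell's own token is never an input) and are
#' collapsed by attention pooling. Deterministic; independent of how
#' neighborhoods are batched together.
#'
#' @param model a [nichescope_model()]
#' @param batch a [batch_neighborhoods()] result
#' @param table the [cell_table()]
#' @return B x d matrix of pooled neighborhood vectors
#' @export
encode_and_pool <- function(model, batch, table) {
  model_forward(model, batch, table)$embeddings
}

#' Decode a masked reference cell from its neighborhood vector
#'
#' A two-token sequence (neighborhood vector, learned type-specific mask
#' token) passes through the decoder stack; linear heads emit the ZINB
#' parameters with positivity enforced by softplus and zero inflation by
#' a logistic transform.
#'
#' @param model a [nichescope_model()]
#' @param nbhd_vec numeric d-vector (or B x d matrix) of neighborhood
#'   representations
#' @param ref_type integer reference cell type(s) in `1..C`
#' @return list of ZINB parameters: `mean` (per-gene simplex), `dispersion`,
#'   `zero_inflation_logit`, `scale` (per cell), and `mu = scale * mean`
#' @export
decode_masked_cell <- function(model, nbhd_vec, ref_type) {
  cfg <- model$config; P <- model$params
  Z <- if (is.null(dim(nbhd_vec))) matrix(nbhd_vec, 1) else as.matrix(nbhd_vec)
  ref_type <- as.integer(ref_type)
  if (any(ref_type < 1 | ref_type > cfg$n_cell_types)) {
    stop2("unknown reference cell type")
  }
  b <- nrow(Z)
  dtrow <- if (cfg$type_decoder) ref_type else rep(1L, b)
  D <- matrix(0, 2L * b, cfg$embed_dim)
  odd <- seq(1L, 2L * b, by = 2L); even <- odd + 1L
  D[odd, ] <- Z
  D[even, ] <- P$dec_type_embed[dtrow, , drop = FALSE]
  dgroups <- lapply(seq_len(b), function(i) c(odd[i], even[i]))
  for (l in seq_len(cfg$n_decoder_layers)) {
    D <- encoder_layer_fwd(D, dgroups, P, paste0("dec", l), cfg$n_heads)$out
  }
  hm <- layernorm_fwd(D[even, , drop = FALSE], P$out_ln_g, P$out_ln_b)$out
  p <- softmax_rows(sweep(hm %*% P$head_mean_W, 2, P$head_mean_b, "+")) + .prop_floor
  theta <- softplus(sweep(hm %*% P$head_disp_W, 2, P$head_disp_b, "+")) + .theta_floor
  z <- if (cfg$zero_inflated) {
    sweep(hm %*% P$head_pi_W, 2, P$head_pi_b, "+")
  } else matrix(-Inf, b, cfg$n_genes)
  s <- as.vector(softplus(hm %*% P$head_scale_W + P$head_scale_b)) + .scale_floor
  list(mean = p, dispersion = theta, zero_inflation_logit = z, scale = s,
       mu = p * s)
}

#' Save / load a model checkpoint
#'
#' Checkpoints bundle the architecture config, the parameters, and any
#' training state into one versioned file (RDS).
#'
#' @param model a [nichescope_model()] (optionally carrying `$train_state`)
#' @param path file path
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = 1L, config = unclass(model$config),
               params = model$params,
               train_state = model$train_state %||% NULL),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version)) stop2("not a nichescope checkpoint: ", path)
  m <- structure(list(config = structure(ck$config, class = "model_config"),
                      params = ck$params),
                 class = "nichescope_model")
  m$train_state <- ck$train_state
  m
}
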