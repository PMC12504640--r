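# Transformer building blocks with explicit reverse-mode gradients.
# All forward functions return list(out, cache); the matching *_bwd takes
# the upstream gradient plus the cache and returns input/parameter grads.
# Tokens are stacked row-wise across neighborhoods; `groups` is a list of
# row-index vectors, one per neighborhood, so attention never crosses
# neighborhood boundaries (the block-diagonal attention contract).

# add / multiply a length-ncol vector into every row without aperm copies
row_add <- function(Y, b) Y + rep(b, rep.int(nrow(Y), length(b)))
row_mul <- function(Y, b) Y * rep(b, rep.int(nrow(Y), length(b)))

linear_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- row_add(Y, b)
  list(out = Y, cache = list(X = X, W = W, has_b = !is.null(b)))
}

linear_bwd <- function(dY, cache) {
  list(dX = dY %*% t(cache$W),
       dW = crossprod(cache$X, dY),
       db = if (cache$has_b) colSums(dY) else NULL)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- row_add(row_mul(xhat, g), b)
  list(out = Y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- row_mul(dY, cache$g)
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

gelu_fwd <- function(X) {
  Phi <- stats::pnorm(X)
  list(out = X * Phi, cache = list(X = X, Phi = Phi))
}

gelu_bwd <- function(dY, cache) {
  X <- cache$X
  dY * (cache$Phi + X * (0.3989422804014327 * exp(-0.5 * X * X)))
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# --- multi-head self-attention restricted to groups -------------------------

attn_core_fwd <- function(Q, K, V, groups, H) {
  d <- ncol(Q)
  dh <- d %/% H
  O <- matrix(0, nrow(Q), d)
  A_cache <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    Ah <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      A <- softmax_rows(tcrossprod(Qh, Kh) / sqrt(dh))
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      Ah[[h]] <- A
    }
    A_cache[[gi]] <- Ah
  }
  list(out = O, cache = list(A = A_cache, Q = Q, K = K, V = V,
                             groups = groups, H = H, dh = dh))
}

attn_core_bwd <- function(dO, cache) {
  Q <- cache$Q; K <- cache$K; V <- cache$V
  dh <- cache$dh; H <- cache$H
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- dQ; dV <- dQ
  for (gi in seq_along(cache$groups)) {
    rows <- cache$groups[[gi]]
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[gi]][[h]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOh, Vh)
      dV[rows, cols] <- dV[rows, cols] + crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dQ[rows, cols] + dS %*% K[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- dK[rows, cols] + crossprod(dS, Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

# --- one pre-norm transformer layer (attention block + MLP block) -----------
# Parameter names are looked up in P with the given prefix; Q/K/V carry
# biases, the output projection and MLP do not.

encoder_layer_fwd <- function(X, groups, P, prefix, H) {
  ln1 <- layernorm_fwd(X, P[[paste0(prefix, "_ln1_g")]], P[[paste0(prefix, "_ln1_b")]])
  q <- linear_fwd(ln1$out, P[[paste0(prefix, "_Wq")]], P[[paste0(prefix, "_bq")]])
  k <- linear_fwd(ln1$out, P[[paste0(prefix, "_Wk")]], P[[paste0(prefix, "_bk")]])
  v <- linear_fwd(ln1$out, P[[paste0(prefix, "_Wv")]], P[[paste0(prefix, "_bv")]])
  att <- attn_core_fwd(q$out, k$out, v$out, groups, H)
  proj <- linear_fwd(att$out, P[[paste0(prefix, "_Wo")]])
  X1 <- X + proj$out
  ln2 <- layernorm_fwd(X1, P[[paste0(prefix, "_ln2_g")]], P[[paste0(prefix, "_ln2_b")]])
  m1 <- linear_fwd(ln2$out, P[[paste0(prefix, "_mlp_W1")]])
  act <- gelu_fwd(m1$out)
  m2 <- linear_fwd(act$out, P[[paste0(prefix, "_mlp_W2")]])
  X2 <- X1 + m2$out
  list(out = X2,
       cache = list(ln1 = ln1, q = q, k = k, v = v, att = att, proj = proj,
                    ln2 = ln2, m1 = m1, act = act, m2 = m2))
}

encoder_layer_bwd <- function(dX2, cache, prefix, G) {
  b_m2 <- linear_bwd(dX2, cache$m2$cache)
  gadd(G, paste0(prefix, "_mlp_W2"), b_m2$dW)
  d_act <- gelu_bwd(b_m2$dX, cache$act$cache)
  b_m1 <- linear_bwd(d_act, cache$m1$cache)
  gadd(G, paste0(prefix, "_mlp_W1"), b_m1$dW)
  b_ln2 <- layernorm_bwd(b_m1$dX, cache$ln2$cache)
  gadd(G, paste0(prefix, "_ln2_g"), b_ln2$dg)
  gadd(G, paste0(prefix, "_ln2_b"), b_ln2$db)
  dX1 <- dX2 + b_ln2$dX
  b_proj <- linear_bwd(dX1, cache$proj$cache)
  gadd(G, paste0(prefix, "_Wo"), b_proj$dW)
  datt <- attn_core_bwd(b_proj$dX, cache$att$cache)
  b_q <- linear_bwd(datt$dQ, cache$q$cache)
  b_k <- linear_bwd(datt$dK, cache$k$cache)
  b_v <- linear_bwd(datt$dV, cache$v$cache)
  gadd(G, paste0(prefix, "_Wq"), b_q$dW); gadd(G, paste0(prefix, "_bq"), b_q$db)
  gadd(G, paste0(prefix, "_Wk"), b_k$dW); gadd(G, paste0(prefix, "_bk"), b_k$db)
  gadd(G, paste0(prefix, "_Wv"), b_v$dW); gadd(G, paste0(prefix, "_bv"), b_v$db)
  b_ln1 <- layernorm_bwd(b_q$dX + b_k$dX + b_v$dX, cache$ln1$cache)
  gadd(G, paste0(prefix, "_ln1_g"), b_ln1$dg)
  gadd(G, paste0(prefix, "_ln1_b"), b_ln1$db)
  dX1 + b_ln1$dX
}

# --- attention pooling: learned single query over each neighborhood ---------

pool_fwd <- function(X, groups, P, H) {
  ln <- layernorm_fwd(X, P$pool_ln_g, P$pool_ln_b)
  k <- linear_fwd(ln$out, P$pool_Wk, P$pool_bk)
  v <- linear_fwd(ln$out, P$pool_Wv, P$pool_bv)
  d <- ncol(X); dh <- d %/% H
  q <- as.vector(P$pool_q)
  Z <- matrix(0, length(groups), d)
  a_cache <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    ah <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      s <- as.vector(k$out[rows, cols, drop = FALSE] %*% q[cols]) / sqrt(dh)
      a <- exp(s - max(s)); a <- a / sum(a)
      Z[gi, cols] <- as.vector(crossprod(v$out[rows, cols, drop = FALSE], a))
      ah[[h]] <- a
    }
    a_cache[[gi]] <- ah
  }
  proj <- linear_fwd(Z, P$pool_Wo)
  list(out = proj$out,
       cache = list(ln = ln, k = k, v = v, proj = proj, a = a_cache,
                    groups = groups, H = H, dh = dh, q = q, Z = Z))
}

pool_bwd <- function(dZout, cache, G) {
  b_proj <- linear_bwd(dZout, cache$proj$cache)
  gadd(G, "pool_Wo", b_proj$dW)
  dZ <- b_proj$dX
  Km <- cache$k$out; Vm <- cache$v$out
  dK <- matrix(0, nrow(Km), ncol(Km)); dV <- dK
  dq <- numeric(ncol(Km))
  dh <- cache$dh; q <- cache$q
  for (gi in seq_along(cache$groups)) {
    rows <- cache$groups[[gi]]
    for (h in seq_len(cache$H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      a <- cache$a[[gi]][[h]]
      dz <- dZ[gi, cols]
      dV[rows, cols] <- dV[rows, cols] + outer(a, dz)
      da <- as.vector(Vm[rows, cols, drop = FALSE] %*% dz)
      ds <- a * (da - sum(da * a))
      dK[rows, cols] <- dK[rows, cols] + outer(ds, q[cols]) / sqrt(dh)
      dq[cols] <- dq[cols] +
        as.vector(crossprod(Km[rows, cols, drop = FALSE], ds)) / sqrt(dh)
    }
  }
  gadd(G, "pool_q", matrix(dq, 1))
  b_k <- linear_bwd(dK, cache$k$cache)
  b_v <- linear_bwd(dV, cache$v$cache)
  gadd(G, "pool_Wk", b_k$dW); gadd(G, "pool_bk", b_k$db)
  gadd(G, "pool_Wv", b_v$dW); gadd(G, "pool_bv", b_v$db)
  b_ln <- layernorm_bwd(b_k$dX + b_v$dX, cache$ln$cache)
  gadd(G, "pool_ln_g", b_ln$dg); gadd(G, "pool_ln_b", b_ln$db)
  b_ln$dX
}

# gradient accumulator: an environment holding a named list
new_grad_acc <- function() {
  G <- new.env(parent = emptyenv())
  G$g <- list()
  G
}

gadd <- function(G, name, value) {
  if (is.null(value)) return(invisible(NULL))
  cur <- G$g[[name]]
  G$g[[name]] <- if (is.null(cur)) value else cur + value
  invisible(NULL)
}
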