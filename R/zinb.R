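#' Zero-inflated negative binomial negative log-likelihood
#'
#' The count model used for masked-cell prediction. A gene's count is zero
#' either through the inflation component (probability
#' `pi = sigmoid(zero_inflation_logit)`) or through a negative binomial
#' with mean `mu = scale * mean` and inverse-dispersion `theta`:
#' \deqn{P(y=0) = \pi + (1-\pi)\,(\theta/(\theta+\mu))^{\theta}}
#' \deqn{P(y>0) = (1-\pi)\,\mathrm{NB}(y;\mu,\theta).}
#' With `zero_inflation_logit = -Inf` (`pi = 0`) this reduces exactly to
#' the plain negative binomial likelihood. The per-cell loss is the mean
#' NLL over genes. Computation is carried out in log space and is stable
#' at `y = 0` and for large `theta`.
#'
#' @param observed non-negative integer counts: a vector of length g or an
#'   N x g matrix
#' @param mean positive relative mean per gene (same shape as `observed`,
#'   or a vector recycled across cells); the absolute mean is
#'   `scale * mean`
#' @param dispersion positive NB inverse-dispersion `theta` per gene
#' @param zero_inflation_logit real logit of the zero-inflation weight;
#'   `-Inf` disables inflation (default)
#' @param scale positive per-cell scale factor (library size), default 1
#' @return numeric vector of per-cell mean NLL over genes (length N)
#' @export
zinb_nll <- function(observed, mean, dispersion, zero_inflation_logit = -Inf,
                     scale = 1) {
  if (is.null(dim(observed))) observed <- matrix(observed, nrow = 1)
  if (!is_count_vector(as.vector(observed))) {
    stop2("observed counts must be non-negative integers")
  }
  n <- nrow(observed); g <- ncol(observed)
  # broadcast to N x g; a bare vector of length g is a per-gene parameter,
  # length N (when N != g) a per-cell one -- pass matrices when ambiguous
  bc <- function(v) {
    if (is.null(dim(v))) {
      if (length(v) == g) matrix(v, n, g, byrow = TRUE)
      else if (length(v) == 1) matrix(v, n, g)
      else if (length(v) == n) matrix(v, n, g)
      else stop2("parameter of length ", length(v), " cannot be broadcast")
    } else v
  }
  mu <- bc(mean) * bc(scale)
  th <- bc(dispersion)
  z <- bc(zero_inflation_logit)
  if (any(mu <= 0) || any(th <= 0)) stop2("mean and dispersion must be positive")
  ll <- zinb_loglik_elementwise(observed, mu, th, z)
  rowMeans(-ll)
}

# elementwise ZINB log-likelihood (matrices of identical shape)
zinb_loglik_elementwise <- function(y, mu, th, z) {
  nb0 <- th * (log(th) - log(th + mu)) # NB log P(0)
  ll <- matrix(0, nrow(y), ncol(y))
  zero <- y == 0
  ll[zero] <- logaddexp(z[zero], nb0[zero]) - log1pexp(z[zero])
  if (any(!zero)) {
    i <- !zero
    ll[i] <- -log1pexp(z[i]) +
      lgamma(y[i] + th[i]) - lgamma(th[i]) - lgamma(y[i] + 1) +
      nb0[i] + y[i] * (log(mu[i]) - log(th[i] + mu[i]))
  }
  ll
}

# Gradients of the summed ZINB NLL wrt mu, theta and the zero logit.
# Returns matrices shaped like y; used by the training backward pass.
zinb_nll_grad <- function(y, mu, th, z) {
  zero <- y == 0
  sz <- sigmoid(z)
  nb0 <- th * (log(th) - log(th + mu))
  dmu <- matrix(0, nrow(y), ncol(y))
  dth <- matrix(0, nrow(y), ncol(y))
  dz <- matrix(0, nrow(y), ncol(y))
  # y > 0: d(-ll)
  i <- !zero
  if (any(i)) {
    dmu[i] <- -(y[i] / mu[i] - (y[i] + th[i]) / (th[i] + mu[i]))
    dth[i] <- -(digamma(y[i] + th[i]) - digamma(th[i]) + log(th[i]) + 1 -
                  log(th[i] + mu[i]) - (y[i] + th[i]) / (th[i] + mu[i]))
    dz[i] <- sz[i]
  }
  # y = 0: ll = logaddexp(z, nb0) - log1pexp(z)
  if (any(zero)) {
    m <- pmax(z[zero], nb0[zero])
    wa <- exp(z[zero] - m); wb <- exp(nb0[zero] - m)
    tot <- wa + wb
    w_nb <- wb / tot # posterior weight of the NB component
    w_z <- wa / tot
    dmu[zero] <- -(w_nb * (-th[zero] / (th[zero] + mu[zero])))
    dth[zero] <- -(w_nb * (log(th[zero]) + 1 - log(th[zero] + mu[zero]) -
                             th[zero] / (th[zero] + mu[zero])))
    dz[zero] <- -(w_z - sz[zero])
  }
  list(dmu = dmu, dtheta = dth, dz = dz)
}
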