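# Internal numerical helpers shared across modules.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

softplus <- function(x) log1pexp(x)

# inverse of softplus; ~ y for large y
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

sigmoid <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  dim(out) <- dim(x)
  out
}

# elementwise log(exp(a) + exp(b)); tolerates -Inf in either argument
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  m[m == -Inf] <- 0 # both -Inf
  m + log(exp(a - m) + exp(b - m))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library functions never perturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count_vector <- function(x) {
  all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
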