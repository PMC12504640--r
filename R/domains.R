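#' Compute per-cell neighborhood embeddings
#'
#' Applies the trained model to every cell as a reference and extracts the
#' pooled neighborhood representation (not the masked-cell token). Rows
#' align with the cell table; values are independent of `batch_size`.
#'
#' @param model a trained [nichescope_model()]
#' @param table a [cell_table()]
#' @param index the matching [build_neighborhood_index()]
#' @param batch_size forward-pass batch size
#' @return N x d numeric matrix with attribute `provenance`
#' @export
compute_embeddings <- function(model, table, index, batch_size = 512L) {
  n <- n_cells(table)
  if (index$n_cells != n) stop2("index and table disagree on cell count")
  d <- model$config$embed_dim
  emb <- matrix(NA_real_, n, d)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    batch <- batch_neighborhoods(index, chunk, table)
    emb[chunk, ] <- encode_and_pool(model, batch, table)
  }
  attr(emb, "provenance") <- list(smoothing_sigma = NULL,
                                  box_width = index$config$box_width)
  emb
}

#' Neighborhood cell-type composition embedding
#'
#' A model-free reference embedding: row i is the fraction of each cell
#' type among cell i's box neighbors (reference excluded; a cell with no
#' neighbors gets its own type as a one-hot row). Useful as a baseline
#' feature set and for stability scans that do not require training.
#'
#' @param table a [cell_table()]
#' @param index a [build_neighborhood_index()]
#' @return N x C row-stochastic matrix
#' @export
composition_embedding <- function(table, index) {
  C <- length(table$type_levels)
  types <- table$obs$cell_type
  n <- n_cells(table)
  emb <- matrix(0, n, C)
  for (i in seq_len(n)) {
    nb <- index$neighbors[[i]]
    if (length(nb) == 0) {
      emb[i, types[i]] <- 1
    } else {
      tb <- tabulate(types[nb], nbins = C)
      emb[i, ] <- tb / sum(tb)
    }
  }
  colnames(emb) <- table$type_levels
  emb
}

#' Gaussian smoothing of embeddings over the spatial point cloud
#'
#' Kernel regression over same-section cells: row i becomes the
#' kernel-weighted average of embeddings within `truncation * sigma`
#' microns (self included), weights `exp(-dist^2 / (2 sigma^2))`. The
#' default sigma of 12.01 microns corresponds to the operative filter
#' width used for MERFISH data. `sigma = 0` is the identity.
#'
#' @param emb N x d embedding matrix
#' @param table the matching [cell_table()]
#' @param sigma kernel width in microns (`>= 0`)
#' @param truncation kernel support radius in multiples of sigma
#' @return smoothed N x d matrix
#' @export
smooth_embeddings <- function(emb, table, sigma = 12.01, truncation = 3) {
  if (sigma < 0) stop2("sigma must be non-negative")
  if (nrow(emb) != n_cells(table)) stop2("embedding rows must match cells")
  if (sigma == 0) return(emb)
  out <- matrix(NA_real_, nrow(emb), ncol(emb))
  r <- truncation * sigma
  x <- table$obs$x; y <- table$obs$y
  for (sec in unique(table$obs$section_id)) {
    idx <- which(table$obs$section_id == sec)
    xs <- x[idx]; ys <- y[idx]
    E <- emb[idx, , drop = FALSE]
    # bin at radius r; contributors live in the 3x3 bin neighborhood
    bx <- floor(xs / r); by <- floor(ys / r)
    key <- paste(bx, by)
    bins <- split(seq_along(idx), key)
    for (ii in seq_along(idx)) {
      cand <- unlist(bins[as.vector(outer(bx[ii] + (-1:1), by[ii] + (-1:1),
                                          paste))], use.names = FALSE)
      d2 <- (xs[cand] - xs[ii])^2 + (ys[cand] - ys[ii])^2
      cand <- cand[d2 <= r^2]
      w <- exp(-((xs[cand] - xs[ii])^2 + (ys[cand] - ys[ii])^2) / (2 * sigma^2))
      out[idx[ii], ] <- as.vector(crossprod(E[cand, , drop = FALSE], w)) / sum(w)
    }
  }
  attr(out, "provenance") <- utils::modifyList(
    attr(emb, "provenance") %||% list(), list(smoothing_sigma = sigma))
  out
}

# squared Euclidean distances between rows of X (n x d) and rows of C (k x d)
dist2_to_centroids <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * tcrossprod(X, C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

# assignment step shared by full-batch and minibatch paths
assign_to_centroids <- function(X, C, chunk = 8192L) {
  n <- nrow(X)
  lab <- integer(n); d2 <- numeric(n)
  for (rows in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    D <- dist2_to_centroids(X[rows, , drop = FALSE], C)
    lab[rows] <- max.col(-D, ties.method = "first")
    d2[rows] <- D[cbind(seq_along(rows), lab[rows])]
  }
  list(labels = lab, dist2 = pmax(d2, 0))
}

# scalable k-means++ (k-means||) seeding with the given oversampling factor
kmeanspp_seed <- function(X, k, oversampling = 3, rounds = 5L) {
  n <- nrow(X)
  cand <- X[sample.int(n, 1L), , drop = FALSE]
  for (r in seq_len(rounds)) {
    d2 <- assign_to_centroids(X, cand)$dist2
    tot <- sum(d2)
    if (tot <= 0) break
    p <- pmin(1, oversampling * k * d2 / tot)
    new <- which(stats::runif(n) < p)
    if (length(new) > 0) cand <- rbind(cand, X[new, , drop = FALSE])
    if (nrow(cand) >= 5 * k) break
  }
  cand <- unique(cand)
  if (nrow(cand) < k) { # top up with random rows so k centers exist
    extra <- X[sample.int(n, min(n, k - nrow(cand))), , drop = FALSE]
    cand <- rbind(cand, extra)
  }
  # weight candidates by how many points they attract, then standard
  # k-means++ on the weighted candidate set
  w <- tabulate(assign_to_centroids(X, cand)$labels, nbins = nrow(cand)) + 1e-9
  centers <- matrix(NA_real_, k, ncol(X))
  d2c <- rep(Inf, nrow(cand))
  pick <- sample.int(nrow(cand), 1L, prob = w)
  centers[1, ] <- cand[pick, ]
  for (j in seq_len(k - 1L)) {
    d2c <- pmin(d2c, rowSums(sweep(cand, 2, centers[j, ])^2))
    prob <- w * d2c
    if (sum(prob) <= 0) prob <- w
    centers[j + 1L, ] <- cand[sample.int(nrow(cand), 1L, prob = prob), ]
  }
  centers
}

#' Cluster embeddings into spatial domains with k-means
#'
#' Embeddings from all sections are clustered jointly (cross-section
#' integration is definitional for organ-level domains). Seeding is
#' scalable k-means++ with oversampling factor 3; the best of `n_init`
#' initializations by inertia is returned. Within one initialization the
#' inertia is checked to be non-increasing every Lloyd iteration. Empty
#' clusters are re-seeded from the farthest point. With `minibatch_size`
#' set, assignment/update run on random minibatches so memory stays
#' O(batch x d + k x d).
#'
#' @param emb N x d embedding matrix
#' @param k number of domains (`<= N`)
#' @param n_init independent initializations
#' @param max_iter Lloyd (or minibatch) iteration cap
#' @param seed integer seed
#' @param minibatch_size optional minibatch size; `NULL` = full batch
#' @param tol relative inertia change declaring convergence
#' @return a `domain_labels` list: `labels` (0-based integers), `k`,
#'   `centroids` (k x d), `inertia`, `seed`
#' @export
cluster_domains <- function(emb, k, n_init = 3L, max_iter = 1000L, seed = 1L,
                            minibatch_size = NULL, tol = 1e-6) {
  X <- as.matrix(emb)
  n <- nrow(X)
  if (k > n) stop2("k (", k, ") exceeds the number of cells (", n, ")")
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      C <- kmeanspp_seed(X, k)
      if (is.null(minibatch_size)) {
        prev <- Inf
        for (it in seq_len(max_iter)) {
          a <- assign_to_centroids(X, C)
          inertia <- sum(a$dist2)
          stopifnot(inertia <= prev * (1 + 1e-9)) # Lloyd monotonicity
          counts <- tabulate(a$labels, nbins = k)
          if (any(counts == 0)) {
            far <- order(a$dist2, decreasing = TRUE)
            empties <- which(counts == 0)
            C[empties, ] <- X[far[seq_along(empties)], , drop = FALSE]
            message("re-seeded ", length(empties), " empty cluster(s)")
            prev <- Inf
            next
          }
          Cn <- rowsum(X, a$labels) / counts
          if (prev - inertia < tol * max(prev, 1e-12) && it > 1) { C <- Cn; break }
          prev <- inertia
          C <- Cn
        }
      } else {
        counts <- rep(0, k)
        for (it in seq_len(max_iter)) {
          rows <- sample.int(n, min(minibatch_size, n))
          a <- assign_to_centroids(X[rows, , drop = FALSE], C)
          for (j in unique(a$labels)) {
            sel <- rows[a$labels == j]
            counts[j] <- counts[j] + length(sel)
            eta <- length(sel) / counts[j]
            C[j, ] <- (1 - eta) * C[j, ] + eta * colMeans(X[sel, , drop = FALSE])
          }
        }
      }
      a <- assign_to_centroids(X, C)
      inertia <- sum(a$dist2)
      if (is.null(best) || inertia < best$inertia) {
        best <- list(labels = a$labels - 1L, k = as.integer(k), centroids = C,
                     inertia = inertia, seed = seed)
      }
    }
  })
  structure(best, class = "domain_labels")
}

#' @export
print.domain_labels <- function(x, ...) {
  cat(sprintf("<domain_labels> k=%d over %d cells | inertia %.4g\n",
              x$k, length(x$labels), x$inertia))
  invisible(x)
}

#' Amari-type dissimilarity between two centroid sets
#'
#' Permutation-tolerant distance between clustering solutions. With C the
#' K x K Pearson correlation matrix between the centroids of D and D'
#' (each centroid correlated across the d embedding dimensions),
#' \deqn{\mathrm{diss}(D,D') = \frac{1}{2K}\Big(2K - \sum_k \max_j C_{kj}
#'   - \sum_j \max_k C_{kj}\Big).}
#' Zero iff the sets match up to permutation (perfect correlation);
#' bounded by 2.
#'
#' @param D,Dp K x d centroid matrices (equal dimensions)
#' @return scalar dissimilarity in `[0, 2]`
#' @export
amari_dissimilarity <- function(D, Dp) {
  D <- as.matrix(D); Dp <- as.matrix(Dp)
  if (!all(dim(D) == dim(Dp))) stop2("centroid sets must have equal dimensions")
  K <- nrow(D)
  sds <- apply(D, 1, stats::sd); sdp <- apply(Dp, 1, stats::sd)
  if (any(sds == 0) || any(sdp == 0)) {
    bad <- c(which(sds == 0), which(sdp == 0))[1]
    stop2("centroid ", bad, " is constant; Pearson correlation undefined")
  }
  C <- stats::cor(t(D), t(Dp))
  (2 * K - sum(apply(C, 1, max)) - sum(apply(C, 2, max))) / (2 * K)
}

#' Stability scan over the number of domains
#'
#' For each k in the grid, k-means is repeated with `replicates` distinct
#' seeds; instability is the mean Amari-type dissimilarity over all
#' unordered replicate pairs, and the mean inertia is recorded alongside.
#'
#' @param emb embedding matrix
#' @param k_grid strictly increasing integer grid of candidate k
#' @param replicates clustering replicates per k (default 20)
#' @param seed base seed; replicate r of k uses a seed derived from it
#' @param ... passed to [cluster_domains()] (e.g. `n_init`, `max_iter`,
#'   `minibatch_size`)
#' @return a `stability_result`: `k_grid`, `mean_diss`, `mean_inertia`,
#'   and `centroids` (list over k of lists over replicates)
#' @export
stability_scan <- function(emb, k_grid, replicates = 20L, seed = 1L, ...) {
  if (replicates < 2) stop2("need at least 2 replicates")
  if (is.unsorted(k_grid, strictly = TRUE)) stop2("k_grid must be strictly increasing")
  mean_diss <- numeric(length(k_grid))
  mean_inertia <- numeric(length(k_grid))
  centroids <- vector("list", length(k_grid))
  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    reps <- lapply(seq_len(replicates), function(r) {
      tryCatch(
        cluster_domains(emb, k, seed = seed + 7919L * ki + r, ...),
        error = function(e) stop2("k = ", k, ": ", conditionMessage(e)))
    })
    cent <- lapply(reps, `[[`, "centroids")
    pairs <- utils::combn(replicates, 2)
    dvals <- apply(pairs, 2, function(pr) {
      amari_dissimilarity(cent[[pr[1]]], cent[[pr[2]]])
    })
    mean_diss[ki] <- mean(dvals)
    mean_inertia[ki] <- mean(vapply(reps, `[[`, numeric(1), "inertia"))
    centroids[[ki]] <- cent
  }
  structure(list(k_grid = as.integer(k_grid), mean_diss = mean_diss,
                 mean_inertia = mean_inertia, centroids = centroids,
                 replicates = as.integer(replicates)),
            class = "stability_result")
}

#' Choose the number of domains from a stability scan
#'
#' The mean-inertia and mean-instability curves are min-max normalized to
#' `[0, 1]`, averaged, and the second derivative of the averaged curve is
#' estimated by central differences on the (possibly non-uniform) grid.
#' The selected k is the grid point at which the second derivative first
#' changes sign; if it never does, `NA` is returned with a warning.
#'
#' @param result a [stability_scan()] result (at least 4 grid points)
#' @return the selected k (integer) or `NA`
#' @export
select_k <- function(result) {
  kg <- result$k_grid
  if (length(kg) < 4) stop2("need at least 4 grid points to locate an inflection")
  mm <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }
  f <- (mm(result$mean_inertia) + mm(result$mean_diss)) / 2
  i <- 2:(length(kg) - 1)
  h1 <- kg[i] - kg[i - 1]; h2 <- kg[i + 1] - kg[i]
  d2 <- 2 * ((f[i + 1] - f[i]) / h2 - (f[i] - f[i - 1]) / h1) / (h1 + h2)
  sgn <- sign(d2)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0) {
    warning("no second-derivative sign change on the grid; returning NA")
    return(NA_integer_)
  }
  # grid point of the later interior node of the first sign-change pair
  kg[i[flip[1] + 1L]]
}
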