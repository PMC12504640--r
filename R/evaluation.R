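#' Spatial homogeneity of a parcellation
#'
#' For every cell, the fraction of its `n_neighbors` nearest same-section
#' Euclidean neighbors (self excluded) carrying the same domain label.
#' Reported per cell, averaged over the dataset, and averaged within each
#' domain (the per-domain means feed [discreteness()]). Sections with too
#' few cells are clamped to `section size - 1` neighbors with a message.
#'
#' @param table a [cell_table()]
#' @param labels integer domain labels aligned with the table (a
#'   `domain_labels` object or a bare vector)
#' @param n_neighbors spatial neighbors per cell (default 100)
#' @return list with `per_cell`, `dataset_mean`, `per_domain_mean`,
#'   `n_neighbors`
#' @export
spatial_homogeneity <- function(table, labels, n_neighbors = 100L) {
  lab <- if (inherits(labels, "domain_labels")) labels$labels else labels
  if (length(lab) != n_cells(table)) {
    stop2("labels (", length(lab), ") misaligned with table (", n_cells(table), ")")
  }
  stopifnot(n_neighbors >= 1)
  per_cell <- numeric(length(lab))
  x <- table$obs$x; y <- table$obs$y
  for (sec in unique(table$obs$section_id)) {
    idx <- which(table$obs$section_id == sec)
    kn <- min(n_neighbors, length(idx) - 1L)
    if (kn < n_neighbors) {
      message("section ", sec, ": clamped to ", kn, " neighbors")
    }
    if (kn < 1) { per_cell[idx] <- NA_real_; next }
    labs <- lab[idx]
    for (rows in split(seq_along(idx), ceiling(seq_along(idx) / 2048L))) {
      D <- outer(x[idx[rows]], x[idx], "-")^2 + outer(y[idx[rows]], y[idx], "-")^2
      D[cbind(seq_along(rows), rows)] <- Inf # exclude self
      for (r in seq_along(rows)) {
        nb <- order(D[r, ])[seq_len(kn)]
        per_cell[idx[rows[r]]] <- mean(labs[nb] == labs[rows[r]])
      }
    }
  }
  doms <- sort(unique(lab))
  per_domain <- vapply(doms, function(d) mean(per_cell[lab == d], na.rm = TRUE),
                       numeric(1))
  names(per_domain) <- doms
  list(per_cell = per_cell, dataset_mean = mean(per_cell, na.rm = TRUE),
       per_domain_mean = per_domain, n_neighbors = as.integer(n_neighbors))
}

#' Classify domains as discrete against a reference parcellation
#'
#' The threshold is the given percentile (default 20th) of the reference
#' parcellation's per-domain mean homogeneity values; a method domain is
#' discrete iff its own per-domain mean is at or above the threshold.
#'
#' @param per_domain_mean per-domain mean homogeneity of the method's
#'   domains (from [spatial_homogeneity()])
#' @param per_domain_mean_ref same for the reference parcellation
#' @param percentile reference percentile defining the cutoff
#' @return list with `proportion_discrete`, logical `discrete` flags, and
#'   the `threshold`
#' @export
discreteness <- function(per_domain_mean, per_domain_mean_ref, percentile = 20) {
  if (length(per_domain_mean) == 0 || length(per_domain_mean_ref) == 0) {
    stop2("per-domain vectors must be non-empty")
  }
  thr <- stats::quantile(per_domain_mean_ref, percentile / 100, names = FALSE)
  flags <- per_domain_mean >= thr
  list(proportion_discrete = mean(flags), discrete = flags, threshold = thr)
}

#' Domain-by-type composition matrix
#'
#' Entry (domain, type) is the fraction of the domain's cells of that
#' type; rows sum to 1. Empty domains are dropped with a warning.
#'
#' @param labels domain labels (`domain_labels` or integer vector)
#' @param table a [cell_table()]
#' @return K x C row-stochastic matrix with domain row names and type
#'   column names
#' @export
composition_matrix <- function(labels, table) {
  lab <- if (inherits(labels, "domain_labels")) labels$labels else labels
  if (length(lab) != n_cells(table)) stop2("labels misaligned with table")
  doms <- sort(unique(lab))
  C <- length(table$type_levels)
  M <- matrix(0, length(doms), C,
              dimnames = list(as.character(doms), table$type_levels))
  for (di in seq_along(doms)) {
    tb <- tabulate(table$obs$cell_type[lab == doms[di]], nbins = C)
    M[di, ] <- tb / sum(tb)
  }
  if (inherits(labels, "domain_labels") && length(doms) < labels$k) {
    warning(labels$k - length(doms), " empty domain(s) dropped")
  }
  M
}

#' Match two parcellations by cell-type composition
#'
#' Rows of A are matched to rows of B by Pearson correlation of their
#' composition vectors: either each A-domain's best match (non-exclusive
#' maximum) or an exclusive one-to-one pairing maximizing total
#' correlation via the linear sum assignment algorithm. When the two sets
#' differ in size, assignment pairs the smaller set's domains.
#'
#' @param A,B composition matrices over the same type vocabulary
#' @param mode `"max"` or `"assignment"`
#' @return list with `mean_r` and a `matches` data.frame
#'   (`domain_a`, `domain_b`, `r`)
#' @export
match_compositions <- function(A, B, mode = c("max", "assignment")) {
  mode <- match.arg(mode)
  if (ncol(A) != ncol(B)) stop2("composition matrices use different type vocabularies")
  flag_constant <- function(M, nm) {
    sds <- apply(M, 1, stats::sd)
    if (any(sds == 0)) {
      stop2("domain ", rownames(M)[which(sds == 0)[1]] %||% which(sds == 0)[1],
            " of ", nm, " has a constant composition; correlation undefined")
    }
  }
  flag_constant(A, "A"); flag_constant(B, "B")
  R <- stats::cor(t(A), t(B))
  if (mode == "max") {
    j <- max.col(R, ties.method = "first")
    r <- R[cbind(seq_len(nrow(R)), j)]
    matches <- data.frame(domain_a = rownames(A) %||% seq_len(nrow(A)),
                          domain_b = (rownames(B) %||% seq_len(nrow(B)))[j],
                          r = r)
  } else {
    flipped <- nrow(A) > nrow(B)
    Rm <- if (flipped) t(R) else R
    if (flipped) message("rectangular assignment over ", nrow(Rm), " pairs")
    j <- solve_assignment(-Rm)
    r <- Rm[cbind(seq_len(nrow(Rm)), j)]
    ida <- if (flipped) j else seq_len(nrow(A))
    idb <- if (flipped) seq_len(nrow(Rm)) else j
    matches <- data.frame(domain_a = (rownames(A) %||% seq_len(nrow(A)))[ida],
                          domain_b = (rownames(B) %||% seq_len(nrow(B)))[idb],
                          r = r)
  }
  list(mean_r = mean(matches$r), matches = matches, mode = mode)
}

#' Agreement between two labelings
#'
#' Normalized mutual information (arithmetic normalization of entropies)
#' and the adjusted Rand index.
#'
#' @param labels_a,labels_b aligned label vectors
#' @return list with `nmi` and `ari`
#' @export
clustering_agreement <- function(labels_a, labels_b) {
  a <- if (inherits(labels_a, "domain_labels")) labels_a$labels else labels_a
  b <- if (inherits(labels_b, "domain_labels")) labels_b$labels else labels_b
  if (length(a) != length(b)) stop2("label vectors differ in length")
  af <- as.integer(factor(a)); bf <- as.integer(factor(b))
  nmi <- if (max(af) == 1 && max(bf) == 1) 1 else
    igraph::compare(af, bf, method = "nmi")
  list(nmi = nmi, ari = mclust::adjustedRandIndex(af, bf))
}

# minimum-norm least squares via SVD (rank-deficient designs allowed)
minnorm_lstsq <- function(X, Y) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < ncol(X)) message("rank-deficient design: minimum-norm solution")
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, Y))
}

#' Linear probing of embeddings
#'
#' Quantifies the metadata content of the embedding space with simple
#' linear readouts. `target = "coordinates"`: ordinary least squares from
#' embeddings (plus intercept) to spatial coordinates; the per-cell error
#' is the Euclidean distance between the predicted and true position, and
#' both the median and mean are reported (per animal too when animal ids
#' exist). `target = "donor"`: multinomial logistic regression on the
#' animal identity with per-donor accuracy.
#'
#' @param emb N x d embedding matrix
#' @param table the matching [cell_table()]
#' @param target `"coordinates"` or `"donor"`
#' @param coords optional N x p coordinate matrix; defaults to the table's
#'   registered `ccf_x/ccf_y/ccf_z` columns when present, else `(x, y)`
#' @return a list report: for coordinates `median_abs_error`,
#'   `mean_abs_error`, `per_cell_error`, `coefficients`, and `per_donor`
#'   when available; for donor `accuracy`, `per_donor_accuracy`,
#'   `predicted`
#' @export
linear_probe <- function(emb, table, target = c("coordinates", "donor"),
                         coords = NULL) {
  target <- match.arg(target)
  emb <- as.matrix(emb)
  if (nrow(emb) != n_cells(table)) stop2("embedding rows misaligned with table")
  if (target == "coordinates") {
    if (is.null(coords)) {
      coords <- if (all(c("ccf_x", "ccf_y", "ccf_z") %in% names(table$obs))) {
        as.matrix(table$obs[, c("ccf_x", "ccf_y", "ccf_z")])
      } else {
        as.matrix(table$obs[, c("x", "y")])
      }
    }
    coords <- as.matrix(coords)
    X <- cbind(1, emb)
    beta <- minnorm_lstsq(X, coords)
    err <- sqrt(rowSums((X %*% beta - coords)^2))
    out <- list(median_abs_error = stats::median(err),
                mean_abs_error = mean(err), per_cell_error = err,
                coefficients = beta)
    if (!is.null(table$obs$animal_id)) {
      out$per_donor <- vapply(split(err, table$obs$animal_id), stats::median,
                              numeric(1))
    }
    out
  } else {
    if (is.null(table$obs$animal_id)) stop2("donor probing needs animal_id")
    donor <- factor(table$obs$animal_id)
    df <- data.frame(donor = donor, emb)
    cap <- utils::capture.output(
      fit <- nnet::multinom(donor ~ ., data = df, maxit = 200, MaxNWts = 1e5,
                            trace = FALSE))
    pred <- stats::predict(fit, df)
    acc <- mean(pred == donor)
    per <- vapply(levels(donor),
                  function(d) mean(pred[donor == d] == d), numeric(1))
    list(accuracy = acc, per_donor_accuracy = per, predicted = pred)
  }
}

#' Predicted mean expression for every cell
#'
#' Runs the trained model over each cell's neighborhood and decodes the
#' ZINB mean (`scale * mean` simplex) for the masked reference cell.
#'
#' @param model a trained [nichescope_model()]
#' @param table,index data and neighborhood index
#' @param batch_size forward-pass batch size
#' @return N x g matrix of predicted mean counts
#' @export
predict_expression <- function(model, table, index, batch_size = 512L) {
  n <- n_cells(table)
  out <- matrix(NA_real_, n, n_genes(table))
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    batch <- batch_neighborhoods(index, chunk, table)
    out[chunk, ] <- model_forward(model, batch, table)$params$mu
  }
  colnames(out) <- gene_names(table)
  out
}

#' Spatial contribution to expression prediction
#'
#' Per cell, the Pearson correlation between observed counts and (a) the
#' model's predicted mean profile and (b) the dataset-wide mean expression
#' vector; each is averaged within cell type and the difference
#' `delta_r = r_model - r_baseline` reports what neighborhood context adds
#' for that type. Cells with zero-variance observed vectors are skipped
#' and counted.
#'
#' @param table a [cell_table()]
#' @param predicted N x g matrix of model predictions (e.g. from
#'   [predict_expression()])
#' @param baseline optional baseline profile (default: dataset mean
#'   expression)
#' @return data.frame per type: `type`, `r_model`, `r_baseline`,
#'   `delta_r`, `n_cells`; attribute `n_skipped`
#' @export
spatial_contribution <- function(table, predicted, baseline = NULL) {
  Y <- as.matrix(table$counts)
  if (!all(dim(predicted) == dim(Y))) stop2("prediction matrix misaligned")
  base <- baseline %||% colMeans(Y)
  vy <- apply(Y, 1, stats::var)
  skip <- vy == 0
  r_model <- r_base <- rep(NA_real_, nrow(Y))
  ok <- which(!skip)
  r_model[ok] <- vapply(ok, function(i) stats::cor(Y[i, ], predicted[i, ]),
                        numeric(1))
  r_base[ok] <- vapply(ok, function(i) stats::cor(Y[i, ], base), numeric(1))
  types <- table$obs$cell_type
  out <- do.call(rbind, lapply(sort(unique(types)), function(t) {
    sel <- types == t & !skip
    data.frame(type = table$type_levels[t],
               r_model = mean(r_model[sel]),
               r_baseline = mean(r_base[sel]),
               n_cells = sum(sel))
  }))
  out$delta_r <- out$r_model - out$r_baseline
  attr(out, "n_skipped") <- sum(skip)
  out
}

#' Rank marker genes per domain
#'
#' For domain d and gene g the log2 fold change is
#' `log2((mean in d + pc) / (mean outside d + pc))`; genes with
#' `lfc >= min_log2fc` (default 1) are markers, sorted by lfc.
#'
#' @param table a [cell_table()]
#' @param labels domain labels
#' @param min_log2fc marker threshold on log2 fold change
#' @param pseudocount added to both means before the ratio
#' @return named list (one per domain) of data.frames `gene`, `lfc`,
#'   `mean_in`, `mean_out`
#' @export
rank_domain_markers <- function(table, labels, min_log2fc = 1, pseudocount = 1) {
  lab <- if (inherits(labels, "domain_labels")) labels$labels else labels
  doms <- sort(unique(lab))
  if (length(doms) < 2) stop2("need at least 2 domains to rank markers")
  Y <- table$counts
  out <- lapply(doms, function(d) {
    m_in <- Matrix::colMeans(Y[lab == d, , drop = FALSE])
    m_out <- Matrix::colMeans(Y[lab != d, , drop = FALSE])
    lfc <- log2((m_in + pseudocount) / (m_out + pseudocount))
    sel <- which(lfc >= min_log2fc)
    df <- data.frame(gene = gene_names(table)[sel], lfc = lfc[sel],
                     mean_in = m_in[sel], mean_out = m_out[sel])
    df[order(-df$lfc), , drop = FALSE]
  })
  names(out) <- as.character(doms)
  out
}

#' Cross-animal domain consistency
#'
#' A domain counts as present in an animal when at least `min_cells` of
#' that animal's cells carry the label; the headline number is the
#' fraction of domains present in every animal.
#'
#' @param labels domain labels
#' @param animal_ids aligned animal/donor ids
#' @param min_cells presence threshold per animal
#' @return list with `fraction_shared`, logical `presence` matrix
#'   (domain x animal), and `n_domains`
#' @export
cross_animal_consistency <- function(labels, animal_ids, min_cells = 10L) {
  lab <- if (inherits(labels, "domain_labels")) labels$labels else labels
  if (length(lab) != length(animal_ids)) stop2("labels and animal ids misaligned")
  animals <- sort(unique(as.character(animal_ids)))
  if (length(animals) < 2) stop2("need at least 2 animals")
  doms <- sort(unique(lab))
  pres <- sapply(animals, function(a) {
    tab <- table(factor(lab[animal_ids == a], levels = doms))
    as.vector(tab) >= min_cells
  })
  rownames(pres) <- as.character(doms)
  list(fraction_shared = mean(rowSums(pres) == length(animals)),
       presence = pres, n_domains = length(doms))
}
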