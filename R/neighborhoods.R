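#' Neighborhood configuration
#'
#' A cell j belongs to the neighborhood of reference cell i when it lies
#' inside an axis-aligned square box centered on i. With the default
#' `"full"` width convention a `box_width` of 85 microns (the MERFISH
#' setting; 50 microns for Slide-seqV2) admits cells within 42.5 microns
#' in Chebyshev distance; the `"half"` convention treats `box_width` as
#' the half-width itself.
#'
#' @param box_width box size in microns
#' @param max_neighbors optional cap on neighbors per reference; when set,
#'   the nearest cells by Euclidean distance are kept (ties broken by cell
#'   index)
#' @param same_section_only neighborhoods never cross tissue sections
#'   (sections are physically separate); kept as an explicit flag
#' @param width_convention `"full"` (default: half-width = box_width / 2)
#'   or `"half"`
#' @return a `neighborhood_config` list
#' @export
neighborhood_config <- function(box_width = 85, max_neighbors = NULL,
                                same_section_only = TRUE,
                                width_convention = c("full", "half")) {
  stopifnot(box_width > 0)
  width_convention <- match.arg(width_convention)
  structure(list(box_width = box_width, max_neighbors = max_neighbors,
                 same_section_only = same_section_only,
                 width_convention = width_convention),
            class = "neighborhood_config")
}

half_width <- function(cfg) {
  if (cfg$width_convention == "full") cfg$box_width / 2 else cfg$box_width
}

#' Build the spatial neighborhood index
#'
#' For every cell (each cell appears once as a reference) the sorted
#' indices of all other same-section cells within the box are recorded:
#' `max(|xi - xj|, |yi - yj|) <= half-width`, boundary inclusive, no
#' self-loops. Uses spatial binning, so cost is near-linear in cells for
#' realistic densities.
#'
#' @param table a [cell_table()]
#' @param cfg a [neighborhood_config()]
#' @return a `neighborhood_index`: list with `neighbors` (list of sorted
#'   integer vectors), `degree`, `section_id`, and the config
#' @export
build_neighborhood_index <- function(table, cfg = neighborhood_config()) {
  n <- n_cells(table)
  if (n == 0) stop2("cell table is empty")
  x <- table$obs$x; y <- table$obs$y
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    bad <- which(!is.finite(x) | !is.finite(y))[1]
    stop2("non-finite coordinates for cell ", table$obs$cell_id[bad])
  }
  h <- half_width(cfg)
  neighbors <- vector("list", n)
  sections <- if (cfg$same_section_only) table$obs$section_id else rep("all", n)
  for (sec in unique(sections)) {
    idx <- which(sections == sec)
    xs <- x[idx]; ys <- y[idx]
    # bin side = half-width: candidates live in the 3x3 bin neighborhood
    bx <- floor(xs / h); by <- floor(ys / h)
    key <- paste(bx, by)
    bins <- split(seq_along(idx), key)
    bin_of <- match(key, names(bins))
    neigh_keys <- function(b1, b2) {
      as.vector(outer(b1 + (-1:1), b2 + (-1:1), paste))
    }
    for (ii in seq_along(idx)) {
      cand <- unlist(bins[neigh_keys(bx[ii], by[ii])], use.names = FALSE)
      cand <- cand[cand != ii]
      keep <- abs(xs[cand] - xs[ii]) <= h & abs(ys[cand] - ys[ii]) <= h
      nb <- cand[keep]
      if (!is.null(cfg$max_neighbors) && length(nb) > cfg$max_neighbors) {
        d2 <- (xs[nb] - xs[ii])^2 + (ys[nb] - ys[ii])^2
        nb <- nb[order(d2, nb)][seq_len(cfg$max_neighbors)]
      }
      neighbors[[idx[ii]]] <- sort(idx[nb])
    }
  }
  structure(list(neighbors = neighbors,
                 degree = lengths(neighbors),
                 section_id = table$obs$section_id,
                 config = cfg, n_cells = n),
            class = "neighborhood_index")
}

#' @export
print.neighborhood_index <- function(x, ...) {
  cat(sprintf("<neighborhood_index> %d cells | box %g um (%s width) | mean degree %.1f\n",
              x$n_cells, x$config$box_width, x$config$width_convention,
              mean(x$degree)))
  invisible(x)
}

#' Assemble a padded, masked batch of neighborhoods
#'
#' Each selected reference cell contributes one neighborhood whose token
#' slots are its neighbors plus one register slot (slot 1, encoded 0).
#' Slots are padded to the largest neighborhood in the batch; the validity
#' mask guarantees padded slots never reach the model. The block (ragged)
#' layout used internally keeps attention strictly within neighborhoods.
#'
#' @param index a [build_neighborhood_index()] result
#' @param refs integer indices of reference cells
#' @param table the [cell_table()] the index was built on
#' @return a `neighborhood_batch`: `slots` (B x S integer matrix, 0 =
#'   register token, NA = padding), `mask` (B x S logical), `refs`,
#'   `ref_types`, and flat block structure (`groups`, `flat_cells`,
#'   `is_register`)
#' @export
batch_neighborhoods <- function(index, refs, table) {
  if (length(refs) == 0) stop2("empty reference set")
  if (any(refs < 1 | refs > index$n_cells)) stop2("reference ids outside the index")
  nb <- index$neighbors[refs]
  sizes <- lengths(nb) + 1L # register token
  smax <- max(sizes)
  b <- length(refs)
  slots <- matrix(NA_integer_, b, smax)
  mask <- matrix(FALSE, b, smax)
  slots[, 1] <- 0L
  mask[, 1] <- TRUE
  for (i in seq_len(b)) {
    m <- sizes[i] - 1L
    if (m > 0) {
      slots[i, 1 + seq_len(m)] <- nb[[i]]
      mask[i, 1 + seq_len(m)] <- TRUE
    }
  }
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  flat_cells <- integer(ends[b])
  is_register <- logical(ends[b])
  for (i in seq_len(b)) {
    is_register[starts[i]] <- TRUE
    flat_cells[starts[i]] <- NA_integer_
    if (sizes[i] > 1L) flat_cells[(starts[i] + 1L):ends[i]] <- nb[[i]]
  }
  structure(list(slots = slots, mask = mask, refs = refs,
                 ref_types = table$obs$cell_type[refs],
                 groups = mapply(function(s, e) s:e, starts, ends,
                                 SIMPLIFY = FALSE),
                 flat_cells = flat_cells, is_register = is_register,
                 n_tokens = ends[b]),
            class = "neighborhood_batch")
}

#' Recover per-reference neighbor sets from a batch
#'
#' @param batch a [batch_neighborhoods()] result
#' @return named list of sorted neighbor index vectors, one per reference
#' @export
unbatch_neighborhoods <- function(batch) {
  out <- lapply(seq_along(batch$refs), function(i) {
    s <- batch$slots[i, ]
    sort(s[!is.na(s) & s > 0])
  })
  names(out) <- as.character(batch$refs)
  out
}
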