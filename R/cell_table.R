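#' Construct a cell table
#'
#' The central data container: one row per cell with 2D spatial coordinates
#' in microns, a tissue-section identifier, an optional animal/donor
#' identifier, a categorical cell-type label, and a cell-by-gene matrix of
#' raw transcript counts (MERFISH probe counts or deconvoluted Slide-seqV2
#' counts). Counts are stored sparsely; log-transformed counts are derived
#' lazily as `log1p` unless supplied by the source.
#'
#' @param obs data.frame with columns `cell_id`, `x`, `y`, `section_id`,
#'   `cell_type` (integer codes in `1..C` or a factor/character vector that
#'   will be encoded against `type_levels`), and optionally `animal_id` and
#'   registered 3D coordinates `ccf_x`, `ccf_y`, `ccf_z`.
#' @param counts cell-by-gene matrix of non-negative integer counts (dense
#'   or any Matrix sparse class; stored as `dgCMatrix`). Column names are
#'   gene names.
#' @param type_levels character vocabulary of cell-type labels; defaults to
#'   the levels present in `obs$cell_type`.
#' @param meta named list of free-form provenance metadata (e.g. the
#'   log-transform used, original coordinate units).
#' @return An object of class `cell_table`.
#' @export
cell_table <- function(obs, counts, type_levels = NULL, meta = list()) {
  required <- c("cell_id", "x", "y", "section_id", "cell_type")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    stop2("cell table metadata is missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(obs$x)) || !all(is.finite(obs$y))) {
    bad <- which(!is.finite(obs$x) | !is.finite(obs$y))
    stop2("non-finite coordinates for cell(s): ",
          paste(utils::head(obs$cell_id[bad], 5), collapse = ", "))
  }
  if (anyNA(obs$section_id)) stop2("section_id must be present for every cell")
  if (!methods::is(counts, "sparseMatrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != nrow(obs)) {
    stop2("count matrix has ", nrow(counts), " rows but metadata has ",
          nrow(obs), " rows")
  }
  if (any(counts@x < 0) || any(abs(counts@x - round(counts@x)) > 1e-8)) {
    stop2("counts must be non-negative integers")
  }
  if (is.numeric(obs$cell_type)) {
    ct <- as.integer(obs$cell_type)
    if (is.null(type_levels)) type_levels <- as.character(seq_len(max(ct)))
  } else {
    f <- factor(obs$cell_type, levels = type_levels %||% sort(unique(as.character(obs$cell_type))))
    type_levels <- levels(f)
    ct <- as.integer(f)
  }
  if (anyNA(ct) || any(ct < 1) || any(ct > length(type_levels))) {
    stop2("cell_type labels fall outside the type vocabulary")
  }
  obs$cell_type <- ct
  obs$section_id <- as.character(obs$section_id)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%03d", seq_len(ncol(counts)))
  }
  structure(
    list(obs = obs, counts = counts, type_levels = type_levels,
         meta = utils::modifyList(list(log_transform = "log1p"), meta)),
    class = "cell_table"
  )
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf(
    "<cell_table> %d cells x %d genes | %d section(s), %d cell type(s)%s\n",
    nrow(x$obs), ncol(x$counts), length(unique(x$obs$section_id)),
    length(x$type_levels),
    if (!is.null(x$obs$animal_id))
      sprintf(", %d animal(s)", length(unique(x$obs$animal_id))) else ""))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

n_cells <- function(table) nrow(table$obs)
n_genes <- function(table) ncol(table$counts)
gene_names <- function(table) colnames(table$counts)

#' Subset a cell table by cell and/or gene
#'
#' @param x a [cell_table()]
#' @param i integer/logical index over cells
#' @param j integer/logical/character index over genes
#' @param ... ignored
#' @export
`[.cell_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$obs))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  cell_table(x$obs[i, , drop = FALSE],
             x$counts[i, j, drop = FALSE],
             type_levels = x$type_levels, meta = x$meta)
}

#' Log-transformed counts for a set of cells
#'
#' Returns the dense matrix of log-transformed counts (natural `log1p` of
#' raw counts unless the source supplied pre-logged values) used as the
#' expression input of the cell tokenizer.
#'
#' @param table a [cell_table()]
#' @param cells integer indices of cells (default all)
#' @return dense numeric matrix, `length(cells)` x genes
#' @export
log_counts <- function(table, cells = NULL) {
  cells <- cells %||% seq_len(n_cells(table))
  m <- as.matrix(table$counts[cells, , drop = FALSE])
  log1p(m)
}

#' Read a cell table from disk
#'
#' Two on-disk layouts are supported. `"mtx"`: a directory holding
#' `matrix.mtx` (cells x genes, MatrixMarket), `genes.tsv` (one gene name
#' per line) and `metadata.tsv` (tab-separated cell metadata, rows aligned
#' with the matrix). `"tabular"`: a single wide CSV (or Parquet, read via
#' the arrow package when installed) with the metadata columns followed by
#' one column per gene.
#'
#' @param path directory (`"mtx"`) or file (`"tabular"`) path
#' @param format one of `"mtx"`, `"tabular"`; `"h5"` is recognized but not
#'   supported by this build and raises an informative error
#' @param coord_unit unit of the source `x`/`y` columns; `"mm"` sources are
#'   converted to microns (multiplied by 1000) on load
#' @return a validated [cell_table()]
#' @export
read_cell_table <- function(path, format = c("mtx", "tabular", "h5"),
                            coord_unit = c("micron", "mm")) {
  format <- match.arg(format)
  coord_unit <- match.arg(coord_unit)
  if (format == "h5") {
    stop2("the HDF5 single-cell container is not supported by this build; ",
          "export to MTX + metadata or a tabular file instead")
  }
  if (format == "mtx") {
    mfile <- file.path(path, "matrix.mtx")
    gfile <- file.path(path, "genes.tsv")
    ofile <- file.path(path, "metadata.tsv")
    for (f in c(mfile, gfile, ofile)) {
      if (!file.exists(f)) stop2("expected file not found: ", f)
    }
    counts <- Matrix::readMM(mfile)
    genes <- readLines(gfile)
    obs <- utils::read.delim(ofile, stringsAsFactors = FALSE)
    if (nrow(obs) != nrow(counts)) {
      stop2("metadata rows (", nrow(obs), ") do not align with matrix rows (",
            nrow(counts), ")")
    }
    colnames(counts) <- genes
  } else {
    if (grepl("\\.parquet$", path)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop2("reading Parquet requires the arrow package")
      }
      df <- as.data.frame(arrow::read_parquet(path))
    } else {
      df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    }
    meta_cols <- intersect(
      c("cell_id", "x", "y", "section_id", "animal_id", "cell_type",
        "ccf_x", "ccf_y", "ccf_z", "domain_truth"),
      names(df))
    obs <- df[, meta_cols, drop = FALSE]
    counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  }
  if (coord_unit == "mm") {
    obs$x <- obs$x * 1000
    obs$y <- obs$y * 1000
  }
  cell_table(obs, counts, meta = list(source = path, coord_unit = "micron"))
}

#' Write a cell table to disk
#'
#' Inverse of [read_cell_table()]; round-trips counts exactly and
#' coordinates to full double precision.
#'
#' @param table a [cell_table()]
#' @param path directory (`"mtx"`) or file (`"tabular"`) to write
#' @param format one of `"mtx"`, `"tabular"`
#' @return `path`, invisibly
#' @export
write_cell_table <- function(table, path, format = c("mtx", "tabular")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(table$counts, file.path(path, "matrix.mtx"))
    writeLines(gene_names(table), file.path(path, "genes.tsv"))
    obs <- table$obs
    obs$cell_type <- table$type_levels[obs$cell_type]
    utils::write.table(obs, file.path(path, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    df <- cbind(table$obs, as.matrix(table$counts))
    df$cell_type <- table$type_levels[df$cell_type]
    if (grepl("\\.parquet$", path)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop2("writing Parquet requires the arrow package")
      }
      arrow::write_parquet(df, path)
    } else {
      utils::write.csv(df, path, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Reproducible train/test split over cells
#'
#' Uniform random split across the entire dataset (not stratified by
#' section), with an 80/20 default.
#'
#' @param table a [cell_table()]
#' @param train_fraction fraction of cells assigned to training, in (0, 1)
#' @param seed integer seed; the caller's RNG stream is left untouched
#' @return list with disjoint, exhaustive integer vectors `train` and `test`
#' @export
split_train_test <- function(table, train_fraction = 0.8, seed = 1L) {
  n <- n_cells(table)
  if (n < 2) stop2("need at least 2 cells to split")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop2("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- max(1L, min(n - 1L, round(n * train_fraction)))
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}
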