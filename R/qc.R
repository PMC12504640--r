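#' Quality-control configuration
#'
#' Defaults follow the filters used for deconvoluted Slide-seqV2 data:
#' cells with more than 20% mitochondrial counts or within the lowest 10th
#' percentile of read depth of their own section are removed, and only
#' genes expressed in more than 10% of cells are kept.
#'
#' @param mito_fraction_max maximum tolerated mitochondrial count fraction
#' @param depth_percentile_min per-section read-depth percentile below (or
#'   at) which cells are removed
#' @param gene_prevalence_min minimum fraction of cells in which a gene
#'   must be detected (count > 0)
#' @param mito_gene_set character vector of mitochondrial gene names (may
#'   be empty); these genes are used for the fraction and then dropped
#' @return a `qc_config` list
#' @export
qc_config <- function(mito_fraction_max = 0.20, depth_percentile_min = 10,
                      gene_prevalence_min = 0.10, mito_gene_set = character()) {
  stopifnot(mito_fraction_max >= 0, mito_fraction_max <= 1,
            depth_percentile_min >= 0, depth_percentile_min <= 100,
            gene_prevalence_min >= 0, gene_prevalence_min <= 1)
  structure(list(mito_fraction_max = mito_fraction_max,
                 depth_percentile_min = depth_percentile_min,
                 gene_prevalence_min = gene_prevalence_min,
                 mito_gene_set = mito_gene_set),
            class = "qc_config")
}

#' Filter low-quality cells and rarely expressed genes
#'
#' Gene filters run first: mitochondrial genes (after computing per-cell
#' mitochondrial fractions on the full matrix) and genes detected in no
#' more than `gene_prevalence_min` of cells are dropped. Cell filters then
#' run on the gene-filtered matrix: a cell is removed if its mitochondrial
#' fraction exceeds `mito_fraction_max` or its total depth falls at or
#' below the `depth_percentile_min` percentile of its own section.
#'
#' @param table a [cell_table()]
#' @param cfg a [qc_config()]
#' @return the filtered `cell_table`, with a `qc_report` attribute listing
#'   `removed_cells` (ids with a `reason` column) and `removed_genes`
#' @export
filter_qc <- function(table, cfg = qc_config()) {
  genes <- gene_names(table)
  unknown_mito <- setdiff(cfg$mito_gene_set, genes)
  mito <- intersect(cfg$mito_gene_set, genes)
  depth_all <- Matrix::rowSums(table$counts)
  mito_frac <- if (length(mito) > 0) {
    Matrix::rowSums(table$counts[, mito, drop = FALSE]) / pmax(depth_all, 1)
  } else rep(0, n_cells(table))

  prevalence <- Matrix::colMeans(table$counts > 0)
  keep_gene <- prevalence > cfg$gene_prevalence_min & !(genes %in% mito)
  removed_genes <- genes[!keep_gene]

  counts_f <- table$counts[, keep_gene, drop = FALSE]
  depth <- Matrix::rowSums(counts_f)
  depth_cut <- tapply(depth, table$obs$section_id, stats::quantile,
                      probs = cfg$depth_percentile_min / 100, names = FALSE)
  low_depth <- as.vector(depth <= depth_cut[table$obs$section_id])
  high_mito <- mito_frac > cfg$mito_fraction_max
  drop_cell <- low_depth | high_mito
  if (all(drop_cell)) stop2("QC removed every cell; relax the thresholds")

  reason <- ifelse(high_mito & low_depth, "mito+depth",
                   ifelse(high_mito, "mito", "depth"))[drop_cell]
  out <- table[!drop_cell, which(keep_gene)]
  attr(out, "qc_report") <- list(
    removed_cells = data.frame(cell_id = table$obs$cell_id[drop_cell],
                               reason = reason),
    removed_genes = removed_genes,
    unknown_mito_genes = unknown_mito,
    n_cells_kept = sum(!drop_cell),
    n_genes_kept = sum(keep_gene))
  out
}
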