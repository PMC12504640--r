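#' Synthetic tissue configuration
#'
#' Generates tissue-like datasets with known ground-truth domains:
#' spatially contiguous domains (layered bands by default, mimicking
#' cortical-layer-like strata 400 microns thick), domain-specific
#' cell-type composition (one Dirichlet draw per domain), and counts from
#' a zero-inflated negative binomial whose log-mean combines a
#' type-specific base profile with an additive domain effect. The default
#' scale (2 sections x 2,500 cells, 5 domains, 8 types, 60 genes, ~4.4e-3
#' cells per square micron so an 85-micron box holds ~30 neighbors) keeps
#' a full train-embed-cluster cycle in CPU minutes.
#'
#' @param n_sections tissue sections
#' @param cells_per_section cells per section
#' @param n_domains ground-truth spatial domains
#' @param n_types cell types C
#' @param n_genes genes g
#' @param geometry `"layered_bands"` (horizontal strata), `"voronoi"`
#'   (nearest of random sites) or `"blocks"` (grid tiles)
#' @param section_width,band_height section geometry in microns; section
#'   height is `n_domains * band_height`
#' @param composition_concentration Dirichlet concentration of per-domain
#'   type compositions (smaller = more domain-distinct)
#' @param expression_effect sd of the additive domain effect on the
#'   type-specific log-mean gene profile (0 = no domain signal in counts)
#' @param zero_inflation probability a count is forced to zero
#' @param depth_mean mean total counts per cell
#' @param dispersion_range per-gene NB dispersion drawn log-uniform in
#'   this range
#' @param n_animals animals for [generate_multi_animal()]
#' @param animal_depth_shift multiplicative per-animal depth factor range
#'   (batch structure); `c(1, 1)` disables it
#' @param seed integer seed
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_sections = 2L, cells_per_section = 2500L,
                             n_domains = 5L, n_types = 8L, n_genes = 60L,
                             geometry = c("layered_bands", "voronoi", "blocks"),
                             section_width = 285, band_height = 400,
                             composition_concentration = 0.5,
                             expression_effect = 1.0, zero_inflation = 0.05,
                             depth_mean = 250, dispersion_range = c(0.5, 10),
                             n_animals = 2L, animal_depth_shift = c(0.7, 1.3),
                             seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_sections >= 1, cells_per_section >= 1, n_domains >= 1,
            n_types >= 1, n_genes >= 1, zero_inflation >= 0, zero_inflation < 1,
            depth_mean > 0)
  if (n_domains > cells_per_section) stop2("more domains than cells per section")
  structure(as.list(environment()), class = "synthetic_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# shared latent parameters (type profiles, domain effects, compositions,
# dispersions) drawn once per dataset so multiple animals can reuse them
draw_truth_params <- function(cfg) {
  list(
    base_profile = matrix(stats::rnorm(cfg$n_types * cfg$n_genes), cfg$n_types),
    domain_effect = matrix(stats::rnorm(cfg$n_domains * cfg$n_genes,
                                        sd = cfg$expression_effect),
                           cfg$n_domains),
    composition = t(vapply(seq_len(cfg$n_domains), function(d) {
      rdirichlet1(rep(cfg$composition_concentration, cfg$n_types))
    }, numeric(cfg$n_types))),
    dispersion = exp(stats::runif(cfg$n_genes, log(cfg$dispersion_range[1]),
                                  log(cfg$dispersion_range[2]))),
    voronoi_sites = cbind(stats::runif(cfg$n_domains, 0, cfg$section_width),
                          stats::runif(cfg$n_domains, 0,
                                       cfg$n_domains * cfg$band_height)))
}

domain_from_geometry <- function(cfg, truth, x, y) {
  height <- cfg$n_domains * cfg$band_height
  switch(cfg$geometry,
    layered_bands = pmin(floor(y / cfg$band_height) + 1L, cfg$n_domains),
    voronoi = {
      D <- dist2_to_centroids(cbind(x, y), truth$voronoi_sites)
      max.col(-D, ties.method = "first")
    },
    blocks = {
      nbx <- ceiling(sqrt(cfg$n_domains))
      bw <- cfg$section_width / nbx
      bh <- height / ceiling(cfg$n_domains / nbx)
      tile <- pmin(floor(x / bw) + nbx * floor(y / bh), cfg$n_domains - 1L)
      as.integer(tile) + 1L
    })
}

sample_counts <- function(cfg, truth, types, domains) {
  n <- length(types)
  logits <- truth$base_profile[types, , drop = FALSE] +
    truth$domain_effect[domains, , drop = FALSE]
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  depth <- stats::rgamma(n, shape = 10, rate = 10 / cfg$depth_mean)
  mu <- p * depth
  th <- matrix(truth$dispersion, n, cfg$n_genes, byrow = TRUE)
  lam <- stats::rgamma(n * cfg$n_genes, shape = th, rate = th / pmax(mu, 1e-12))
  counts <- matrix(stats::rpois(n * cfg$n_genes, lam), n, cfg$n_genes)
  if (cfg$zero_inflation > 0) {
    counts[matrix(stats::runif(n * cfg$n_genes) < cfg$zero_inflation,
                  n, cfg$n_genes)] <- 0L
  }
  counts
}

generate_one_animal <- function(cfg, truth, animal_id, section_prefix,
                                depth_factor = 1) {
  height <- cfg$n_domains * cfg$band_height
  per_sec <- lapply(seq_len(cfg$n_sections), function(s) {
    n <- cfg$cells_per_section
    x <- stats::runif(n, 0, cfg$section_width)
    y <- stats::runif(n, 0, height)
    dom <- domain_from_geometry(cfg, truth, x, y)
    types <- vapply(dom, function(d) {
      sample.int(cfg$n_types, 1, prob = truth$composition[d, ])
    }, integer(1))
    cfg_d <- cfg; cfg_d$depth_mean <- cfg$depth_mean * depth_factor
    counts <- sample_counts(cfg_d, truth, types, dom)
    list(obs = data.frame(
      cell_id = sprintf("%s_s%d_c%05d", animal_id, s, seq_len(n)),
      x = x, y = y,
      section_id = sprintf("%s%d", section_prefix, s),
      animal_id = animal_id,
      cell_type = types,
      domain_truth = dom - 1L),
      counts = counts)
  })
  list(obs = do.call(rbind, lapply(per_sec, `[[`, "obs")),
       counts = do.call(rbind, lapply(per_sec, `[[`, "counts")))
}

#' Generate a synthetic dataset with known domains
#'
#' Cells are placed uniformly per section; the domain label comes from the
#' configured geometry; the cell type is sampled from the domain's
#' composition; counts are ZINB with a type- and domain-dependent mean.
#' Deterministic under `cfg$seed`. Ground-truth domain labels (0-based)
#' are stored in `obs$domain_truth`.
#'
#' @param cfg a [synthetic_config()]
#' @return a [cell_table()]; truth labels in `table$obs$domain_truth`,
#'   generator parameters in `table$meta$truth`
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  with_seed(cfg$seed, {
    truth <- draw_truth_params(cfg)
    a <- generate_one_animal(cfg, truth, "a1", "sec")
    cell_table(a$obs, a$counts,
               type_levels = sprintf("T%02d", seq_len(cfg$n_types)),
               meta = list(truth = truth, config = unclass(cfg)))
  })
}

#' Generate a multi-animal synthetic dataset
#'
#' Identical domain geometry and composition parameters across animals
#' with independent per-animal sampling; an optional per-animal depth
#' factor emulates batch structure. Truth labels use the same domain
#' vocabulary in every animal.
#'
#' @param cfg a [synthetic_config()] with `n_animals >= 2`
#' @return a [cell_table()] spanning all animals
#' @export
generate_multi_animal <- function(cfg = synthetic_config()) {
  if (cfg$n_animals < 2) stop2("need n_animals >= 2")
  with_seed(cfg$seed, {
    truth <- draw_truth_params(cfg)
    shifts <- seq(cfg$animal_depth_shift[1], cfg$animal_depth_shift[2],
                  length.out = cfg$n_animals)
    parts <- lapply(seq_len(cfg$n_animals), function(a) {
      generate_one_animal(cfg, truth, sprintf("a%d", a), sprintf("a%d_sec", a),
                          depth_factor = shifts[a])
    })
    cell_table(do.call(rbind, lapply(parts, `[[`, "obs")),
               do.call(rbind, lapply(parts, `[[`, "counts")),
               type_levels = sprintf("T%02d", seq_len(cfg$n_types)),
               meta = list(truth = truth, config = unclass(cfg),
                           depth_factors = shifts))
  })
}
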