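# Shared fixtures and independent oracles used across the suite.

# small synthetic dataset, wrapped so tests share one scale
small_table <- function(seed = 3, n = 80, genes = 7, types = 3, domains = 2,
                        sections = 1) {
  generate_dataset(synthetic_config(
    n_sections = sections, cells_per_section = n %/% sections,
    n_genes = genes, n_types = types, n_domains = domains, seed = seed))
}

tiny_model <- function(genes = 7, types = 3, d = 8, heads = 2, enc = 1,
                       dec = 1, seed = 5, ...) {
  nichescope_model(model_config(n_genes = genes, n_cell_types = types,
                                embed_dim = d, n_heads = heads,
                                n_encoder_layers = enc, n_decoder_layers = dec,
                                mlp_ratio = 2, ...), seed = seed)
}

# independent ZINB NLL oracle: mixture pmf through stats::dnbinom
oracle_zinb_nll <- function(y, mu, theta, pi) {
  pmf <- (1 - pi) * stats::dnbinom(y, size = theta, mu = mu) + pi * (y == 0)
  -mean(log(pmf))
}

# all permutations of 1..n (exhaustive assignment oracle)
perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# brute-force O(N^2) box neighbors (Chebyshev half-width rule)
brute_force_neighbors <- function(table, half_width) {
  n <- nrow(table$obs)
  x <- table$obs$x; y <- table$obs$y; s <- table$obs$section_id
  lapply(seq_len(n), function(i) {
    keep <- which(s == s[i] & abs(x - x[i]) <= half_width &
                    abs(y - y[i]) <= half_width)
    sort(setdiff(keep, i))
  })
}

# brute-force same-section kNN label agreement
brute_force_homogeneity <- function(table, lab, k) {
  n <- nrow(table$obs)
  x <- table$obs$x; y <- table$obs$y; s <- table$obs$section_id
  vapply(seq_len(n), function(i) {
    j <- setdiff(which(s == s[i]), i)
    d <- (x[j] - x[i])^2 + (y[j] - y[i])^2
    nb <- j[order(d)][seq_len(min(k, length(j)))]
    mean(lab[nb] == lab[i])
  }, numeric(1))
}

# hand-rolled NMI (arithmetic normalization) and ARI from the contingency
# table, used only as test oracles
oracle_nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n; pi. <- rowSums(pij); p.j <- colSums(pij)
  I <- sum(ifelse(pij > 0, pij * log(pij / outer(pi., p.j)), 0))
  H <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  2 * I / (H(pi.) + H(p.j))
}

oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  exp_ <- si * sj / choose(n, 2)
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
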