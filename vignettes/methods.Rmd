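---
title: "Methods: masked-cell neighborhood modeling and domain detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-cell neighborhood modeling and domain detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

nichescope discovers spatial domains — tissue regions with a shared local
cellular and molecular makeup — from single-cell-resolution spatial
transcriptomics without using any anatomical annotation. The premise is
self-supervision: if a representation of a cell's spatial neighborhood is
informative, it should predict the transcript counts of a cell held out
from that neighborhood.

Given per-cell coordinates $(x_i, y_i)$ in microns, a cell-type label
$c_i \in \{1,\dots,C\}$ and a count vector $x_i \in \mathbb{N}^{g}$, the
neighborhood of a *reference cell* $i$ is every other cell of the same
tissue section inside an axis-aligned box centered on $i$:
$\max(|x_i-x_j|, |y_i-y_j|) \le w/2$ for box width $w$ (85 µm for
MERFISH-scale data, 50 µm for denser Slide-seqV2-style data). Working per
section is deliberate: sections are physically separate tissue, so a
neighborhood must never span two of them.

Each neighbor becomes a token: a two-layer GELU perceptron maps its
$\log(1+\text{counts})$ to half the embedding dimension, a learned
embedding table maps its type to the other half, and the two are
concatenated (384 dims at full scale; the expression/type split is
half/half). One learned *register token* per neighborhood accumulates
global context. Tokens pass through pre-norm transformer encoder layers
whose self-attention is restricted to the neighborhood (block-diagonal
attention), and a learned-query multi-head attention pooling collapses
them into a single neighborhood vector. The reference cell's own token is
never an input — its expression is what the model must predict.

Decoding is a two-token transformer: the neighborhood vector and a
type-specific mask token for the reference cell attend only to each
other; linear heads on the mask token then emit the parameters of a
zero-inflated negative binomial (ZINB) over the reference cell's counts:
a mean simplex over genes (softmax), a per-cell positive scale
(softplus), per-gene dispersions (softplus) and per-gene zero-inflation
logits. The per-cell loss is the mean per-gene ZINB negative
log-likelihood of the raw counts, with mean $\mu = \text{scale} \times
\text{simplex}$.

Two parameterization decisions deserve note. First, the four heads are
reconciled by interpreting "scale" as a library-size factor multiplying a
normalized expression profile; that is the standard count-model
decomposition and makes the mean head scale-free. Second, the likelihood
is implemented as ZINB with the plain negative binomial recovered exactly
at $\pi = 0$ (the `zero_inflated` flag selects between them); at
$y = 0$ the two mixture branches are combined in log space, so the loss
is stable for any dispersion.

## Training

ADAM with decoupled weight decay (applied to weights only — never to
norms, embeddings or biases), linear warmup to the peak learning rate
followed by continuous inverse-square-root decay:
$\eta(t) = \eta_{\max}\min(t/t_w, \sqrt{t_w/t})$, continuous at
$t = t_w$. Full-scale defaults: 40 epochs, effective batch 256 reference
cells per step, $t_w = 500$, $\eta_{\max} = 10^{-3}$, weight decay
$5\times10^{-5}$ (not warmed up). The exact offset/normalization of the
inverse-sqrt decay is a free choice; the $\min$ form above is used
because it is the simplest schedule that is continuous and peaks exactly
at the warmup boundary. ADAM moments are $(0.9, 0.999)$ with
$\epsilon = 10^{-8}$ — conventional values, recorded in the config.

Before the first step the output heads are calibrated from the training
split: the mean-head bias starts at the global log gene proportions and
the scale bias at the (inverse-softplus of the) median depth. Training
therefore starts at the dataset-mean predictor and spends its budget
learning type and context effects rather than rediscovering the library
size; this matters most in short desk-scale runs.

Everything is seeded: the split, the per-epoch shuffles, and weight init
are all reproducible, and a fixed seed reproduces loss traces bitwise.

## Domain detection

After training, the pooled neighborhood vector is extracted for every
cell (evaluation mode, batch-size independent) and all sections are
clustered jointly with k-means — cross-section concatenation is what
turns per-section parcels into organ-level domains. The k-means is
written for scale: k-means|| seeding with oversampling factor 3, best of
`n_init = 3` starts by inertia, `max_iter = 1000`, optional minibatch
assignment/update with $O(\text{batch}\cdot d + k\cdot d)$ memory, and an
inertia-monotonicity assertion every Lloyd iteration. Empty clusters are
re-seeded from the farthest point; convergence is a relative inertia
change below $10^{-6}$. Both policies are unstated in the sources this
design follows, so they are explicit config here.

An optional pre-clustering Gaussian smoothing operates directly on the
point cloud (kernel regression over same-section cells, truncated at
3σ by default): this follows the per-cell nature of the embeddings
rather than rasterizing to a grid. The default σ of 12.01 µm is the
operative value even though it is inconsistent with the nominal 40 µm
full-width-at-half-maximum it is usually quoted with (40 µm FWHM implies
σ ≈ 17 µm); both are settable, and the printed σ wins by default.

**Choosing k.** For each k on a grid, clustering is repeated (20
replicates by default) with different seeds and the instability is the
mean over unordered replicate pairs of an Amari-type dissimilarity
between centroid sets: with $C$ the $K \times K$ Pearson correlation
matrix between the centroids of $D$ and $D'$,
$$\mathrm{diss}(D, D') = \frac{1}{2K}\Big(2K - \sum_{k}\max_j C_{kj} -
\sum_{j}\max_k C_{kj}\Big),$$
which is zero iff the two solutions match up to permutation and is
bounded by 2. The mean-inertia and mean-instability curves are min-max
normalized (so both are scale-free — the normalization itself is a
design choice), averaged, and the selected k is the grid point where the
averaged curve's central-difference second derivative first changes
sign; a strictly convex curve yields `NA` with a warning rather than a
fabricated answer.

## Evaluation metrics

* **Spatial homogeneity** — per cell, the fraction of its 100 nearest
  same-section spatial neighbors sharing its domain label; averaged over
  the dataset and within domains.
* **Discreteness** — a method domain is "discrete" when its mean
  homogeneity reaches the 20th percentile of a reference parcellation's
  per-domain values.
* **Composition matching** — domains are summarized as row-stochastic
  domain-by-type composition matrices and matched across parcellations
  by Pearson correlation, either non-exclusively (best match per row) or
  one-to-one via linear sum assignment (Jonker–Volgenant, written
  in-package and tested against exhaustive permutation search).
* **NMI / ARI** — standard agreement measures; NMI uses the
  arithmetic-mean entropy normalization.
* **Linear probing** — ordinary least squares (minimum-norm via SVD when
  rank-deficient) from embeddings to coordinates, reporting both median
  and mean per-cell Euclidean error (the two conventions coexist in the
  literature, so both are emitted); multinomial logistic regression for
  donor identity with per-donor accuracy.
* **Spatial contribution** — per cell type, the gain in per-cell Pearson
  correlation of predicted vs observed counts over a dataset-mean
  baseline predictor.
* **Markers** — gene g marks domain d when
  $\log_2\frac{\bar{x}_{g,d} + 1}{\bar{x}_{g,\neg d} + 1} \ge 1$; the
  pseudocount of 1 on mean counts is this package's choice.
* **Cross-animal consistency** — a domain is present in an animal when
  at least `min_cells = 10` of its cells carry the label (the threshold
  is exposed because no canonical value exists); the headline is the
  fraction of domains present in every animal.

All metrics are invariant to domain relabeling.

## The synthetic generator

Real multi-million-cell atlases are out of reach for routine testing, so
the generator builds tissue with the structural assumptions the method
relies on: spatially contiguous domains (horizontal bands by default,
400 µm thick — cortical-layer scale; Voronoi and block geometries are
alternatives), domain-specific cell-type composition (one Dirichlet draw
per domain, concentration 0.5 so compositions are distinct), and
ZINB counts (gamma–Poisson with Bernoulli zeroing at rate 0.05,
per-gene dispersion log-uniform in [0.5, 10]) whose log-mean adds a
domain effect (sd 1.0) to a type-specific base profile, scaled by a
gamma-distributed per-cell depth with mean 250. The default density
(~4.4×10⁻³ cells/µm²; 2 sections × 2,500 cells on 285 × 2000 µm
sections) puts ≈30 cells in an 85 µm box, matching a MERFISH-like
cellular density. The band thickness is chosen so that ground-truth
labels are spatially homogeneous at the 100-neighbor scale the
homogeneity metric uses (mean kNN radius ≈85 µm ⇒ expected boundary
impurity ≈0.42·R/H ≈ 0.09).

What the generator does *not* emulate: real anatomy (curved, nested,
bilaterally symmetric structures), spatially graded rather than
categorical composition changes, segmentation errors, probe-panel
biases, or cell-type hierarchies. Passing the end-to-end tests therefore
demonstrates that the machinery — graph construction, likelihood,
optimization, pooling, clustering, metrics — works and that the method
recovers planted spatial signal; it does not by itself certify
performance on real atlases.

A multi-animal mode reuses the same geometry and composition parameters
across animals with independent sampling and an optional per-animal
depth factor, supporting the cross-animal consistency and donor-probing
analyses.

## Numerical choices and degenerate inputs

* Box membership is Chebyshev distance against the half-width, boundary
  inclusive; "box width" is read as the full side length by default,
  with a `width_convention = "half"` switch because the sources are
  ambiguous between the two readings.
* Dispersion and scale carry softplus floors of $10^{-4}$ and the mean
  simplex a floor of $10^{-10}$, keeping the likelihood finite for any
  head output.
* A neighborhood with zero neighbors is valid: the register token alone
  is pooled.
* Truncation ties in `max_neighbors` break by cell index, making the
  graph deterministic.
* Batching invariance holds to machine precision (about one ulp, not
  bitwise): BLAS matrix products use shape-dependent blocking, so the
  same row computed in different batch shapes can differ in the last
  bit. Tests assert invariance at $10^{-12}$ relative tolerance.
* The Amari dissimilarity refuses constant centroids (undefined Pearson
  correlation) with an error naming the centroid, rather than returning
  NaN.
* QC order: gene filters (mitochondrial names, then >10% prevalence) are
  applied before per-section depth percentiles are computed, matching
  the order the filters are usually described in; the depth cutoff is
  inclusive.

## Problem sizes used by the test suite

The suite and the acceptance script run the full pipeline at the
generator's default scale: 5,000 cells, 60 genes, a 64-dimensional model
with 2 encoder and 2 decoder layers, 5 epochs at batch 64 with warmup 30
and peak rate 2×10⁻³ — warmup and batch are scaled with the step budget
(≈390 steps) in the same proportion a full-scale run uses, and the
architecture is the full-scale design at reduced width/depth. Oracle
tests (brute-force neighborhoods, exhaustive assignment, dense kernel
smoothing, finite-difference gradients) run on 50–500-cell instances
where exact reference computation is feasible.

## Known limitations

* Training is CPU-bound R; full-scale atlases (10⁶–10⁷ cells, 384-dim,
  4+4 layers) are out of scope for this implementation, which targets
  method-development and desk-scale validation.
* The HDF5 single-cell container is not read directly; convert to MTX +
  metadata or tabular/Parquet first.
* No registration to a common coordinate framework is performed;
  registered coordinates, when present, are consumed as plain columns by
  the linear probe.
* Approximate nearest neighbors are not used; the homogeneity metric is
  exact and therefore quadratic per section, which is fine up to ~10⁴
  cells per section.
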