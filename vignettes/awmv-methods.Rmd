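---
title: "Adaptively weighted multi-view NMF for paired scRNA-seq and scATAC-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptively weighted multi-view NMF for paired scRNA-seq and scATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Paired single-cell multiome experiments measure gene expression (scRNA-seq)
and chromatin accessibility (scATAC-seq) in the same cells. The two assays
carry complementary but unequally noisy information, and a subset of their
features is biologically linked: accessibility summarized at a gene's
transcription start site (the *gene activity score*) is positively
associated with that gene's expression. This package integrates the two
assays through a joint non-negative matrix factorization of four views
built from the data:

* `rna_linked` — expression of genes that also have a gene activity score;
* `atac_linked` — the gene activity scores of the same genes, in the same
  order;
* `rna_unlinked` — highly variable genes outside the linked panel;
* `atac_unlinked` — distal/unassigned peaks.

Each view $X_v \ge 0$ (features $\times$ cells) is factorized as
$X_v \approx W_v H_v^{\mathsf T}$ with $W_v \ge 0$ (features $\times K$)
and $H_v \ge 0$ (cells $\times K$). The fitted criterion is

$$
\sum_{v}\Big[\omega_v\,\lVert X_v - W_v H_v^{\mathsf T}\rVert_F^2
 + \lambda_v\,\lVert H_v Q_v - H^*\rVert_F^2\Big]
 + \beta\,\lVert W_{\text{rna,linked}} - W_{\text{atac,linked}}\rVert_F^2
 + \gamma \sum_v \omega_v \ln \omega_v ,
\qquad \textstyle\sum_v \omega_v = 1,
$$

with four coupled ingredients:

1. **Adaptive view weights** $\omega_v$ on the probability simplex. Given
   the current reconstruction errors $e_v$, the optimal weights have the
   closed form $\omega_v \propto \exp(-e_v/\gamma)$ — a softmax that gives
   better-reconstructed (more informative) views larger weight, with
   bandwidth $\gamma$ controlling how peaked the weighting is. The entropy
   penalty $\gamma\sum\omega\ln\omega$ is what makes this solution finite
   and smooth; without it the best view would take all the weight.
2. **A consensus cell representation** $H^*$ toward which every scaled
   coefficient matrix $H_v Q_v$ is pulled. $Q_v =
   \mathrm{Diag}(\text{colSums}(W_v))$ absorbs the diagonal rescaling
   ambiguity of the factorization ($W D^{-1}, H D$ gives the same product
   but $H Q$ is invariant), so coefficient matrices from views with very
   different feature counts become comparable. $H^*$ has the closed-form
   solution $\sum_v \lambda_v H_v Q_v / \sum_v \lambda_v$ and is the
   low-dimensional representation used for clustering.
3. **A linked-basis constraint** $\beta\lVert W_{\text{rna,linked}} -
   W_{\text{atac,linked}}\rVert_F^2$. The two linked views index the same
   genes, and the constraint encodes the biological expectation that a
   factor's gene-expression signature and gene-activity signature agree.
4. **Multiplicative updates** for all $W_v$ and $H_v$, of the familiar
   numerator/denominator form, which preserve non-negativity and zeros.

## Fitting, defaults, and why

`awmv()` fits the model. The defaults follow the scheme below; each is a
single number a user can override.

* **Initialization.** Every view is factorized independently
  (`nmf_single()`, 200 multiplicative sweeps) from `runif(0,1)` entries
  scaled by `sqrt(mean(X)/K)`, so the initial product matches the data
  scale. All randomness flows from one integer `seed` (view $i$ uses
  `seed + i - 1`), and fits are bitwise reproducible.
* **$\lambda = 0.01$** for every view: the consensus pull is deliberately
  soft relative to reconstruction. One scalar is used for all views; a
  per-view vector is accepted.
* **$\beta$** defaults to the ratio of the (uniformly weighted) total
  initial reconstruction error to the initial squared distance between the
  linked bases, which puts the coupling term on the same scale as the
  reconstruction terms at the start of the fit (`default_beta()`).
* **$\gamma$** defaults to $\max_v |e_v / \ln \tilde\omega_v|$ at
  initialization with uniform $\tilde\omega_v = 1/V$ (`default_gamma()`),
  i.e. $\max_v e_v / \ln V$. With this calibration the exponent
  $e_v/\gamma$ stays in $[0, \ln V]$, so no view's weight can collapse
  toward zero purely because the objective scale is small.
* **$K = 20$** factors by default, matching common practice for multiome
  data of a few thousand cells; for simulated data with a known number of
  groups we fit $K$ equal to that number.
* **Update order** within one cycle: all $W_v$, then all $H_v$, then the
  closed-form $\omega$, then the closed-form $H^*$. The two exact solves
  are refreshed last so they are consistent with the factors that end the
  cycle.

### Stopping rule

Iteration stops when the objective decrease between adjacent cycles falls
below `tol * sum_v ||X_v||_F^2` with `tol = 1e-4`. The decrement is
measured *per unit of total squared data mass* rather than absolutely,
for two reasons. First, the preprocessing normalizes every view to total
mass one, which makes the objective's absolute scale shrink with matrix
size — a fixed absolute threshold would stop a large problem immediately
and let a small one run forever. Second, the objective itself is not a
safe relative scale because its entropy term is negative and the total can
cross zero. Under the scaled rule the bundled synthetic fixtures converge
in roughly 40–110 cycles, consistent with the tens-of-iterations behavior
expected of multiplicative multi-view NMF. The plain absolute rule is
available as `stop_rule = "absolute"`, and `rel_tol` switches to a
relative-to-objective criterion.

### Numerical details

* Every multiplicative-update denominator carries a guard
  $\varepsilon = 10^{-12}$; the printed rules are undefined at zero
  denominators, and the guard preserves fixed points to numerical
  precision while keeping exact zeros exact.
* A zero column of some $W_v$ makes the corresponding $Q_v$ entry zero;
  that factor simply contributes nothing to the consensus instead of
  raising an error, so degenerate factors are inert.
* The $W$ and $H$ iterates are *not* rescaled by $Q_v$ between updates.
  The consensus terms are invariant to the diagonal rescaling, but the
  linked-basis term is not, so renormalizing would silently change the
  objective being minimized. Monotonicity of the objective trace without
  renormalization is verified property-style in the test suite (no
  increase beyond $10^{-8}$ relative, on dozens of random instances over
  forced long runs).
* The coefficient update's consensus terms use $H^*$ and $H$ directly
  (not $Q$-scaled), mirroring the closed-form derivation the update rules
  come from; the basis update carries the $Q$-bearing terms. The combined
  cycle is what the monotonicity tests exercise.
* With a single view the model reduces exactly — elementwise to
  $10^{-12}$ over 50 sweeps, by test — to classical multiplicative NMF
  when $\lambda = 0$, $\beta = 0$, $\omega \equiv 1$.

### Ablations

Three reduced variants used for comparison are built in:
`link_enabled = FALSE` removes the linked-basis term;
`fixed_weights = "uniform"` freezes $\omega$ at $1/V$ (the entropy term
then only shifts the objective by a constant); `drop_view =
"atac_linked"` fits the remaining three views. A single-view fit is the
plain-NMF baseline.

## Preprocessing

`build_views()` constructs the four views from a gene-by-cell count
matrix, a peak-by-cell count matrix and a gene annotation.

* **Gene activity** (`gene_activity()`): each gene's accessibility is the
  distance-weighted sum of peak counts near its TSS, with weight
  $\exp(-d/5000)$ for peak-midpoint-to-TSS distance $d \le 100$ kb. The
  exponential kernel with a 5 kb length scale and 100 kb window is the
  convention of distance-weighted gene scoring in the single-cell ATAC
  literature; both numbers are arguments. Coordinates are BED-style
  0-based half-open, the TSS is the 5' gene end (strand-aware), and peaks
  on chromosomes absent from the annotation are an error (they usually
  indicate a naming mismatch such as `chr1` vs `1`).
* **Highly variable genes** (`select_hvg()`): genes are ranked by
  variance standardized against a loess mean–variance trend
  (`log10` variance on `log10` mean, span 0.3), with standardized values
  clipped at $\sqrt n$ — the variance-stabilizing selection popularized by
  the major single-cell toolkits, reimplemented deterministically. Ties
  break by feature identifier; selection is invariant to cell order. On
  panels too small to fit a trend (< 30 variable genes) the statistic
  falls back to plain dispersion (variance/mean).
* **Panel assembly**: the linked panel is the top `n_linked = 2000` HVGs
  selected on RNA among genes that have a (nonzero) activity profile; the
  unlinked RNA panel is the top `n_unlinked_rna = 2000` HVGs among the
  remaining genes; the unlinked ATAC panel is the `n_unlinked_atac =
  5000` peaks with the largest total raw count. HVG selection runs on raw
  counts; RNA-derived views are then `log1p`-transformed (activity is not,
  by default — the transform targets the heavy right tail of expression
  counts; `log_activity = TRUE` is available); finally every view is
  divided by its grand total (`normalize_view()`), so views of very
  different sizes enter the objective on one scale.

## Clustering and evaluation

`louvain_cluster()` clusters cells from $H^*$: exact k-nearest-neighbor
graph (Euclidean, `knn_k = 20`, each cell in its own neighborhood),
shared-nearest-neighbor Jaccard edge weights pruned below $1/15$, Louvain
modularity optimization. Rows are used raw by default (`l2_normalize`
available). When a target number of clusters is requested — the usual
situation when matching an external annotation — the modularity resolution
is bisected on $[0.01, 10]$, relying on the empirically monotone
resolution–cluster-count relationship (itself checked on fixtures in the
tests); if the target is unreachable the closest partition is returned
with a warning.

Evaluation follows standard definitions: `nmi()` divides mutual
information by the geometric mean of the label entropies (natural logs,
$0\log 0 = 0$, zero-entropy cases return 0); `ari()` is the
chance-corrected pair-counting index computed from the contingency table,
returning 1 in the degenerate all-pairs-agree cases. `ragi()` scores a
clustering without truth labels: for each gene the Gini index of its
per-cluster mean expression — the pairwise mean-absolute-difference form
$\sum_{ij}|x_i - x_j| / (2m^2\bar x)$ over $m$ cluster means, 0 by
convention for a single cluster or an all-zero gene — and then the mean
Gini of user-supplied marker genes minus the mean Gini of housekeeping
genes. Markers should concentrate in few clusters (high Gini) and
housekeeping genes should not (low Gini), so higher is better. The Gini
is computed over cluster *means*, making it invariant to cluster sizes
and to expression scale; we feed it `log1p` expression by default, though
any non-negative representation works. Gene lists are inputs; curated
marker/housekeeping databases are outside the package's scope.

## The synthetic data generator

`simulate_multiview()` exists so every stage is testable without
multi-gigabyte downloads. It emulates exactly the structure the model
assumes: one planted partition of cells shared by four non-negative
views; linked views sharing a feature panel with bases mixed as
`link_corr * W_rna + (1 - link_corr) * W_indep`; ATAC views sparser and
noisier than RNA views (default dropout 0.6 vs 0.3). Cells load 0.8–1.2
on their own cluster's factor and at most `h_leak = 0.05` elsewhere;
feature blocks load `signal * U(0.5, 1.5)` in block. Views are
$W H^{\mathsf T}$ plus truncated Gaussian noise (`noise_sd = 0.1`)
followed by Bernoulli dropout. The first `n_marker` linked features load
on exactly one factor (planted markers) and the next `n_housekeeping`
load equally on all factors. Defaults: 300 cells, 3 equiprobable
clusters, 100/100/100/200 features.

What the generator does *not* emulate: count distributions (the model
consumes normalized continuous matrices, so negative-binomial realism
adds nothing to these tests), batch effects, doublets, realistic genomic
coordinates, or cluster-specific sequencing depth. Passing tests
therefore demonstrate correctness of the algorithm and its claimed
properties under the assumed structure — not performance on any real
tissue.

Two test-design notes. The planted-marker check of RAGI uses the clean
construction (`h_leak = 0`, `noise_sd = 0`) because its analytic
expectation (Gini $= 1 - 1/k$ for a marker expressed in one of $k$
clusters) holds exactly only when markers are silent outside their
cluster; under the noisy defaults, off-block leakage and the
truncation bias of the additive noise deflate marker Gini to roughly
0.5–0.6, which the default-pipeline numbers reflect. And the
property-style monotonicity tests disable the stopping rule to force long
traces, since a converged two-step trace would test little.

## Problem sizes and limitations

The test suite and the acceptance script run entirely on simulated data
at deliberate desk scale: 50 instances of 100 cells ($50/50/50/120$
features, $K=5$) for monotonicity, 300-cell datasets for pipeline
recovery and ablation comparisons (10 seeds), $10^4$ random simplex
points per draw for the weight-optimality check. A full fit at these
sizes takes a fraction of a second to a few seconds.

Known limitations: the factorization is non-convex, and small problems
(tens of cells, tens of features) can land in initialization-dependent
local optima — use several seeds if results look unstable; the bisection
search assumes cluster count grows with resolution, which Louvain does
not strictly guarantee; `K` selection is left to the user (no automatic
model-order choice); and the 10x HDF5 container is not read directly —
export to the MTX convention first.
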