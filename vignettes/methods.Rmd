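---
title: "Detecting spatially variable genes with cluster-covariate NB models"
author: "spaceLRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatially variable genes with cluster-covariate NB models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaceLRT)
```

## The model

Spatially resolved transcriptomics (SRT) measures gene expression at
spatially indexed locations ("spots"). A gene is *spatially variable*
(an SVG) when its mean abundance differs across tissue locations. spaceLRT
encodes space through pre-computed spatial clusters — manual annotations or
the output of a spatially resolved clustering tool — and asks, per gene,
whether mean expression differs between those clusters.

For gene $g$ in spot $i$ belonging to spatial cluster $c$, counts are
modeled as negative binomial,

$$x_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi_g), \qquad
  \log \mu_{gi} = \log M_i + \beta_{gc},$$

with variance $\mu(1+\mu\phi)$. $M_i$ is the *effective library size* of
spot $i$ — its total count times its TMM normalization factor — and enters
as a fixed offset, so the $\beta_{gc}$ are normalized log abundances per
cluster. The global SVG test is the likelihood-ratio test (LRT) of

$$H_0:\ \beta_{g1} = \dots = \beta_{gC}$$

against an unrestricted alternative, with $C-1$ degrees of freedom; twice
the log-likelihood difference is referred to a $\chi^2$ distribution.
Benjamini–Hochberg adjustment is applied across genes.

With biological replicates the mean gains a sample term,
$\log \mu_{gi} = \log M_i + \beta_{gc} + \gamma_{gj}$, with
$\gamma_{g1} = 0$ for identifiability; the cluster coefficients are tested
jointly while the sample terms stay in both models, so replicate-level
depth and composition differences are absorbed rather than mistaken for
spatial signal. In design-matrix terms the single-sample model uses
cluster-means coding ($P = C$) and the multi-sample model an intercept
plus $C-1$ cluster and $J-1$ sample dummies ($P = 1 + (C-1) + (J-1)$);
the tested set always has $C-1$ degrees of freedom.

The *individual-cluster* test replaces the $C$-level factor by a
one-vs-rest indicator for each cluster in turn (1 df per test), still on
spot-level counts rather than pseudo-bulk aggregates. The sign of the
indicator coefficient reports whether the cluster is more (`high`) or less
(`low`) abundant than the remaining tissue, and each gene's *key cluster*
is the one with the smallest per-cluster p-value (ties: larger absolute
coefficient, then cluster order). BH families are per cluster: each
cluster's gene-wise p-value vector is adjusted on its own, since the
per-cluster tests answer distinct scientific questions.

## Estimation choices

**Fitting.** Coefficients are estimated by iteratively reweighted least
squares (IRLS) with the log link, offsets, and up to ten step-halvings per
iteration; convergence is a relative deviance change below $10^{-8}$
(at most 50 iterations). Starting values come from continuity-shimmed log
counts ($\log(y + 1/6)$) regressed on the design. For partition designs
(cluster means, one-vs-rest, intercept-only) the score equations decouple
per cluster, and the package solves them by a vectorized per-cluster
Newton iteration across all genes simultaneously; the generic IRLS path
handles multi-sample designs. The two paths agree to numerical precision
and are cross-checked in the test suite, as is agreement of the IRLS
optimum with a derivative-free optimizer and with the closed-form Poisson
MLE at $\phi = 0$ (the engine degrades continuously to a Poisson GLM).
All-zero genes are fitted at the mean floor, flagged, excluded from
dispersion pooling, and reported with `NA` p-values after BH (ranked
last).

**Dispersion.** Each gene's $\phi_g$ is estimated from the Cox–Reid
adjusted profile likelihood (APL) — the profile log-likelihood minus
$\tfrac12 \log\det(X^\top W X)$, which corrects for estimating the mean
coefficients — evaluated on a 21-point log-spaced grid on
$[10^{-4}, 10]$. Grid maxima are refined by golden-section/parabolic
search (`stats::optimize`) on a cubic-spline interpolant of the APL over
log dispersion, which avoids re-fitting the GLM at off-grid points. Three
estimators are produced: a *common* dispersion maximizing the summed APL;
a *trended* dispersion from a lowess fit (span 0.3) of per-gene APL
maximizers against mean log2-CPM (falling back to the common value below
10 usable genes); and *tagwise* dispersions maximizing

$$\mathrm{APL}_g(\log\phi)\; -\; \frac{\texttt{prior\_df}}{4}
  (\log\phi - \log\mathrm{trend}_g)^2,$$

a Gaussian prior on the log dispersion centered at the trend with
precision `prior_df / 2`. `prior_df` defaults to 10: enough pooling to
stabilize sparse genes, little enough that with hundreds of spots the
data dominate. As `prior_df` grows the tagwise values collapse onto the
trend; as it vanishes they revert to the per-gene maximizers (both limits
are tested). The full and reduced fits of every LRT share the same
tagwise $\phi_g$, so the test isolates mean differences.

The fast individual-cluster mode (the default) recycles the tagwise
dispersions estimated once under the global cluster design; the full mode
re-estimates them under each one-vs-rest design. On the package's
benchmarks the two agree on the key cluster for essentially all true SVGs
(measured by the acceptance script), at a $C$-fold difference in
dispersion-estimation work.

**Normalization.** TMM factors follow the published trimmed mean of
M-values scheme: the reference spot is the one whose upper-quartile count
fraction (over its expressed genes) is closest to the mean such fraction;
gene-wise log ratios against the reference are doubly trimmed (30% of
M-values and 5% of A-values from each tail, rank-based) and averaged with
inverse-variance precision weights; genes with a zero in either spot are
excluded; factors are rescaled to geometric mean one. A pure library-size
mode (`normalize = "libsize"`) is available. Default filters — genes with
at least 20 total counts expressed in at least 10 spots, spots with at
least 10 counts — mirror common SRT practice and are fully configurable;
gene filtering precedes spot filtering.

## The simulators

`simulate_synthetic()` generates a square grid of spots cut into
vertical-band clusters, log-normal baseline abundances
(`baseline_meanlog = 0`, `baseline_sdlog = 1`: median one count per spot
per gene at average depth, the scale of reasonably expressed genes after
standard filtering), per-spot depths uniform on `lib_size_range` (only
their ratios matter), NB noise with dispersion `phi = 0.4` by default
(typical of cortex-scale Visium data), and a multiplicative $2^{\pm
\text{log2fc}}$ effect for SVG genes inside their key region. Strong and
weak effect tiers default to log2 fold changes of 1.0 and 0.5, split
50/50 among SVGs.

Five spatial profiles are supported. The geometric ones (`bottom_right`,
`circular`) and `annotations` share one key region, with half of the SVGs
high and half low inside it. The `mixture` and `inverted_mixture`
profiles are *mixtures of cluster-based patterns*: every SVG gene is
assigned its own key cluster, uniformly over cluster labels, in which it
is respectively more or less abundant than elsewhere. This per-gene
structure is what makes key-cluster identification a non-trivial task,
and it spreads differential abundance across regions so that
normalization stays identifiable (see the limitations below). Pinning
`params$cluster` in `make_mask()` recovers the single-small-cluster
variant.

`simulate_from_anchor()` instead rearranges real (or otherwise supplied)
counts: each SVG's observed counts are rank-split so the largest (or
smallest) values land in its key region, uniformly shuffled within
region, while uniform genes are permuted across the whole tissue. Every
gene's count multiset — hence its marginal distribution, total, and
dispersion — is preserved exactly. `simulate_multisample()` applies this
per sample with one shared truth, so SVG identities, directions and key
clusters are consistent across replicates while placements are
independent. All generators take explicit seeds and restore the caller's
RNG state.

What the simulations do *not* emulate: cell-type mixture within spots,
spatial autocorrelation within clusters, platform artifacts (spot
swapping, segmentation noise), or imperfect clustering — the last can be
approximated by `perturb_clusters()`, which relabels a chosen fraction of
spots. Passing benchmarks on these simulations therefore demonstrates
correctness of the inferential machinery under the stated model, not
robustness to everything real tissue does.

## Numerical and degenerate-input conventions

LRT statistics are clipped at zero; a statistic below $-10^{-6}$ flags
non-convergence and yields `NA`. Fitted means are floored at $10^{-8}$
(and capped at $10^{10}$) to keep likelihoods finite; Cox–Reid weight
sums are floored at $10^{-10}$ before taking logs. One cluster is an
error for the global test, and fewer than three clusters is an error for
the cluster test (with two clusters it would coincide with the global
test, which the error message points to). Cluster levels are ordered by
first appearance and fix coefficient order downstream; a cluster
confounded with sample membership produces a rank-deficiency error naming
the offending clusters. Spots with missing cluster labels are dropped
with a warning. Results are invariant to row/column permutations of the
input up to floating-point summation order (about $10^{-7}$ on LRT
statistics).

## Benchmark scales

The test suite and the acceptance script run, on one CPU in a few
minutes, at these problem sizes: null calibration with 1,000 genes by 500
spots (3 clusters); FDR/power on the mixture benchmark with 1,000 genes
by 1,000 spots (5 clusters, strong tier); multi-sample comparisons with 3
replicates of 300 spots and 400 genes (weak tier); key-cluster accuracy
on 600 genes by 1,000 spots for both mixture (strong) and inverted
mixture (weak). These sizes give binomial standard errors of 1–2% on the
reported rates while keeping a full run under a minute.

## Known limitations

* **Normalization under extreme, one-sided differential abundance.** TMM
  factors are computed between individual spots, whose counts are sparse.
  When a large fraction of genes (approaching the trim fraction) is
  differentially abundant in the *same* direction in the same region, and
  counts are low, zero-exclusion removes down-shifted genes asymmetrically
  and the trimmed mean is biased; spurious offsets then inflate the
  false discovery rate for *every* pipeline built on spot-level TMM (we
  verified the same inflation with an independent reference
  implementation). The mixture simulators avoid this regime by spreading
  key clusters across genes; analysts facing tissues where most genes
  shift one way in one region should interpret absolute FDR with care.
* **Clusters are taken as given.** Errors in the spatial clustering
  propagate into the covariate; the test cannot detect variability that
  the clustering does not delineate, and within-cluster spatial structure
  is invisible by construction.
* **Asymptotics.** $\chi^2$ p-values rely on large-sample theory; with
  very few spots per cluster or near-all-zero genes the calibration
  degrades (all-zero genes are excluded outright).
* **No quasi-likelihood variant.** The LRT uses estimated tagwise
  dispersions as fixed; uncertainty in $\phi_g$ is not propagated. The
  empirical-Bayes shrinkage mitigates, and the null-calibration benchmark
  verifies, that this does not materially distort type-I error at the
  tested scales.
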