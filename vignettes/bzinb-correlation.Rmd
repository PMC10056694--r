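---
title: "Model-based correlation and module identification for zero-inflated omics counts"
author: "bzinbcor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based correlation and module identification for zero-inflated omics counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzinbcor)
```

## The problem

Microbiome and metabolome count data contain many zeros: some biological
(a species genuinely absent from a sample), some technical (dropout — the
feature is present but unobserved). Pearson and Spearman correlations treat
all zeros as ordinary small values; under heavy zero inflation both estimators
are pulled toward zero, so networks and modules built from them understate the
underlying associations. This package estimates the association between two
count features from a joint model that separates the count process from the
zero masking.

## The model

The latent count pair follows a shared-component Poisson–Gamma mixture
(bivariate negative binomial, BNB). With independent
$R_0 \sim \Gamma(\alpha_0, \beta_1)$, $R_1 \sim \Gamma(\alpha_1, \beta_1)$,
$R_2 \sim \Gamma(\alpha_2, \beta_1)$ (scale parameterisation) and
$\delta = \beta_2/\beta_1$,

$$X_1 \mid R \sim \mathrm{Pois}(R_0 + R_1), \qquad
  X_2 \mid R \sim \mathrm{Pois}(\delta (R_0 + R_2)),$$

so that marginally $X_i \sim \mathrm{NB}(\alpha_0+\alpha_i,\, 1/(\beta_i+1))$
with mean $(\alpha_0+\alpha_i)\beta_i$. The shared component $R_0$ induces

$$\rho_{\mathrm{BNB}} =
  \frac{\alpha_0 \sqrt{\beta_1\beta_2}}
  {\sqrt{(\alpha_0+\alpha_1)(\alpha_0+\alpha_2)(\beta_1+1)(\beta_2+1)}}
  \in [0, 1).$$

Only non-negative association is expressible — correlation enters solely
through the shared Gamma component, and $\rho \le
\sqrt{\beta_1\beta_2/((\beta_1+1)(\beta_2+1))}$, which vanishes in the
Poisson limit $\beta \to 0$. Both facts matter for interpretation: negative
associations are estimated as near zero, and under-dispersed (sub-Poisson)
data cannot display model correlation at all.

The observed pair $(Y_1, Y_2)$ adds a four-category masking layer with
probabilities $\pi_1..\pi_4$ (both observed / only first / only second /
both masked to zero); these are probabilities of *zero inflation*, not of
observing a zero — the NB component produces zeros of its own. The headline
estimator $\rho_{\mathrm{BZINB}}$ fits all nine parameters and evaluates the
BNB formula on the count component, i.e. the association freed of masking.
The *naive* BZINB correlation — the Pearson correlation of the masked pair,
a closed form in all nine parameters — is also provided; it can be negative
(opposite-margin masking induces negative dependence) and is mainly useful
as a sampling-oracle cross-check.

## Fitting

The joint pmf is computed by a finite-sum decomposition: splitting each
count into its shared-component and idiosyncratic parts reduces
$P(X_1 = x_1, X_2 = x_2)$ to a double convolution of a closed-form bivariate
term with two NB pmfs, at most $(x_1+1)(x_2+1)$ log-space terms (C++).

Two fitting engines are provided, and which one a user gets matters:

* **`engine = "ml"`** (default for single pairs, `fitBnb()`/`fitBzinb()`):
  Nelder–Mead maximisation of the observed-data log-likelihood over
  log-transformed shapes/scales and log-ratio-transformed $\pi$, initialised
  at the moment solution, with deterministic restarts and a final
  simplex-restart polish. The accepted-evaluation log-likelihood trace is
  retained and non-decreasing, and the fit satisfies the ascent property
  (final log-likelihood dominates the initialisation). We cap evaluations at
  5000 (`maxIter = 1000` scaled) and use an absolute log-likelihood
  tolerance of `1e-6`. Fitted parameters are floored at `1e-8`.
* **`engine = "moment"`**: closed-form solution of the model's moment and
  zero-probability equations — per margin, the unmasking probability and NB
  parameters solve the mean/second-moment/zero-fraction system (one
  univariate root); the shared shape and $\pi_1$ then solve the
  cross-moment and joint-zero equations (one more root). No likelihood is
  evaluated; a fit costs well under a millisecond, which is what makes
  all-pairs matrices over hundreds of features practical
  (~80{,}000 pairwise fits). It is less efficient statistically than ML
  (roughly Pearson-level noise) and is the documented default inside
  `corrMatrix()` whenever more than `engineThreshold = 200` pairs are
  requested.

Degenerate pairs (a margin all zero or constant) return an explicit failure
status; downstream consumers (`corrMatrix()`, `toAffinity()`) record the
failure and treat the entry as missing/zero rather than inventing a number.

For model-based methods `corrMatrix()` rescales large-count features to a
common nonzero-part standard deviation of 30 (rounded) before ML fitting —
a cost device only; correlations are essentially scale-free. The scale is
set by the *nonzero* part deliberately: zero-inflated features have a total
sd dominated by the zero/nonzero gap, and scaling by that would quantize the
informative fluctuation away on rounding. The moment engine is scale-robust
and works on raw counts.

## Simulation designs

Two families of synthetic pairs reproduce the evaluation designs, with
presets shipped in `inst/extdata/scenarios.json` and validated at load time:

* **Zero-inflated lognormal pairs** (`met_sp_a..d`, `sp_sp_a..c`): $n = 300$
  bivariate normal log-counts with unit log-variance and target correlation,
  exponentiated and rounded. Metabolite margins lose values by a rank-based
  dropout rule, $p_i = (0.5 - \mathrm{rank}_i/n)\cdot 0.3 + p_{zero}$
  (smallest counts likeliest to vanish — low concentration), clamped to
  $[0,1]$; species margins have an exact number of uniformly chosen
  structural zeros. Note that for $p_{zero} < 0.15$ the rule goes negative
  for the largest counts, so the expected zero count is the sum of the
  clamped probabilities (≈ 31.1 at $p_{zero} = 0.1$, slightly above the
  unclamped $n\,p_{zero} - 0.15$).
* **BZINB pairs** (`bzinb_a..d`): the four masking designs
  $\pi = (0.75,0.15,0.05,0.05)$, $(0.1,0.2,0.1,0.6)$,
  $(0.2,0.6,0.05,0.15)$, $(0.2,0.05,0.6,0.15)$, whose expected masked-zero
  counts at $n=300$ are (30, 60), (210, 240), (60, 225), (225, 60). The
  shape/scale sets behind each target correlation are constructed, not
  tabulated: scales fixed per relationship kind (metabolite–species
  $\beta = (4, 2)$, species–species $(3, 3)$), total shape 2 per margin, and
  the shared shape solved from the closed form so that
  `rhoBnb(preset)` equals the target exactly. Counts then have single-digit
  means, which keeps likelihood evaluation cheap without affecting the
  masking structure under study.

`benchmarkEstimators()` runs the estimator comparison (Spearman, Pearson,
BNB, BZINB per replicate; mean/median per cell) reproducibly under one seed.
We run 100 replicates per cell in the acceptance checks — enough to order
the estimators stably; the mean BZINB estimate under heavy masking at true
$\rho = 0.5$ is markedly closer to the truth than Spearman's, which is
dragged toward zero by the tied zeros.

## The semi-parametric module experiment, honestly

`generateBaselineMatrix()` emulates a species-by-sample metagenomic matrix:
a two-component rank-abundance profile (about 4% dominant features around
$22\times$ the target matrix mean of 17,968, a bulk two orders of magnitude
lower), NB dispersion 0.5, and a zero probability that rises as the log-mean
falls. It reproduces the features real sparse count data show — a long
right tail, feature-wise excess zeros, a decreasing mean-versus-zeros trend
— but not compositionality, batch structure, or taxon-taxon interactions.

`craftClusterSignal()` plants ground-truth modules: features are permuted,
split into 10 clusters of 40, and each cluster's member features have their
nonzero counts replaced by $\mathrm{round}(0.9\,Y + 0.1\,R_k)$ with a
cluster-shared vector $R_k \sim \mathrm{Pois}(17{,}968)$ per sample; zeros
are preserved exactly.

A caution derived in development and worth stating plainly: a Poisson vector
with mean 17,968 has standard deviation 134, i.e. it is nearly constant in
relative terms. At weight 0.9 the injected between-feature covariance is
$(0.1)^2 \lambda \approx 180$ while nonzero means shift by
$0.1\lambda \approx 1797$, so quiet features become sub-Poisson (where the
model expresses no correlation) and loud features bury the signal in their
own variance; the model-expressible injected correlation is bounded by
about $(1-w)\lambda / ((1-w)\lambda + w\mu) \le 0.1$. At 180 samples the
per-pair estimate noise (~0.1–0.17) then puts 40-feature blocks below the
spectral detection threshold for *every* estimator we tried, Spearman
included. The end-to-end experiment therefore runs and is tested end to
end, but cluster recovery under these exact defaults is essentially at
chance, and the corresponding acceptance expectation is left unmet rather
than met by strengthening the signal. With a more variable shared vector or
a lower weight on the original counts the same pipeline recovers planted
modules exactly (see the block-recovery unit tests).

## Spectral clustering and evaluation

Affinities are clamped correlations: negatives to zero, diagonal zero,
missing entries zero with a warning, symmetry enforced by averaging.
`spectralCluster()` uses the symmetric normalised Laplacian embedding — the
$k$ leading eigenvectors of $D^{-1/2} A D^{-1/2}$, rows unit-normalised —
followed by seeded k-means with 20 restarts; zero-degree features are
re-assigned to the cluster with the nearest mean affinity row and reported.
`eigengapK()` is advisory (largest gap of the ascending Laplacian spectrum,
ties toward smaller $k$); the pipeline always accepts an explicit $k$.

`matchClusters()` implements two-stage matching: mutual-mode pairs are fixed
first (ties toward the lower cluster index), then the remaining clusters get
the bijection maximising pooled accuracy, computed by exact subset-DP
optimal assignment — identical in objective and result to exhaustive search
over bijections, but feasible for any remaining-cluster count up to 20.
Both reference-side and predicted-side per-cluster accuracies are reported,
since either denominator is defensible. `adjustedRandIndex()` is the
standard permutation-model closed form; `nestedDistanceCurve()` ranks
clusters by Frobenius distance between two correlation matrices and
re-evaluates the distance on cumulative nested sets.

## Networks and goodness of fit

`buildNetwork()` keeps the `ceiling(topFraction × eligible)` strongest
correlations (largest signed value; magnitude ranking behind a flag), with
all cutoff ties included for determinism. Group networks are thresholded
per group and merged with `both`/`groupA`/`groupB` edge tags. Exports:
Cytoscape SIF (with lossless attribute sidecars), GraphML via igraph, and
plain edge TSV; every text output carries `#` provenance headers (version,
configuration fingerprint, seed).

The marginal goodness-of-fit workflow fits zero-inflated Poisson / NB /
lognormal per feature — nonzero-part parameters by ML on the nonzero counts
(untruncated, a documented simplification), zero proportion empirical —
simulates replicates (zeros Binomial, lognormal draws rounded), and runs the
plain one-sample KS test of the nonzero counts against their own fitted
lognormal. Using estimated parameters without a Lilliefors-style correction
makes the test conservative, and count ties make it approximate; both
behaviours match the intended workflow and are asserted only at that level
(calibration ≥ 90% non-rejection on true lognormal data, clear power against
exponential-tailed data).

## Numerical choices and limitations

* pmf/likelihood in log space with log-Gamma tables; parameters floored at
  `1e-8`; likelihood cost scales with the number of *distinct* observed
  pairs, not $n$.
* All randomness flows through explicit seeds (`withr::with_seed`); restarts
  use fixed deterministic offsets so per-pair results are independent of
  execution order. Pairwise fits are embarrassingly parallel in principle;
  the implementation is sequential.
* Problem sizes in the test suite: sampling oracles use $10^6$ draws,
  recovery checks $n = 10{,}000$ with 2 replicates per cell, the benchmark
  100 replicates, and the module experiment the full 400×180 design over
  5 seeds.
* Only non-negative model correlations; covariate adjustment, Kendall/MI/
  copula comparators, and consensus or soft clustering are out of scope.
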