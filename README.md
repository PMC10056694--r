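# bzinbcor

Model-based correlation networks and module identification for zero-inflated
omics counts.

Microbiome and metabolome count data are riddled with zeros — biological
absences and technical dropouts alike. Ordinary Pearson and Spearman
correlations treat those zeros as small observations and are dragged toward
zero, so correlation networks and feature modules built from them understate
real associations. `bzinbcor` estimates the association between two count
features under the **bivariate zero-inflated negative binomial (BZINB)**
model and carries that estimator through the full workflow: pairwise
correlation matrices (within one omics layer or across two), spectral
clustering of correlation affinities into modules, thresholded network
construction with Cytoscape-compatible export, simulators for method
evaluation, and marginal goodness-of-fit diagnostics.

## The model in brief

The latent count pair is a shared-component Poisson–Gamma mixture: with
independent Gamma variables R0, R1, R2 (shapes α0, α1, α2, scale β1) and
δ = β2/β1,

    X1 | R ~ Pois(R0 + R1),   X2 | R ~ Pois(δ (R0 + R2)),

so each margin is negative binomial, NB(α0 + αi, 1/(βi + 1)), and the shared
component R0 induces the non-negative latent correlation

    ρ = α0 √(β1 β2) / √((α0+α1)(α0+α2)(β1+1)(β2+1)).

Observed pairs add a four-category masking layer π1..π4 (both observed /
only the first / only the second / neither). Fitting all nine parameters and
evaluating ρ on the count component gives the **model-based BZINB
correlation** — the association freed of zero masking — which is the
package's headline estimator. Two fitting engines are provided: numerical
maximum likelihood (default for single pairs) and a closed-form
moment/zero-probability solver fast enough for ~10^5 pairwise fits
(default inside `corrMatrix()` for large matrices).

## Worked example

Simulate one heavily masked pair with latent correlation 0.5 and recover it:

```r
library(bzinbcor)

params <- BzinbParams(BnbParams(1.37, 0.63, 0.63, 4, 2),
                      pi = c(0.1, 0.2, 0.1, 0.6))
params
#> BZINB parameters
#> BNB parameters
#>   alpha0 = 1.37, alpha1 = 0.63, alpha2 = 0.63
#>   beta1 = 4, beta2 = 2 (delta = 0.5)
#>   rhoBnb = 0.5003
#>   pi = (0.100, 0.200, 0.100, 0.600)

y <- rbzinb(300, params, seed = 1)
colSums(y == 0)                      # masking + NB zeros
#>  x1  x2
#> 226 246
spearmanCorr(y[, 1], y[, 2])         # rank correlation, crushed by the zeros
#> [1] 0.231

fit <- fitBzinb(y[, 1], y[, 2])
fit
#> BZINB fit (engine ml): status ok
#>   rho = 0.5902, logLik = -666.768, converged = TRUE, evals = 215
round(zeroInflation(fit@params), 3)
#>   pi1   pi2   pi3   pi4
#> 0.090 0.170 0.104 0.636
```

With three quarters of each margin masked, Spearman reports 0.23 where the
truth is 0.50; the model-based estimate (0.59 on this single draw, unbiased
across replicates) recovers it along with the masking probabilities.

From matrices to modules and networks:

```r
se  <- generateBaselineMatrix(seed = 1)          # 400 x 180 species counts
cm  <- corrMatrix(se, method = "bzinb")          # all-pairs, moment engine
sol <- spectralCluster(toAffinity(cm), k = 6, seed = 1)
net <- buildNetwork(cm, topFraction = 0.30)
exportNetwork(net, format = "graphml", path = "species.graphml")
```

A thin command-line wrapper (`inst/scripts/bzinbcor`) exposes the same
pipeline as subcommands: `simulate | fit | corr | benchmark | cluster |
network | gof`.

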