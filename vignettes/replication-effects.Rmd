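---
title: "Quantifying replication effects in metabarcoding diet analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replication effects in metabarcoding diet analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietrep)
```

## The problem

Metabarcoding diet studies record, for each sequenced PCR of each faecal
sample, which prey taxa were detected. Because extraction and PCR are noisy
and because an individual's samples vary in content, the diet descriptors a
study reports — richness, composition, and per-taxon frequency of occurrence
(FO) — depend on how many individuals, samples per individual, and PCRs per
sample were analysed. `dietrep` treats that dependence as the object of
study. The data model is a boolean incidence tensor
(individual × pellet × PCR × taxon) with a presence mask for ragged designs,
plus an optional pool block (individual × PCR × taxon) for samples pooled
before extraction. Read counts, when present, are used only by a per-PCR
relative-abundance filter (default 1%, the conventional haplotype-filter
threshold); detection is boolean everywhere downstream, because occurrence
— not read abundance — is the quantity these designs can estimate reliably.

## Diversity: rarefaction and Chao2

For one individual with `m` pellets (after PCR collapse) and incidence
counts `m_t`, the expected richness in `n` pellets drawn without replacement
has the closed hypergeometric form
`E[S(n)] = Σ_t [1 − C(m−m_t, n)/C(m, n)]`, which equals the exhaustive mean
over all `C(m, n)` subsets (the test suite verifies this identity exactly
for `m ≤ 6`). Chao2 uses the classic incidence form
`S_obs + ((m−1)/m) Q₁²/(2Q₂)`, falling back to the bias-corrected
`Q₁(Q₁−1)/(2(Q₂+1))` when `Q₂ = 0`. Because Chao2 of a subsample has no
simple closed form, the Chao2 accumulation curve is built by seeded
resampling (default 200 subsamples per point; at `n = m` the full-matrix
value is returned exactly). Curves are averaged across individuals with SE
= SD/√I; a single individual reports SE = 0 by convention.

Two PCR-collapse conventions are provided: `union` (a taxon is in a pellet
if any PCR detected it) and `single_random` (one seeded random PCR per
pellet — the convention used for the 320-unit analysis set in the
motivating design, and the pipeline default). The same selection machinery
applies to pools, including one random PCR per pool under `single_random`.

## Composition: nested PERMANOVA with RRPP

The PCR-level 0/1 unit × taxon matrix is partitioned with squared Euclidean
distance, equivalent to a linear model in data space; the test suite checks
the McArdle–Anderson identity against a Gower-centred distance-matrix
computation. Terms are fully nested — individuals, pellets within
individuals, PCRs within pellets — so the model is saturated: the deepest
term's SS *is* the residual SS, and the residual row has 0 df. Pseudo-F
under the default `next_nested` scheme tests each term against the next
term down (`F_ind = MS_ind/MS_pel`, `F_pel = MS_pel/MS_pcr`). Significance
uses the randomized residual permutation procedure: residuals of the
reduced model (all shallower terms) are permuted across units, and
`p = (1 + #{F* ≥ F})/(1 + B)` with ties counted as exceedances.

The deepest term deserves a caveat. With 0 residual df there is no
denominator for a PCR-term F, so its RRPP p is computed descriptively with
MS(PCR) as the statistic. Observed residuals are centred within pellets,
which makes the observed MS an upper bound over residual permutations — the
p-value is therefore degenerate at `1/(B+1)`. We report it because the
reference analyses print one, but it should be read as "the PCR level was
partitioned", not as evidence. This is a property of the saturated design,
not of the implementation.

## FO error: pellet subsampling

For each pellet count `n`, each Monte-Carlo replicate draws `n` pellets
*with replacement* from every individual (with replacement even near
`n = m`, exactly as the procedure is defined; a without-replacement variant
would be natural but is not the stated procedure), marks individuals
positive per taxon, and re-estimates FO. One draw per individual and
replicate is shared across taxa, as in the original procedure; per-taxon
marginals follow the exact product-binomial law
`E[FÔ_n] = (1/I) Σ_i [1 − (1 − m_it/m)^n]`, the oracle the acceptance tests
compare against at R = 10,000 replicates. The default error kind is
*relative*, `e_n = (FO_m − mean FÔ_n)/FO_m`: reported pool "error rates"
above 80% are only interpretable on a relative scale, and beta regression
needs a (0,1) response. Absolute differences are available via
`error_kind = "absolute"`. Taxa undetected under the chosen collapse
(FOtot = 0) are excluded from error summaries. The binomial band drawn
around FO_m uses the Clopper–Pearson exact interval on `FO_m·I` successes
out of `I`.

## Beta regression

Mean relative errors per (taxon, n) are modelled with a beta likelihood:
logit mean link on the full interaction design
`n * FOtot * FOpel` (8 columns) and a log-scale intercept-only precision φ.
The fit is direct maximum likelihood — BFGS with analytic gradient,
initialised from OLS on `logit(y)` and a method-of-moments φ, converged at
relative log-likelihood change < 1e-10 (≤ 200 iterations); standard errors
come from the inverse observed information. Responses touching the boundary
are compressed by the Smithson–Verkuilen transform
`y' = (y(N−1) + 0.5)/N`. Monte-Carlo noise can leave a mean error
infinitesimally below 0 for taxa detected in essentially every pellet;
`beta_design()` treats responses outside [0,1] as an error by contract, and
the pipeline floors such values at 0 (`clip = "zero"`) before compression.
The reported pseudo-R² is the squared Pearson correlation between
`logit(y)` and the fitted linear predictor — the standard beta-regression
definition; the original analysis did not state which definition it used.

Pool detection is modelled as fixed-effect logistic regression of the
per-(individual, taxon) pool detection flag on FOpel, restricted to pairs
detected in the individual's separate pellets. The reference analysis used
a GLMM with an individual random intercept; random-effects ML is outside
this artifact's scope, and the scientific claim — a strongly positive slope
of detection on within-individual frequency — is carried by the fixed-effect
slope's sign and scale. Complete separation raises an error rather than
returning divergent coefficients.

## The synthetic world

`synth_params()` defaults *are* the stated conditions: I = 20, J = 15,
K = 3, T = 150 taxa; consumption probabilities `q_t ~ Beta(0.4, 2.5)`
(right-skewed: few common, many rare prey — ~21 taxa consumed per
individual on average); within-individual frequencies
`r_it ~ Beta(1.2, 3.0)` (mean 0.286, a moderate among-pellet heterogeneity);
PCR detection 0.97 with no false positives (near-identical PCR replicates);
pool detection `plogis(−3 + 6·r_it)`, the slope mirroring the magnitude
(≈6) estimated from real pool data. One seeded RNG stream with a documented
draw order makes datasets bit-reproducible. The generator emulates the
hierarchical variance structure and the pool bias; it does not emulate read
counts, primer bias, contamination, taxonomy errors, or covariate structure
(season, sex), so a green test establishes that the estimators behave
correctly under the assumed hierarchy — not that any particular field study
satisfies it.

On this stated world the pipeline reproduces the qualitative findings the
package exists to demonstrate: MS(individual) > MS(pellet) > MS(PCR); mean
FO error strictly decreasing in pellets analysed; pools no better than a
single pellet for richness and far worse than 14 separate pellets for FO
error; beta-regression pseudo-R² ≈ 0.85. One exploratory comparison does
not transfer: the two-group pools-vs-pellets PERMANOVA is not significant
on synthetic data (the generator's pools are a thinned version of the same
composition, whereas real pools distort composition through template
competition); the unit set and factor coding of that test were not fully
specified in the source analyses, and it is reported descriptively only.

## Numerical and design choices

* Seeds: every stochastic stage takes an explicit integer seed; the
  pipeline derives stage seeds deterministically from one master seed.
* Permutation p-values use the `(1+b)/(1+B)` add-one convention.
* `paired_t` returns `t = 0, p = 1` for all-zero differences and errors on
  zero-variance nonzero differences, where t is undefined.
* Chao2 curve default of 200 resamples balances smoothness against the
  O(reps · n · T) cost; the FO procedure default is R = 10,000.
* Config serialization uses JSON (no YAML parser is assumed present).

## Known limitations

Coverage-based rarefaction, Hill numbers beyond q = 0, non-Euclidean
dissimilarities (Jaccard, Bray–Curtis), mixed-effects estimation, and
sequence-level processing (merging, clustering, taxonomy assignment) are
out of scope; the pipeline starts from a taxon detection table.
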