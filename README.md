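# dietrep

Tools for asking "how much replication is enough?" in DNA-metabarcoding
diet studies. Given presence/absence detections of prey taxa organised in a
nested design — individuals, faecal samples (pellets) per individual, PCR
replicates per sample, plus optional pooled samples — the package quantifies
how technical and biological replication affect the three standard diet
descriptors:

* **diet diversity** — per-individual sample-based rarefaction
  `E[S(n)] = Σ_t [1 − C(m−m_t, n)/C(m, n)]` and the incidence-based Chao2
  estimator `Ŝ = S_obs + ((m−1)/m) Q₁²/(2Q₂)` (with the bias-corrected
  `Q₁(Q₁−1)/(2(Q₂+1))` fallback at `Q₂ = 0`), averaged across individuals;
* **diet composition** — a three-level nested PERMANOVA (individual /
  pellet within individual / PCR within pellet) on squared Euclidean
  distances of the 0/1 unit × taxon matrix, with significance from the
  randomized residual permutation procedure (RRPP);
* **frequency of occurrence (FO)** — a Monte-Carlo pellet-subsampling
  procedure: resample `n` pellets per individual with replacement, re-estimate
  each taxon's FO as the fraction of positive individuals, and model the
  relative estimation error `e_n = (FO_m − FÔ_n)/FO_m` by beta regression
  (logit mean link, precision φ) on `n`, FOtot, FOpel and their interactions.

A synthetic hierarchical generator (`generate_dataset()`) emulates the
motivating study design — 20 individuals × 15 pellets × 3 PCRs plus one
15-pellet pool × 3 PCRs per individual (960 sampling units) — with strong
among-individual heterogeneity, moderate among-pellet heterogeneity,
near-identical PCRs, and pools that preferentially detect taxa frequent
within an individual. It returns the ground truth, so every stage is
testable without any external data.

## Worked example

```r
library(dietrep)

sim  <- generate_dataset(synth_params(seed = 20))      # cube + pools + truth
res  <- run_pipeline(pipeline_config(synth = synth_params(seed = 20),
                                     seed = 20, out_dir = "demo_out"),
                     quiet = TRUE)
```

`demo_out/report.md` from this exact call contains:

```
- mean observed richness at m pellets: 18.300
- pellets for 80% / 95% of full-sample richness: 6 / 11

                   term  df        SS         MS         R2         F p_perm
1            individual  19 1750.1489 92.1130994 0.37469165  9.197878  0.001
2     individual:pellet 280 2804.0889 10.0146032 0.60033103 51.503673  0.001
3 individual:pellet:PCR 600  116.6667  0.1944444 0.02497732        NA  0.001

- mean relative error at n=1: 0.669; at n=14: 0.082
- pseudo R2: 0.8489; phi: 31.10; converged: TRUE
- mean richness: pools 5.4 vs separate 18.3 (paired t = 19.53, df = 19, p = 4.9e-14)
- mean pool error: 0.676 (vs 0.082 at n = 14 separate pellets)
- slope (fopel): 4.501 (SE 0.646, z = 6.97)
```

Reading the output: about 6 of 15 pellets recover 80% of an individual's
detected prey species; variation in composition is dominated by individuals
(MS 92.1) over pellets (10.0) over PCRs (0.19), all significant under RRPP;
FO error falls monotonically with pellets analysed; and a 15-pellet pool
performs like a single pellet — far lower richness (5.4 vs 18.3) and much
larger FO error (0.676 vs 0.082) — because pool detection rises steeply with
a taxon's within-individual frequency (logistic slope ≈ 4.5).

Real data enter as a long-format CSV (columns `individual, unit, unit_kind,
pcr, taxon, detected|reads`) via `read_long_table()`; read counts are
filtered per PCR at a 1% relative-abundance threshold by
`apply_relative_abundance_filter()`. A command-line interface with
`simulate | accumulate | fo-error | permanova | betareg | run` subcommands
ships as `inst/cli/dietrep`.

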