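# dtiboot

Robust diffusion-tensor estimation and wild-bootstrap fractional-anisotropy
(FA) analysis for sparse clinical DWI protocols, with a fully synthetic
data generator standing in for cohort data.

## The problem

Neonatal diffusion MRI is often acquired with a minimal protocol: one
b = 0 volume plus 15 diffusion-weighted directions from the vendor's
anisotropic "over-plus" gradient table at b = 700 s/mm², repeated three
times (48 volumes). Such data are just sufficient for a tensor fit, but
fragile: subject motion produces signal-dropout outliers in up to ~15% of
weighted volumes, re-shimming between repeats offsets intensities, and
the sparse single-shell sampling leaves mean diffusivity (MD)
ill-determined even where FA is reliable. `dtiboot` implements the whole
computation chain needed to work with — and to *trust* — FA estimates
from such a protocol, for imaging scientists and biostatisticians who
want every stage testable without any patient data.

## What it computes

* **Tensor model.** Per volume $k$, $S_k = S_0\exp(-\sum_{ij}B_{k,ij}D_{ij})$
  with $B_k = b\,g_k g_k^\top$; log-domain weighted least squares with
  variance weights $\propto \hat S_k^2$, eigenvalue clamping, and
  $\mathrm{FA}=\sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert/\lVert\lambda\rVert$,
  $\mathrm{MD}=\bar\lambda$.
* **Outlier down-weighting.** Modified Z-scores (median/MAD) of absolute
  log-residuals per volume; weight 1 below 3.5, 0 above 10, linear
  between; iterated to convergence (`fitTensorRobust()`).
* **Wild residual bootstrap.** Rademacher sign-flips of
  leverage-corrected residuals, refit with frozen weights; per-voxel
  FA/MD distributions, percentile CIs, median-FA maps and convergence
  flags (`wildBootstrap()`, `medianFAMap()`, `checkConvergence()`).
* **Monte-Carlo bias evaluation.** Mean FA error (estimated − truth)
  across a ground-truth FA grid for over-plus vs uniform schemes, 0% vs
  15% dropout outliers (`runBiasExperiment()`, `outlierPenalty()`).
* **Group statistics.** Freedman–Lane permutation inference per
  white-matter bundle with a sex covariate and Bonferroni control;
  Cohen's *D* and Akinshin's gamma (Harrell–Davis quantiles over a
  pooled MAD spread) effect sizes (`permutationLM()`, `regionReport()`).
* **Outcome statistics.** Unadjusted group regressions (β = difference
  of group means, t-based CI, Shapiro–Wilk screen) plus Fisher exact,
  Mann–Whitney U and Kendall tau-b background tests (`olsGroupBeta()` …).
* **Synthetic data.** Gradient schemes, single-voxel signals, Rician
  noise, dropout injection, repetition-scale offsets, labelled
  multi-region phantoms and full two-group cohorts with configurable
  region-wise FA differences and outcome scores
  (`buildOverplusScheme()`, `simulateCohort()`, …).

See `vignettes/dtiboot-methods.Rmd` for the model, the defaults and the
design decisions.

## Worked example

```r
library(dtiboot)

scheme <- buildOverplusScheme(700, 3)   # 3 x (1 b=0 + 15 weighted), b = 700
scheme
#> GradientScheme "overplus15": 48 volumes (3 b=0 + 45 weighted),
#>   3 repetition(s), b = 700 s/mm^2

# one voxel at ground-truth FA 0.5, Rician noise at SNR 20
tn  <- prolateTensor(0.50, md = 1.1e-3)
sig <- addRicianNoise(simulateSignal(tn, scheme), snr = 20, seed = 1)

fit <- fitTensorRobust(sig, scheme)
c(fa = fa(fit), md = md(fit))
#>          fa          md
#> 0.523...    1.067e-03

bs <- wildBootstrap(fit, nSamples = 2000, seed = 1)
medianFAMap(bs); bootstrapCI(bs, "fa")
#> 0.528          lower 0.458, upper 0.598
checkConvergence(bs, "fa"); checkConvergence(bs, "md")
#> TRUE; TRUE
```

The point fit lands within the noise-appropriate distance of the truth
(0.52 vs 0.50), the bootstrap median agrees, and the 95% percentile CI
(width 0.14, below the 0.2 convergence threshold) covers the true value
— the behaviour the protocol's three repetitions are meant to buy.

A cohort-level run:

```r
sim  <- simulateCohort(seed = 42)                  # 10 + 10 subjects
rep_ <- regionReport(sim$cohort, nPermutations = 2000, seed = 42)
head(rep_$effects[, c("region", "cohen_d", "gamma_min", "gamma_max",
                      "p_raw", "p_bonferroni")], 4)
#>   region cohen_d gamma_min gamma_max  p_raw p_bonferroni
#> 1  ATR_l   0.644     0.518     1.244 0.1724            1
#> 2  ATR_r   0.197     0.125     0.564 0.7096            1
#> 3  CST_l   0.692     0.383     0.913 0.0985            1
#> 4  CST_r   0.533     0.403     0.948 0.1999            1

olsGroupBeta(sim$cohort$Arrows, sim$cohort$group)
#> beta = 2.882 (CI 1.252 to 4.512), p = 0.001586, n = 20
```

At n = 10 + 10 the estimated effect sizes scatter widely around their
configured values (here ATR_l drew 0.64 against a configured 0.30) —
exactly the sampling behaviour the permutation test has to contend with;
the Arrows regression recovers a β near its configured group difference
of 2.6 standard-score points.

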