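---
title: "Locating the mutation point of the P/E curve: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the mutation point of the P/E curve: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btqr)
```

## The problem

Species distribution models (SDMs) map environmental covariates to a
continuous habitat-suitability surface $hs \in [0,1]$. Many downstream uses
— reserve design, prevalence estimation, climate-impact assessment — need a
binary habitat map instead, which requires choosing a threshold. With
presence-only occurrence data there are no true absences, so the standard
confusion-matrix rules either rely on pseudo-absences of unknowable quality
or on arbitrary fixed sensitivities.

This package selects the threshold from the shape of the Boyce
predicted-to-expected (P/E) curve, which needs presences only.

## The P/E curve

Suitability is partitioned into $b = 1/W$ classes of width $W$. For class
$i$, with $p_i$ validation presences and $a_i$ valid grid cells,

$$P_i = \frac{p_i}{\sum_j p_j}, \qquad E_i = \frac{a_i}{\sum_j a_j},
\qquad F_i = \frac{P_i}{E_i}.$$

$F_i$ is the density of presences in class $i$ relative to a uniform random
placement over the study area; $F_i > 1$ beats chance. For a model that
ranks habitat correctly, $F$ increases with suitability. Published P/E
curves are overwhelmingly concave-upward with a *mutation point*: a
suitability value where the slope jumps abruptly. Source–sink population
theory offers a reading: below the point, occupancy is sustained by
immigration into sink habitat and responds weakly to suitability; above it,
habitat is a self-sustaining source and occupancy responds strongly. The
mutation point is therefore a natural habitat/non-habitat boundary.

Binning choices (`pe_curve()`):

* Classes are contiguous half-open bins $[lo, hi)$, the top bin closed at 1
  so $hs = 1$ is counted. "Divided into $1/W$ classes" defines a partition;
  an overlapping sliding-window mode (`stride`) exists for curve smoothing
  only and is rejected by the fitting function, whose theory assumes a
  partition.
* The per-class abscissa is the mean suitability of the cells in the class,
  not the bin midpoint, so sparse tails are not misplaced.
* Classes with $a_i = 0$ carry no information ($F$ would be $0/0$) and are
  dropped; classes with area but no presences keep the informative
  $F_i = 0$.
* Presences count per record, not per unique cell: the validation record is
  the sampling unit.
* Default $W = 0.01$ (resolution 100), the conventional resolution for
  P/E curves and the one the comparative experiments use.

## Threshold regression

The mutation point is estimated by a two-region threshold regression on the
retained curve points $(hs_t, pe_t)$, $t = 1,\dots,T$:

$$pe_t = hs_t\,\delta_1 + \epsilon_t \;\; (0 < hs_t \le \gamma), \qquad
  pe_t = hs_t\,\delta_2 + \epsilon_t \;\; (\gamma < hs_t \le hs_{max}),$$

$$\hat\gamma = \operatorname*{arg\,min}_{\gamma \in \Gamma} S(\gamma),
\qquad S(\gamma) = \sum_t \big(pe_t - hs_t\delta_1 I_{(0,\gamma]}(hs_t)
  - hs_t\delta_2 I_{(\gamma,hs_{max}]}(hs_t)\big)^2,$$

with $\Gamma$ the observed $hs$ values between the 10th and 90th empirical
percentiles (trimming 10%). Each region is fitted by least squares through
the origin, $\delta = \sum hs\cdot pe / \sum hs^2$, and the grid search is
exhaustive over $\Gamma$, so the estimate is the exact global minimizer of
the profile.

Numerical and design choices (`btqr()`):

* **No intercepts by default.** The model is written without intercepts,
  so the default is regression through the origin per region;
  `intercept = TRUE` is available because threshold-regression practice in
  econometrics usually includes them, but it is clearly non-default.
* **Least squares by default.** The estimator is defined by the SSR
  criterion. A quantile (check-loss) mode, `loss = "quantile"` with
  configurable `tau`, is provided for robustness experiments; it is solved
  exactly by enumerating basic solutions, not by iterative approximation.
* **Trimming quantiles** use the standard continuous convention
  (`stats::quantile` type 7) with inclusive bounds. For ten equally spaced
  observations and 10% trimming this keeps the eight interior values.
* **Feasibility**: a candidate must leave at least one curve point in each
  region (two with intercepts); infeasible candidates are recorded as `NA`
  in the SSR profile and skipped.
* **Tie-break**: among SSR values equal within a small numerical tolerance
  ($10^{-8}$ relative), the smallest candidate wins — deterministic, and it
  favours the more inclusive habitat map. The tolerance matters: on exactly
  proportional data every candidate attains SSR $= 0$ up to round-off, and
  a strict argmin would pick a floating-point accident.
* **Preconditions**: at least 5 retained classes, strictly increasing class
  means, at least 2 surviving candidates; otherwise the fit aborts with a
  specific error rather than extrapolating.

The curve, not the raw presence set, supplies the regression observations
($T \approx 1/W$): the P/E ratio exists only per class.

No confidence interval is reported for $\hat\gamma$ — the point estimate is
the deliverable, and threshold-regression inference (sup-LR tests) is out
of scope.

## Comparator rules

`select_threshold()` implements the nine classical rules used for
comparison: MSS, ESS, MaxKappa, MinROC (these need pseudo-absences);
EqualPrev and MeanProb (these need the study-area predictions); and fixed
sensitivities Se0.5/0.75/0.9 (presences only). Classification is inclusive
(`>=` keeps a cell). All criterion functions are step functions changing
only at observed prediction values, so the optimizers search the sorted
unique observed values plus 0 and 1 — brute force made exact — with ties to
the smallest threshold.

Two conventions required a decision. `MeanProb` averages over the study
area when area predictions are supplied, otherwise over the validation
records. `EqualPrev` never invents an observed prevalence; the caller must
supply one. In `run_benchmark()` the defaults flip to the
validation-driven variants (`meanprob_over = "validation"`,
`equalprev_prevalence = "validation"`, i.e. presences/(presences +
background)): that is how a practitioner with presence-only data would have
to drive these rules, it is what makes their thresholds respond to the
validation dataset — the very sensitivity the consistency F-test measures —
and it reproduces the qualitative pattern that EqualPrev's accuracy depends
strongly on the validation-set composition. The `"area"`/`"truth"` options
restore the idealized variants.

## The virtual-species generator

`virtual_species()` produces a landscape with known truth, emulating the
standard virtual-species construction:

1. **Environmental layers**: Gaussian white noise smoothed with a separable
   Gaussian kernel (sd `smoothness` cells, truncated at 3 sd, edge-
   renormalized), standardized to mean 0, sd 1 — smooth random fields
   standing in for principal-component layers of real climate/terrain
   predictors. Default 3 layers on a $100 \times 100$ landscape;
   `smoothness = 5` gives patch sizes a realistic fraction of the
   landscape.
2. **Suitability**: one response function per layer (`gaussian`, `linear`
   or `logistic`), summed and min–max rescaled to $[0,1]$. The default is a
   Gaussian response (optimum 0, tolerance 1) per standardized layer — a
   species with an interior environmental optimum.
3. **Occurrence probability**: logistic conversion
   $\Pr = 1/(1 + e^{(hs - \beta)/\alpha})$ with $\alpha = -0.05$ (the
   steepness used throughout the comparative study), and $\beta$ calibrated
   by bisection on $[-1, 2]$ so the expected prevalence (mean $\Pr$) hits
   the target to within $10^{-4}$. The prevalence levels of interest are
   0.1, 0.25, 0.5, 0.75.
4. **Realization**: independent cellwise Bernoulli draws
   ($y = 1$ iff $x < \Pr$, $x \sim U(0,1)$) give the presence–absence
   truth map.

All randomness flows through explicit integer seeds; every artefact is a
deterministic function of its seed.

What the generator does *not* emulate: spatial autocorrelation of the
*occurrences beyond* that of the environment (no dispersal, no clustering
of records), observation bias, imperfect detection, or the gap between a
fitted SDM surface and the true suitability (the benchmark's
"perfect-model" scenario feeds the true suitability back as the
prediction). Passing benchmarks therefore demonstrate the estimator's
behaviour under a correctly specified, cleanly sampled world — the same
idealization virtual-species studies accept — not robustness to survey
artefacts.

## Evaluation framework

* **Accuracy**: Cohen's kappa of the thresholded map against the truth map,
  cellwise over all valid cells by default (synthetic grids are small);
  a prevalence-stratified sample (`n_sample`) reproduces the
  $50{,}000p$-presence/$50{,}000(1-p)$-absence test design, scaled.
* **Prevalence recovery**: the fraction of cells at or above the threshold
  versus the known prevalence.
* **Consistency**: thresholds from repeated random validation sets are
  grouped by validation size and compared by one-way ANOVA. Degenerate
  groups follow a fixed convention: zero within-group variance with unequal
  means gives $F = \infty, p = 0$; all-zero variance gives $F = 0, p = 1$.
  The standard case is the textbook MSB/MSW ratio and matches
  `anova(lm(...))` to $10^{-10}$. Group sizes are equal by design, so
  F-values are directly comparable between rules. A stable rule — the
  design goal — has $F$ near or below 1; validation-driven rules like
  MeanProb reach $F$ in the hundreds at these problem sizes.

The consistency summary compares group-typical (median) thresholds between
the smallest and largest validation size: repeats within a size are
exchangeable random validation sets, so the group level, not an arbitrary
pairing of repeats, is where stability is claimed and measured.

## Problem sizes

The shipped tests and the acceptance script run the full design at reduced
scale, chosen to exercise every code path while keeping the suite quick:
$100 \times 100$ landscapes (10,000 cells), validation ladders of
250/500/1000/2000 presences with 2,500 background points, 5 repeats, and 10
independently seeded landscapes; oracle-equivalence checks use 100 random
curves/validation sets; the null-calibration check uses 10,000 cells and
5,000 presences. Larger designs change none of the algorithms — only
sampling noise.

## Known limitations

* The estimator presumes a two-regime, concave-upward curve. Curves that
  are flat, concave-downward, or lack a clear slope change (as ensemble
  tree models sometimes produce) yield a formally valid but ecologically
  uninformative $\hat\gamma$; inspect `plot(fit)` and the SSR profile.
* At high prevalence the mutation point drifts toward the top of the curve
  and the two-slope model fits less cleanly.
* Exactly two regions; multi-threshold models are out of scope.
* Raster I/O is plain-text (ESRI ASCII or headerless grids) and in-memory
  matrices; coordinate handling is the affine cell-center convention
  without projection support.
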