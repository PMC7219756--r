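---
title: "Genomic prediction for cereal field trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for cereal field trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fieldgblup` evaluates single-seed-descent (SSD) breeding lines from
multi-environment yield trials: it builds genomic and pedigree relationship
matrices, fits single- and multi-trait GBLUP mixed models with spatial field
effects by REML, summarises heritability and genetic correlation, and
measures forward cross-validated predictive ability. This vignette is the
package's account of the underlying statistics and of the design choices a
user should know about.

## The mixed models

Yield records `y` (kg per plot) are modelled per trait (a "trait" here is
yield expressed in a given line generation, F5 or F6) as

    y = X b + Z1 g + e                                   (genomic model)
    y = X b + Z1 a + Z2 g + sum_i Zi s + e               (+ pedigree, spatial)

* `b` — fixed effects of the combined year-location-trial factor (YLT),
  cell-means coded so `X` is automatically full rank. Yield trials are
  grown as randomized complete blocks inside trials nested in locations
  and years; YLT absorbs all of that stratification in one factor.
* `g ~ N(0, G sigma_g2)` — genomic breeding values, with `G` the VanRaden
  method-1 relationship matrix `ZZ'/(2 sum p_j (1 - p_j))` built from
  centred minor-allele counts.
* `a ~ N(0, A sigma_a2)` — an optional additional additive effect with the
  pedigree numerator relationship matrix `A` built by the tabular method
  extended for recorded selfing.
* `s ~ N(0, I sigma_s2)` — spatial effects on field coordinates. For
  unreplicated F5 observation trials the plot's row and its column are two
  factor levels sharing one variance (n = 2 incidences). For replicated F6
  trials every occupied grid position is a level and a plot picks up the
  sum over its own position and its (up to) eight Moore neighbours — a
  moving-average surface with n = 9.
* `e ~ N(0, I sigma_e2)` — plot residuals.

The bivariate model stacks the F5 and F6 records and lets the genetic
effects of the two traits covary, `[g1; g2] ~ N(0, H (x) G)` with an
unstructured 2x2 `H` (Kronecker product). Because the two generations are
grown in different years and locations, no plot carries both traits, and
the residual covariance is **structurally zero** — not merely initialised
at zero: the parameter does not exist in the model. Lines observed for only
one trait contribute that trait's records and still receive breeding values
for both traits through `G` and `H`.

## REML estimation

All covariance parameters enter `V(theta) = sum_k theta_k C_k` linearly
(the off-diagonal of `H` included), so one engine fits every model here.
Estimation is average-information (AI) REML:

* score `dl/dtheta_k = -0.5 [tr(P C_k) - y'P C_k P y]` and AI matrix
  `0.5 y'P C_k P C_l P y`, with `P` the REML projection. Both `P` and
  `C_k` are symmetric, so every trace reduces to an elementwise product;
  the per-iteration cost is a single Cholesky of `V` plus `O(n^2)` per
  parameter, which keeps desk-scale problems (hundreds to a few thousand
  plots) in seconds.
* steps are halved until they stay in the parameter space and do not
  decrease the restricted likelihood; if the AI system is singular
  (confounded terms, boundary degeneracy) a Levenberg-style ridge is tried
  and, failing that, an EM step is substituted — the standard projected
  update for scalar variances and the exact joint update for a 2x2 `H`
  block, which cannot decrease the likelihood.
* variances are floored at `1e-8` times the phenotypic variance;
  covariance blocks are kept positive semidefinite by clamping. A
  parameter pinned at the floor with negative score stays there.
* convergence: relative parameter-change norm below `tol` (default
  `1e-8`), with a stationarity guard — five successive iterations without
  likelihood improvement end the fit, which matters when a correlation
  sits exactly on its boundary. Non-convergence is flagged on the result,
  never raised.
* initial values: half the residual phenotypic variance split equally
  among the random terms, half to the residual; covariances start at half
  their bound. The restricted likelihood includes the `-log|X'X|`
  normalisation so its value does not depend on how the fixed effects are
  coded.

BLUPs and fixed-effect solutions come from the equivalent GLS/conditional
mean form at the final parameters; tests verify them against Henderson's
mixed model equations directly.

Fitting both `A` and `G` for the same lines, as the extended model does,
leaves `sigma_a2` and `sigma_g2` only weakly separated (in SSD material
`A` and `G` are similar); their split is then poorly identified even though
their sum, and the predictions, are stable. The same holds for the two
genetic covariance blocks of the full bivariate model, whose correlations
often end on a boundary. Interpret the components of such fits jointly.

## Genetic parameters

With `d(G)` the mean diagonal of `G`, `n_s` the spatial neighbourhood size
(2 or 9) and `r1`, `r2` the per-line replicate counts of the spatial and
residual terms, the phenotypic variance of a line mean is

    sigma_p2 = d(G) sigma_g2 + n_s sigma_s2 / r1 + sigma_e2 / r2

and heritability is `h2 = d(G) sigma_g2 / sigma_p2`. Plot heritability
sets `r1 = r2 = 1`; with a single plot per line the two coincide, and line
heritability grows monotonically with replication. `sigma_s2` is a
per-position variance and enters multiplied by `n_s`, exactly as the
moving-average model generates plot-level spatial variance. Replicate
counts default to the mean number of plots per line in the fitted data
(one analysis may mix 8-plot lines with checks seen far more often); both
can be overridden. The genetic correlation between the generations is
`H[1,2]/sqrt(H[1,1] H[2,2])`.

## Forward cross-validation

The newest crossing cohort ("set") is the validation population.
Single-trait training uses the F6 records of the earlier sets only;
multi-trait training adds the F5 records of **all** sets, including the
validation lines' own F5 plots — transferring that information to the
unobserved F6 trait is the point of the bivariate model. Predictive
ability is the Pearson correlation, over validation lines, between their
fixed-effect-corrected F6 line means and their genomic EBVs from the
training fit; accuracy divides by the square root of the training
heritability of line means.

The fixed-effect correction needs YLT estimates for the validation trials,
which the training data cannot supply (different year). By default they
come from a genomic model fitted to the validation records alone (line
effects random under `G`), so no training phenotype enters the correction;
a plain within-YLT centring is available as an alternative. Check entries
are excluded from the correlation by default. Replicated checks otherwise
receive genetic effects like any line.

## The synthetic study generator

`sim_config()` / `simulate_study()` emulate the structure of a commercial
cereal programme: four yearly crossing cohorts of ~330 SSD lines
(biparental families of ~4 full sibs drawn from a pool of 80 inbred
founders, selfed to F5 by per-marker gene dropping), an unreplicated
single-location F5 observation trial per cohort, and replicated
multi-location two-year F6 trials of 21 lines plus 4 checks repeated in
every trial. Defaults for the variance scale are winter-wheat-like (in
kg²: genomic 0.029/0.076 and residual 0.078/0.228 for F5/F6, spatial
0.01, YLT 0.25) with genetic correlation 0.7 between the generations —
plot heritabilities of roughly 0.4 (F5) and 0.3 (F6).

Two generator choices matter for what the tests can claim:

* ground truth is model-matched. True breeding values are `Z alpha` with
  bivariate marker effects, so their covariance is exactly `H (x) G` for
  the realised genotypes; the F6 spatial surface is generated in the same
  moving-average form the model fits (an AR1 surface is deliberately not
  the default — recovery tests would otherwise conflate model
  misspecification with estimation error). Parameter-recovery results
  therefore show correctness of the estimator, not robustness to
  misspecification.
* the founder pool is large enough (80) that successive cohorts are
  related but not one extended family. A programme drawing all cohorts
  from a few dozen parents would let relatives' records predict a new
  cohort almost as well as its own data, understating the value of the
  multi-trait route.

What the generator does **not** emulate: marker linkage and LD beyond
what the crossing design creates, selection during line development,
explicit genotype-by-environment interaction variance (environments enter
only through YLT means), non-normal yields, and outlier plots. Passing
recovery and direction tests on this generator says nothing about those
features of real data.

Missing genotype calls (default 1%) are masked at random, mean-imputed
after QC (MAF < 0.01 markers and lines > 2% missing removed — lines
first, then marker frequencies recomputed); allele frequencies for the
centring and the VanRaden denominator are taken from the post-QC,
pre-imputation calls, so imputed cells are exactly neutral in `Z`.

## Numerical and design choices

* Marker centring uses `2 p_j` on 0/1/2 counts. The equivalent -1/0/1
  convention shifts every column by a constant and yields the same `G` up
  to that consistent choice; one convention is fixed and tested.
* Relationship matrices are bent before REML when needed: if the smallest
  eigenvalue is below `1e-6` the deficit is added to the diagonal and
  recorded. PCoA shares are taken over positive eigenvalues only.
* Pedigree founders default to nine selfing cycles (diagonal
  `1.998046875`); unknown parents are treated as unrelated fully-selfed
  founders. Intermediate SSD generations carry their recorded number of
  selfing rounds through `F' = (1 + F)/2`.
* The F6 moving average uses existing neighbours only at trial edges (row
  sums 4-9), never padding or reflection; neighbourhoods never cross
  trial boundaries. A normalised variant (rows summing to 1) exists as an
  option.
* F5 spatial coordinates are modelled as factor levels, not continuous
  covariates; that is the reading consistent with `s ~ N(0, I sigma_s2)`.
* `n_s` defaults to 9 for the F6 neighbourhood (the plot counts itself);
  the heritability functions accept any value.
* One global seed drives the generator; the population is drawn at
  `seed` and the trials at `seed + 1`, in documented order, so reruns are
  bit-identical.

## Problem sizes used by the shipped tests

The validation suite works at a deliberate desk scale: oracle comparisons
on toys of 4-15 observations; gene-dropping on pedigrees of up to ~20
individuals with 1e5 replicates; parameter recovery on 300-400 lines x
2,000 markers with two plots per line over 20 seeds; spatial-variance
recovery on a single ~2,000-plot study; and the single- versus multi-trait
comparison on 400-line studies over 20 seeds per scenario. These sizes
keep Monte-Carlo error comfortably inside the stated bands.
`scripts/acceptance.R` re-runs the whole pipeline at the 400-line scale
and writes its headline numbers as JSON.

## Known limitations

* Dense-matrix REML: cost grows with the cube of the number of plots;
  tens of thousands of plots (a full commercial dataset) would need a
  sparse MME-based engine instead.
* Two traits only in the multivariate model; more generations or
  correlated traits would need a general `t`-trait `H`.
* No standard errors for heritability ratios, only for the variance
  components themselves (from the inverse AI matrix).
* The `sigma_a2`/`sigma_g2` split (and the corresponding bivariate
  covariance split) is reported as estimated but is weakly identified in
  SSD material, as noted above.
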