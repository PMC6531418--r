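---
title: "Genomic selection indices for the yield/protein trade-off: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection indices for the yield/protein trade-off: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`selix` studies how a wheat-type line breeding programme can improve
grain yield (GY, dt/ha) and protein content (PC, %) at the same time,
despite their strong negative genetic correlation, and how much genomic
information adds to early-generation selection. This vignette documents
the statistical models, the tunable parameters, the synthetic data the
package generates for testing, and the design decisions taken where the
methodology left genuine choices.

## 1. Two-stage phenotypic analysis

Each trial × trait combination is analysed separately in stage one with a
fixed-effects model containing line and replicate effects and iid
residuals. The line coefficients (replicate effects summing to zero) are
the per-trial BLUEs. A companion fit with random iid line effects (REML,
via `lme4`) gives the within-trial genetic variance, and the
repeatability is

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \tfrac12\,\mathrm{MVD}},$$

where MVD is the mean variance of a difference between two line BLUEs,
computed from the full coefficient covariance matrix. Trials with
repeatability strictly above 0.3 proceed to stage two.

We deliberately fit no spatial model (no row/column effects, no
autoregressive residual structures): the synthetic generator emits no
spatial field, and nothing downstream consumes spatial information. On
data with real field trends the stage-one model is the natural place to
extend the package.

**Unreplicated preliminary yield trials (PYTs).** When entries are grown
on single plots, the within-trial genetic variance is not estimable. The
package then returns check-adjusted values — line mean minus the mean of
the replicated check entries (or minus the trial mean when no checks
exist) — flags `h2` as `NA`, and warns. Such trials bypass the 0.3
filter by default, because their records are exactly what the
genomics-assisted model is designed to exploit. How to quantify
repeatability for unreplicated entries is an open methodological
question; the check-based adjustment is this package's explicit choice.

Stage two combines the retained per-trial BLUEs with the two-way model
$y_{ij} = \mu + g_i + t_j + e_{ij}$ (trial effects always fixed, residual
absorbing the trial-by-line interaction), with line effects fixed for
across-trial BLUEs and random for the genetic variance. BLUEs are
reported on the grand-mean scale with trial effects summing to zero;
adding a constant to one trial therefore shifts every BLUE by the same
amount and leaves all contrasts, rankings, correlations and index
weights unchanged. Unbalanced (missing-cell) designs are handled by
least squares on the available cells; a disconnected line-by-trial
design raises an error naming the disconnected trial groups.

## 2. Genomic prediction

Markers are coded −1/0/1 for inbred lines. QC removes markers with call
rate below 0.90, minor allele frequency strictly below 0.05, or more
than 10% missing data; remaining gaps are filled by per-marker mean
imputation (fractional codes are harmless downstream — both the kinship
and the ridge-regression view are linear in the codes). Mean imputation
is deterministic and dependency-light; it is a simplification relative
to tree-ensemble imputation, and is peripheral to everything the package
measures.

The genomic relationship matrix is

$$K = \frac{WW^\top}{2\sum_k p_k(1-p_k)}, \qquad
  W_{ik} = Z_{ik} + 1 - 2p_k,$$

with sample allele frequencies $p_k$. The scaling denominator is the
standard positive normalisation $2\sum p_k(1-p_k)$, which makes $K$
positive semi-definite with a positive diagonal. Because $W$ is
column-centered at the sample frequencies, $K\mathbf{1} = 0$ holds to
machine precision (a tested invariant).

GBLUP fits $y = Xb + Zg + e$ with $g \sim N(0, K\sigma^2_G)$:

* **Homogeneous residuals** (one record per line): the restricted
  likelihood is profiled on the variance ratio
  $\lambda = \sigma^2_e/\sigma^2_G$ using the eigendecomposition of $K$
  — an exact, deterministic 1-D optimisation (`optimize`, tolerance
  1e-10 on $\log\lambda$ over ±25), the same device used by standard
  ridge-regression BLUP solvers.
* **Heterogeneous residuals** (the genomics-assisted model): training
  lines contribute multi-environment BLUEs and the selection candidates
  contribute their own PYT records; one common residual variance per
  stage, fixed effects = grand mean + PYT-stage indicator. The REML
  criterion is minimised by bounded quasi-Newton (L-BFGS-B) on the
  log-variances; because line searches can abort on near-flat restricted
  likelihoods, a Nelder-Mead simplex restart from the best point is
  attempted before declaring non-convergence. The PYT residual variance
  is estimated by default; fixing it is exposed
  (`fix_pyt_variance`), and fixing it very large provably degenerates to
  the MET-only fit (a tested invariant).

GEBVs are $\mu + g_i$ for *every* line in $K$; unphenotyped candidates
are predicted through their genomic relationship with the phenotyped
lines. Additive effects are reported as deviations from their mean over
the phenotyped lines, with that mean absorbed into $\mu$ — GEBVs are
unchanged and `mean(g)` over the training set is exactly zero. A
non-positive-definite $K$ is ridge-stabilised with 1e-6 on the diagonal,
with a warning. GBLUP and marker ridge regression with penalty
$c\,\sigma^2_e/\sigma^2_G$ (c the kinship scaling) yield identical
GEBVs; the test suite verifies this to 1e-6 against a dense
mixed-model-equation solve.

Preliminary multivariate (multi-trait) GBLUP is out of scope: indices
below need only per-trait GEBVs and their sample covariance.

## 3. Deviations and restriction indices

The grain protein deviation is the residual of an OLS regression of PC
on GY computed on per-line BLUEs; swapping the roles gives the grain
yield deviation. Restriction-index weights come from

$$b = C^{-1} a, \qquad a = (1, 0)^\top,$$

rescaled so the primary-trait weight is exactly 1:
$b = (1, -\beta)^\top$ with $\beta = \mathrm{cov}/\mathrm{var}_{\rm
secondary}$ — the regression coefficient. Index scores are
$\text{primary} - \beta\,\text{secondary}$, differing from the
regression residuals only by the intercept, hence identical rankings
(tested). The four named indices are GPD (improve PC, hold GY), GYD
(improve GY, hold PC), HP (improve protein yield via PC, hold GY) and HY
(improve protein yield via GY, hold PC), with protein yield
$PY = GY \times PC / 100$ (dt/ha).

$C$ is either the phenotypic sample variance–covariance matrix of the
BLUEs or, for genomic indices, the sample variance–covariance matrix of
the GEBVs. We use the covariance matrix, not the correlation matrix: a
correlation matrix would make $\beta$ dimensionless and the index
unit-inconsistent (PC carries %, GY carries dt/ha), and the structural
orthogonality below would be lost.

When $\beta$ is estimated on the same values the index scores, the index
is *exactly* uncorrelated with its restricted trait — an OLS
orthogonality, not an empirical finding; the suite asserts $|r| <
10^{-10}$ for all four indices with both weight sources.

**Where $\beta$ is estimated.** In forward prediction the weights are
computed on the training population's values (BLUEs for phenotypic
indices, GEBVs for genomic indices) and applied unchanged to the
validation candidates — validation phenotypes must never leak into the
predictor. Observed (validation-side) index values use the validation
population's own phenotypic covariance matrix. Re-estimating $\beta$ per
validation year is a defensible alternative; training-$\beta$ is the
default here.

## 4. Forward prediction and response to selection

The harness assigns every line to the year of its first
multi-environment testing; lines tested in several years (the replicated
checks) belong to no cohort and are excluded from the pools. Models are
trained on lines from the training years and validated against cohorts
of later years. Per validation year and resample, `n_train` lines
(default 300) are drawn from the training pool and `n_valid` candidates
(default 100) from the cohort, `n_resamples` times (default 30); the PYT
set is identical with the validation candidates. One master seed
generates a matrix of per-resample child seeds up front
(`sample.int(.Machine$integer.max - 1)` under the master seed), so any
single resample is reproducible in isolation and results are
bit-identical for fixed seeds.

Three methods produce the seven predictors (GY, PC, PY, four indices):
phenotypic (the candidates' own PYT records), genomics-based (GBLUP on
training BLUEs) and genomics-assisted (weighted GBLUP adding the
candidates' PYT records). Accuracy is the Pearson correlation with the
observed validation value divided by $\sqrt{h^2_{GEN}}$, where

$$h^2_{GEN} = (\sigma^2_P - \sigma^2_e)/\sigma^2_P$$

comes from a GBLUP containing only the validation candidates' own
phenotypes. $h^2_{GEN}$ is clamped to [0, 1] (it can leave the interval
in small samples), which keeps the selected-mean predictor

$$\hat\mu_{Sel} = \mu + h^2_{GEN}(\mu_{Sel} - \mu)$$

a contraction; the relative response $(\hat\mu_{Sel} - \mu)/\mu$ is
reported in percent. Accuracies are clamped to [−1, 1] after the
$\sqrt{h^2_{GEN}}$ division. Selection takes the top
$\lceil f n\rceil$ lines by score for $f$ = 10–50%, ties broken by
ascending line id (stable and documented; guarded against floating-point
overshoot of $f\,n$).

**Combined strategy.** The 10% selection can be split 5% + 5% between a
protein-oriented and a yield-oriented index. Overlap between the two
half-lists is resolved by extending the yield-index ranking until the
union reaches $\lceil f n\rceil$ — a fixed selected-set size. The
overlap rule is not dictated by the methodology; fixing the set size
makes responses comparable across resamples.

## 5. The synthetic breeding programme

`simulate_population()` emulates the data structure the analysis
assumes: `n_lines` inbred lines in `n_families` bi-parental families
(two founder gametes per family; progeny inherit one founder allele per
marker, so within-family kinship exceeds across-family kinship — a
tested invariant), `n_markers` biallelic SNPs with MAF in `maf_range`,
and 2% residual heterozygosity. Marker effects for GY and PC are drawn
bivariate normal with the configured correlation (default −0.5, a
typical strong yield/protein antagonism); additive values
$g = Z\beta$ are rescaled to the configured genetic standard deviations.
Plot phenotypes are trait mean + trial effect + additive value +
residual, with the residual variance set from the stage's single-plot
heritability via $\sigma^2_e = \sigma^2_G(1-h^2)/h^2$; protein yield is
the exact product on every plot.

Defaults describe a mid-sized programme: 900 lines in 180 families over
seven years (three training, four validation cohorts), three MET trials
per year with two replicates, one unreplicated PYT per validation cohort
in the preceding year with replicated checks, means 80 dt/ha (GY) and
14% (PC), genetic SDs 4 and 0.8, MET plot heritabilities 0.4 (GY) and
0.7 (PC), PYT plot heritabilities 0.2 and 0.3. PYT residual magnitudes
for such programmes are not well documented; the 0.2–0.3 single-plot
heritabilities are a modelling choice representing noisy early-stage
data, chosen once. Trial main effects have SD 5 dt/ha and 0.5%.

What the generator does **not** emulate: linkage maps and LD beyond
family structure, genotype-by-environment interaction beyond year/trial
main effects plus residual, dominance/epistasis, spatial field trends,
and selection during the programme (cohorts are random). Passing tests
therefore demonstrate the statistical machinery under the assumed
variance structure, not performance on any real breeding dataset —
published accuracies from real programmes are properties of proprietary
data and are targeted directionally only (method orderings and response
signs, not values).

## 6. Numerical choices and degenerate inputs

* REML tolerances: 1e-10 on $\log\lambda$ (eigen profile); L-BFGS-B
  `factr = 1e7` with simplex fallback (general case); non-convergence is
  an error reporting both optimisers' codes and evaluation counts.
* Noiseless trials: the `lm` covariance warning is suppressed; `lme4`
  failures fall back to expected-mean-squares estimates; $h^2 \to 1$.
* Zero genetic signal: $h^2 \to 0$; constant regressors and singular
  2×2 covariance matrices are errors, as are all-monomorphic marker
  sets (zero kinship denominator) and markers with no observed calls.
* Small-sample GEBV covariance matrices can be near-singular (GEBVs of
  two traits nearly collinear); `restriction_weights()` then fails
  loudly rather than returning unstable weights. Training sets of ≥ 80
  lines were comfortable in all tested settings.
* Problem sizes in the test and acceptance runs are scaled to what the
  method needs, not more: variance-component recovery uses 400 lines ×
  50 seeds, genomic-heritability recovery 30 seeds of 160-line
  programmes, and the directional forward-prediction checks run the
  default 30-resample scheme on one validation year of the default
  programme (the acceptance script runs all four validation years).

## 7. Known limitations

* Stage one ignores spatial structure; with strong field trends the
  repeatability filter will misclassify trials.
* Mean imputation attenuates kinship slightly relative to model-based
  imputation when missingness is high (QC caps it at 10%).
* The genomic covariance matrix from GEBV samples is shrunken relative
  to the true genomic covariance; with very small training sets the
  derived $\beta$ is noisy.
* `h2_gen` clamping biases responses towards zero in very small or very
  noisy validation sets.
* The two-variance heterogeneous model assumes one common PYT residual
  variance; per-trial PYT variances are not modelled.
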