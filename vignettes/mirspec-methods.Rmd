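---
title: "Serum mid-infrared prognostic modelling with mirspec: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum mid-infrared prognostic modelling with mirspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirspec)
```

## The problem

Decompensated cirrhosis carries a high short-term mortality, and the
clinical scores used to triage patients (MELD, Child-Pugh) summarise only a
handful of laboratory values. A mid-infrared (MIR) absorbance spectrum of
serum is a cheap, label-free metabolic fingerprint: every absorbance value
between roughly 3200 and 950 cm^-1 reflects the vibrational signature of the
circulating proteins, lipids, carbohydrates and small metabolites. mirspec
implements a complete chemometric pipeline that turns a matrix of such
spectra plus a six-month survival outcome into a small prognostic marker
panel and a cross-validated discriminant model, and compares that model
against the clinical scores.

The pipeline has four stages, mirroring standard serum FTIR practice:

1. **Pre-treatment** — restrict to the 3200-950 cm^-1 working domain
   (2 cm^-1 step, 1126 points), bridge the ambient-CO2 window 2800-1800
   cm^-1 with a straight line, take a 13-point Savitzky-Golay second
   derivative (polynomial order 2), keep the analysis domain
   [962, 1800] + [2800, 3188] (exactly 615 variables), and scale each
   spectrum to unit Euclidean norm.
2. **Wavenumber selection** — 200 repetitions of a factor-adjusted greedy
   forward selection, each on a random stratified 90% subsample; the
   selection-frequency histogram is cut at a threshold retaining about 30
   variables, and a supervised backward pass under Monte Carlo
   cross-validated AUROC reduces those to a final panel of 7-12.
3. **Classification** — two-class pooled-covariance linear discriminant
   analysis on the final panel, scored on the posterior-probability scale,
   with 100 runs of stratified 90%/10% Monte Carlo cross-validation and a
   Youden-index operating cut-off.
4. **Evaluation** — Mann-Whitney AUROC with percentile (across CV runs) and
   DeLong (full cohort) confidence intervals, DeLong tests against MELD and
   Child-Pugh on the same patients, and a Spearman correlation network
   linking the spectral markers to the clinical chemistry.

## Pre-treatment choices

*One filter, not two.* "Second derivative then smoothing" is implemented as
a single Savitzky-Golay second-derivative filter (window 13, order 2); the
coefficients come from `signal::sgolay` and are exact for polynomials up to
the filter order, so the second derivative of a quadratic is recovered
without error — a property the test suite asserts directly.

*Edge handling.* No padding is used: the filter drops six points at each end
of the 1126-point working domain. Together with open-interval exclusion of
the CO2 gap (the endpoints 1800 and 2800 are kept), this yields exactly
615 analysis variables — 420 in the fingerprint segment and 195 in the C-H
stretch segment. Padded variants would give 621-627 variables and are
rejected by that count.

*Normalization domain.* Unit-norm scaling acts on the 615-point analysis
vector — the vector that enters the classifier — not on the full recorded
range.

*Quality control.* The quality screen requires the protein-band peak
absorbance (1700-1600 cm^-1) to sit in the detector range 0.05-2.0 AU, the
linearly detrended RMS in the signal-free 2200-2000 cm^-1 window to stay
below 5 mAU, and all values to be finite. These thresholds describe a
well-conditioned measurement; they are configuration fields, not constants.
The visual PCA homogeneity check is automated as a Hotelling T-squared
screen over the first 10 principal components with an F-based critical
value at a nominal 2.5% flagging rate; flagged samples are reported, never
silently removed.

## The synthetic cohort generator

Real serum spectra for this design are not redistributable, so the package
ships a generator whose defaults emulate the study conditions: 116
analysable patients, 23 of whom (20%) die within six months; spectra on the
950-3200 cm^-1 grid built from Gaussian absorption bands, a quadratic
baseline drift, 2 mAU white noise, and an ambient-CO2 artifact at 2349
cm^-1 that the gap bridge removes exactly; and clinical covariates drawn
per outcome class from the published per-group means and SDs (bilirubin
49.0 ± 54.1 vs 144.6 ± 183.7 µmol/L, MELD 14.9 ± 4.8 vs 21.4 ± 8.2, and so
on), clamped to physiological ranges.

The discriminative structure deserves explanation, because it is what makes
a factor-adjusted selector meaningful:

* Seven narrow marker bands sit at 2925, 1496, 1468, 1316, 1078, 1030 and
  972 cm^-1 — lipid acyl, aromatic, amide III and carbohydrate/nucleic-acid
  assignments. Their intensities co-vary across patients through a single
  latent "disease axis" concentration factor with signed loadings (some
  constituents rise while others fall), on top of weak per-class background
  factors (total protein, lipids, carbohydrates) and a small idiosyncratic
  jitter per band.
* The class effect is a fractional amplitude shift along the same signed
  pattern. It is therefore *masked*: no single wavenumber separates the
  classes well until the shared factor is adjusted away — precisely the
  regime factor-adjusted discriminant analysis is designed for.
* The signed pattern is chosen nearly power-neutral in the derivative
  domain, and `class_balance_factor()` attenuates whichever sign group
  carries excess second-derivative power (computed through the actual
  linear pipeline). Without this, vector normalization converts a net
  intensity effect into a spurious marker at the strongest background bands
  (amide I/II) — a closure artifact worth knowing about in real data too.

`calibrate_effect(target_auc)` links effect size to discriminability through
the equal-covariance Gaussian identity AUROC = pnorm(delta / sqrt(2)),
where delta is the Mahalanobis distance between the processed class means at
the marker wavenumbers. It measures delta on a 3000-patient pilot cohort
(with a small-sample bias correction) and rescales the effect through three
fixpoint refinements; normalization makes the map mildly nonlinear, so a
single pass is not sufficient.

What the generator does **not** emulate: real between-covariate correlation
structure (covariates are independent given class; MELD and Child-Pugh are
drawn from their per-class margins rather than recomputed from the drawn
labs), Mie/scatter distortions, water-vapour residuals, and instrument
drift. Passing tests on the emulation therefore demonstrate the statistical
machinery, not robustness to every artefact of real serum FTIR.

## Selection: design decisions

The factor model is estimated by within-class PCA: loadings are the leading
principal axes of the pooled within-class correlation matrix scaled by the
root eigenvalues; factor scores are ordinary regressions of each
standardized sample on the loadings, so the adjustment is an orthogonal
projection (exactly idempotent) and class means are preserved. The factor
count uses an elbow rule — the smallest k whose marginal relative drop in
mean squared off-diagonal residual within-class correlation falls below 5%
— which returns 0 on independent data and the true rank on planted factor
structures.

The greedy forward selector uses the mean LDA misclassification rate under
internal 5-fold stratified cross-validation as its fitness. At cohort sizes
around 100-150 this 0/1 loss is granular (multiples of 1/n) and exact ties
among candidates are common; ties are resolved by the larger held-out
discriminant margin (a continuous proxy of the same fitness) and only then
by the lower wavenumber. Without the margin rule, mass ties systematically
flood the lowest-wavenumber columns of the histogram.

The 200 outer repetitions each subsample a stratified 90% of the cohort.
Stratification matters: with 20% prevalence an unstratified 10% holdout
frequently loses the minority class entirely. The retention threshold (the
histogram's "red line") defaults to the count that keeps about 30
variables; `repeated_selection(..., null_permute = TRUE)` provides the
permutation-null reference (labels freshly permuted in every run) against
which that threshold can be judged — under the null no variable exceeds a
few percent selection frequency.

The supervised reduction step is formalized as greedy backward elimination
under 100-run 90/10 Monte Carlo CV AUROC with fixed splits: removal is
forced while the panel exceeds 12 variables, then continues only while the
mean AUROC drops by at most 0.005, and never below 7 variables.

A caveat from the emulation: on full spectral cohorts the selection
histogram resolves markers at *band* rather than single-column resolution —
the 13-point filter correlates neighbouring columns, so counts split
between a band centre and its immediate neighbours, and occasionally a
sidelobe outranks the centre. Recovery claims on spectral data should be
read at a few-cm^-1 tolerance.

## Classification and evaluation choices

LDA is fitted with a small ridge (1e-8) on the pooled covariance; scores
are `plogis(w'x + b)` with the log-prior offset, so a sample midway between
the class means under equal priors scores 0.5 and the published cut-off
scale (around 0.3) is meaningful. Each CV run records the holdout AUROC and
the holdout Youden cut-off; sensitivity and specificity are then recomputed
per run at the across-run *mean* cut-off, which is the operating point a
study would publish. Runs are stratified; an unstratified single-class
holdout would be dropped with a warning rather than imputed.

Two AUROC confidence intervals are available and deliberately kept
distinct: `auc_ci_over_runs()` gives the empirical 2.5/97.5 percentiles
across CV runs (type-7 interpolation), and `auc_ci_delong()` gives the
placement-value variance interval for a single full-cohort curve. DeLong
model comparisons are run on full-cohort fitted scores by default, which is
optimistic — the printout warns about this. Network p-values are raw
(matching exploratory practice); `adjust = "BH"` enables
Benjamini-Hochberg.

## Numerical and statistical caveats

* **Small-cohort AUROC noise.** With 116 patients and 23 events, the
  sampling standard deviation of a cross-validated AUROC is about 0.07 from
  pair-counting alone and about 0.12 once 7-variable LDA estimation noise
  is included. A null cohort therefore lands outside [0.40, 0.60] in a
  substantial minority of replicates; this is a property of the cohort
  size, not an optimism bias, and the test suite documents it honestly.
* **Problem sizes.** The shipped tests and the acceptance script use pilot
  cohorts of 3000 spectra for calibration, 10 replicate cohorts of 116 for
  CV properties, 5 + 5 outer seeds for selection recovery and its
  permutation null, 1000-instance oracle sweeps, a 100 000-replicate
  bootstrap for the DeLong variance and 2000 null replicates for its size.
* **Determinism.** Every stochastic entry point takes a seed and restores
  the caller's RNG state; a cohort is a pure function of its configuration.
* **Degenerate inputs.** All-zero spectra cannot be normalized (error);
  constant variables are skipped by the Spearman network with a warning;
  singular covariances abort rather than silently pseudo-invert.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- cohort_config(n = 116, effect_scale = calibrate_effect(0.90), seed = 7)
sim <- simulate_cohort(cfg)
proc <- preprocess_spectra(sim$spectra)

sel <- select_wavenumbers(proc$matrix, proc$labels,
                          selection_config(seed = 7))
panel <- sel$final$column

cv <- mc_cross_validate(proc$matrix[, panel], proc$labels,
                        cv_config(seed = 7))
glance(cv)

fit <- fit_lda(proc$matrix[, panel], proc$labels)
scores <- score_samples(fit, proc$matrix[, panel])
compare_models(list(MIR = scores,
                    MELD = sim$cohort$meld,
                    ChildPugh = sim$cohort$child_pugh),
               proc$labels)
spearman_network(proc$matrix[, panel], sim$cohort)
```
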