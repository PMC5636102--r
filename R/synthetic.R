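# Synthetic two-class serum MIR cohorts with known ground truth:
# Gaussian absorption bands on the 950-3200 cm^-1 grid, a polynomial
# baseline, white noise, an ambient-CO2 artifact, and clinical covariates
# drawn per outcome class.

#' Default absorption band library
#'
#' Gaussian band definitions emulating a serum fingerprint spectrum. Seven
#' discriminative bands (nonzero `class_shift`) sit at the wavenumbers a
#' mortality model selects on real cohorts — 2925 (nu_as CH2 acyl chains),
#' 1496 (aromatic ring), 1468 (delta CH2), 1316 (amide III), 1078 (PO2-
#' nucleic acids / sugars), 1030 (nu C=O, RNA/polysaccharides) and
#' 972 cm^-1 (all-trans lipid) — plus ten non-discriminative background
#' bands (amide A/B, CH stretches, amide I/II, carboxylate and fingerprint
#' bands). `class_shift` is the fractional amplitude difference of the
#' deceased class relative to the alive class before scaling by
#' `effect_scale`.
#'
#' Per-sample band intensities co-vary through latent concentration factors
#' (one per `group`; the discriminative bands share a "marker" disease-axis
#' factor with signed loadings, backgrounds follow weak protein/lipid/
#' carbohydrate factors) plus a small idiosyncratic jitter, giving the
#' low-rank within-class covariance a factor-adjusted selector assumes.
#'
#' @return A tibble with columns `center`, `fwhm`, `amplitude`,
#'   `class_shift`, `group`, `assignment`.
#' @export
default_band_library <- function() {
  tibble::tribble(
    ~center, ~fwhm, ~amplitude, ~class_shift, ~group, ~factor_loading, ~assignment,
    # discriminative marker bands: one co-regulated disease axis (for
    # instance cholestatic/uremic metabolites rising while lipid acyl
    # signals fall), encoded by signed loadings on the shared "marker"
    # concentration factor. Class shifts follow the same signed pattern, so
    # the effect lies along the factor direction (masked from any single
    # variable until the factor structure is adjusted away) and the signed
    # pattern is chosen nearly power-neutral in the derivative domain, so
    # neither the factor nor the class effect moves the spectrum norm that
    # vector normalization divides out.
    2925,      8,    0.028,      0.10,  "marker",   1, "nu_as CH2 acyl chains (stretching)",
    1496,      8,    0.028,     -0.10,  "marker",  -1, "aromatic ring",
    1468,      8,    0.028,     -0.10,  "marker",  -1, "delta CH2 (bending)",
    1316,      8,    0.028,      0.10,  "marker",   1, "amide III, protein",
    1078,      8,    0.028,      0.10,  "marker",   1, "PO2- nucleic acid / C-C, C-O sugars",
    1030,      8,    0.028,     -0.10,  "marker",  -1, "nu C=O; RNA and exo-ring polysaccharides",
    972,      8,    0.028,     -0.10,  "marker",  -1, "delta all-trans lipid",
    # background serum bands
    3060,     40,    0.080,      0,     "protein",  1, "amide B, N-H stretch overtone",
    2958,     18,    0.090,      0,     "lipid",    1, "nu_as CH3",
    2871,     16,    0.050,      0,     "lipid",    1, "nu_s CH3",
    2853,     16,    0.060,      0,     "lipid",    1, "nu_s CH2 acyl chains",
    1650,     45,    0.800,      0,     "protein",  1, "amide I, protein",
    1548,     40,    0.500,      0,     "protein",  1, "amide II, protein",
    1400,     25,    0.120,      0,     "protein",  1, "nu_s COO- amino-acid side chains",
    1240,     30,    0.070,      0,     "protein",  1, "amide III / nu_as PO2-",
    1171,     20,    0.040,      0,     "carb",     1, "nu C-O ester",
    1115,     22,    0.035,      0,     "carb",     1, "nu C-O carbohydrate"
  )
}

# Per-class (mean, sd) clinical margins of a cirrhosis-with-ascites cohort
# followed for 6-month mortality (alive n = 93 / deceased n = 23 study).
default_covariate_spec <- function() {
  tibble::tribble(
    ~variable,            ~mean_alive, ~sd_alive, ~mean_dead, ~sd_dead,
    "age",                      56.7,      14.4,      59.9,       9.8,
    "creatinine",               81.9,      51.2,     127.2,     145.1,
    "albumin",                  30.0,       4.6,      28.2,       5.1,
    "bilirubin",                49.0,      54.1,     144.6,     183.7,
    "prothrombin_ratio",        56.7,      13.6,      46.6,      14.1,
    "inr",                      1.58,      0.39,      1.89,      0.45,
    "sodium",                  135.8,       4.1,     132.9,       3.9,
    "ast",                      84.8,     112.6,      89.4,      52.6,
    "alt",                      41.3,      56.5,      44.3,      28.8,
    "ggt",                     198.4,     184.9,     255.8,     316.3,
    "crp",                      19.7,      39.7,      27.3,      24.5,
    "alp",                     151.2,      83.0,     201.2,     121.1,
    "meld",                     14.9,       4.8,      21.4,       8.2,
    "child_pugh",                9.1,       1.7,      10.9,       1.6
  )
}

#' Synthetic cohort configuration
#'
#' Defaults describe the emulated study conditions: 116 analysable patients
#' with a 6-month mortality of 23/116 (20%), spectra on the 950-3200 cm^-1
#' grid at 2 cm^-1, instrument noise of 2 mAU RMS, a gentle quadratic
#' baseline, latent concentration-factor jitter (a strong marker "disease
#' axis" plus weak background-group factors) with per-band idiosyncratic
#' jitter, and per-class clinical covariate margins matching the study's
#' cohort table.
#'
#' @param n Number of patients.
#' @param prevalence Fraction deceased at 6 months.
#' @param band_library Band definitions, see [default_band_library()].
#' @param noise_sd White-noise standard deviation, AU.
#' @param baseline_order Polynomial order of the random baseline drift.
#' @param baseline_sd Scale of the random baseline coefficients, AU.
#' @param group_jitter Named lognormal sigmas of the per-sample latent
#'   concentration factors, one per band group.
#' @param jitter_idio Lognormal sigma of the per-band idiosyncratic jitter.
#' @param co2_amplitude Mean amplitude of the 2349 cm^-1 ambient-CO2 artifact.
#' @param effect_scale Multiplier applied to every `class_shift`; 0 gives a
#'   null cohort, [calibrate_effect()] maps a target AUROC to a value.
#' @param covariate_spec Per-class covariate margins,
#'   see `default_covariate_spec`.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 116,
                          prevalence = 23 / 116,
                          band_library = default_band_library(),
                          noise_sd = 0.002,
                          baseline_order = 2,
                          baseline_sd = 0.01,
                          group_jitter = c(marker = 0.08, protein = 0.015,
                                           lipid = 0.015, carb = 0.015),
                          jitter_idio = 0.06,
                          co2_amplitude = 0.02,
                          effect_scale = 1,
                          covariate_spec = default_covariate_spec(),
                          seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, n >= 4,
            all(band_library$fwhm > 0), all(band_library$amplitude >= 0),
            all(unique(band_library$group) %in% names(group_jitter)))
  if (round(n * prevalence) < 1) {
    abort("n * prevalence must round to at least one deceased patient",
          class = "mirspec_validation_error")
  }
  structure(list(n = n, prevalence = prevalence, band_library = band_library,
                 noise_sd = noise_sd, baseline_order = baseline_order,
                 baseline_sd = baseline_sd, group_jitter = group_jitter,
                 jitter_idio = jitter_idio,
                 co2_amplitude = co2_amplitude, effect_scale = effect_scale,
                 covariate_spec = covariate_spec, seed = as.integer(seed)),
            class = "cohort_config")
}

work_grid <- function(cfg_pre = preprocess_config()) {
  seq(cfg_pre$work_domain[1], cfg_pre$work_domain[2], by = cfg_pre$grid_step)
}

# Noise-free class-mean analysis vector (derivative domain, before
# normalization) for per-band amplitude multipliers `mult`.
mean_analysis_vector <- function(bl, mult, cfg_pre = preprocess_config()) {
  wn <- work_grid(cfg_pre)
  sig <- bl$fwhm / (2 * sqrt(2 * log(2)))
  a <- numeric(length(wn))
  for (b in seq_len(nrow(bl))) {
    a <- a + bl$amplitude[b] * mult[b] *
      exp(-0.5 * ((wn - bl$center[b]) / sig[b])^2)
  }
  s <- new_spectrum("mean", wn, a, stage = "raw")
  extract_analysis_domain(
    second_derivative(replace_co2_gap(s, cfg_pre), cfg_pre),
    cfg_pre)$absorbance
}

# Per-sign attenuation factors (both in [0, 1]) making the deceased-class
# mean spectrum carry the same analysis-domain derivative power as the
# alive-class mean, computed through the actual linear pipeline so band
# overlap and the smoothing filter are accounted for. Whichever sign group
# contributes excess power is scaled down; nothing is ever amplified. Keeps
# the class effect compositional: vector normalization removes total-amount
# differences, so an unbalanced effect would surface as a spurious marker
# at the strongest background bands instead of at the shifted bands.
class_balance_factor <- function(cfg) {
  bl <- cfg$band_library
  e <- cfg$effect_scale
  pos <- bl$class_shift > 0
  neg <- bl$class_shift < 0
  if (e == 0 || !any(pos) || !any(neg)) return(c(pos = 1, neg = 1))
  p0 <- sum(mean_analysis_vector(bl, rep(1, nrow(bl)))^2)
  pwr <- function(tp, tn) {
    mult <- 1 + bl$class_shift * e * ifelse(neg, tn, tp)
    sum(mean_analysis_vector(bl, pmax(mult, 0))^2) - p0
  }
  if (pwr(1, 1) > 0) {
    if (pwr(0, 1) > 0) return(c(pos = 0, neg = 1))
    c(pos = stats::uniroot(function(t) pwr(t, 1), c(0, 1), tol = 1e-12)$root,
      neg = 1)
  } else {
    if (pwr(1, 0) < 0) return(c(pos = 1, neg = 0))
    c(pos = 1,
      neg = stats::uniroot(function(t) pwr(1, t), c(0, 1), tol = 1e-12)$root)
  }
}

#' Simulate one serum-like spectrum
#'
#' Sum of Gaussian bands — each amplitude multiplied by
#' `1 + label * class_shift * effect_scale` and by a per-sample lognormal
#' jitter — plus a low-order polynomial baseline, white noise, and a CO2
#' artifact band at 2349 cm^-1 (inside the bridged gap, so the pre-treatment
#' removes it). Strictly reproducible from `(cfg$seed, index)`.
#'
#' @param label 0 (alive) or 1 (deceased).
#' @param cfg A [cohort_config()].
#' @param index Sample index used to derive the per-sample seed.
#' @param sample_id Sample id (default derived from `index`).
#' @return A raw `mir_spectrum` on the 950-3200 cm^-1 grid.
#' @export
simulate_spectrum <- function(label, cfg = cohort_config(), index = 1L,
                              sample_id = sprintf("S%03d", index),
                              balance = NULL) {
  stopifnot(label %in% c(0, 1))
  wn <- work_grid()
  bal <- if (is.null(balance)) class_balance_factor(cfg) else balance
  with_local_seed(child_seed(cfg$seed, index), {
    a <- numeric(length(wn))
    bl <- cfg$band_library
    sig <- bl$fwhm / (2 * sqrt(2 * log(2)))
    shift <- bl$class_shift * cfg$effect_scale *
      ifelse(bl$class_shift < 0, bal[["neg"]], bal[["pos"]])
    groups <- unique(bl$group)
    conc <- setNames(rnorm(length(groups),
                           0, cfg$group_jitter[groups]), groups)
    for (b in seq_len(nrow(bl))) {
      amp <- bl$amplitude[b] * (1 + label * shift[b]) *
        exp(bl$factor_loading[b] * conc[[bl$group[b]]] +
              rnorm(1, 0, cfg$jitter_idio))
      a <- a + amp * exp(-0.5 * ((wn - bl$center[b]) / sig[b])^2)
    }
    # baseline drift: random polynomial on a [-1, 1]-scaled axis
    u <- (wn - mean(wn)) / (diff(range(wn)) / 2)
    coefs <- rnorm(cfg$baseline_order + 1, 0, cfg$baseline_sd)
    a <- a + drop(outer(u, 0:cfg$baseline_order, `^`) %*% coefs)
    # ambient CO2 doublet region, removed later by the gap bridge
    a <- a + cfg$co2_amplitude * exp(runif(1, -0.5, 0.5)) *
      exp(-0.5 * ((wn - 2349) / (30 / 2.3548))^2)
    a <- a + rnorm(length(wn), 0, cfg$noise_sd)
    new_spectrum(sample_id, wn, a, stage = "raw")
  })
}

#' Simulate a full cohort
#'
#' Generates exactly `round(n * prevalence)` deceased patients, a spectrum
#' per patient, and clinical covariates drawn independently per class from
#' Normal margins (clamped to physiological ranges; MELD and Child-Pugh
#' rounded to integer points). Ground truth records the informative
#' wavenumbers and labels.
#'
#' @param cfg A [cohort_config()].
#' @return A list with elements `spectra` (`mir_spectra_set`, labels set),
#'   `cohort` (validated tibble) and `truth` (list: `informative_wavenumbers`,
#'   `labels`, `effect_scale`).
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  n <- cfg$n
  n_dead <- round(n * cfg$prevalence)
  labels <- with_local_seed(child_seed(cfg$seed, 0L), {
    sample(c(rep(1L, n_dead), rep(0L, n - n_dead)))
  })
  ids <- sprintf("S%03d", seq_len(n))
  bal <- class_balance_factor(cfg)
  specs <- lapply(seq_len(n), function(i) {
    simulate_spectrum(labels[i], cfg, index = i, sample_id = ids[i],
                      balance = bal)
  })
  mat <- do.call(rbind, lapply(specs, `[[`, "absorbance"))
  spectra <- new_spectra_set(ids, specs[[1]]$wavenumbers, mat,
                             labels = labels, stage = "raw")

  cov_spec <- cfg$covariate_spec
  ranges <- cohort_columns()
  cohort <- with_local_seed(child_seed(cfg$seed, -1L), {
    cols <- lapply(seq_len(nrow(cov_spec)), function(j) {
      mu <- ifelse(labels == 1L, cov_spec$mean_dead[j], cov_spec$mean_alive[j])
      sdv <- ifelse(labels == 1L, cov_spec$sd_dead[j], cov_spec$sd_alive[j])
      v <- rnorm(n, mu, sdv)
      r <- ranges[ranges$column == cov_spec$variable[j], ]
      if (nrow(r) == 1 && !is.na(r$min)) v <- pmin(pmax(v, r$min), r$max)
      if (cov_spec$variable[j] %in% c("meld", "child_pugh")) v <- round(v)
      v
    })
    names(cols) <- cov_spec$variable
    tibble::tibble(
      sample_id = ids,
      !!!cols,
      sex = ifelse(runif(n) < ifelse(labels == 1L, 18 / 23, 76 / 93),
                   "M", "F"),
      beta_blockers = runif(n) < 51 / 116,
      outcome = labels
    )
  })
  truth <- list(
    informative_wavenumbers = cfg$band_library$center[
      cfg$band_library$class_shift != 0],
    labels = labels,
    effect_scale = cfg$effect_scale
  )
  list(spectra = spectra, cohort = validate_cohort(cohort), truth = truth)
}

# Indices of the informative band centres on an analysis-domain grid:
# nearest grid point to each discriminative band centre.
informative_columns <- function(grid, truth) {
  vapply(truth$informative_wavenumbers,
         function(w) which.min(abs(grid - w)), integer(1))
}

#' Locate ground-truth marker columns in a processed spectra set
#'
#' Maps each informative band centre of a simulation's ground truth to the
#' nearest column of the processed analysis grid.
#'
#' @param x A processed `mir_spectra_set` (e.g. from [preprocess_spectra()]).
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return Integer vector of column indices into `x$matrix`.
#' @export
match_markers <- function(x, truth) {
  stopifnot(inherits(x, "mir_spectra_set"))
  informative_columns(x$grid, truth)
}

#' Calibrate the class-effect multiplier to a target AUROC
#'
#' For equal-covariance Gaussian classes the AUROC of the Bayes-optimal
#' linear score is `pnorm(delta / sqrt(2))` with `delta` the Mahalanobis
#' distance between the processed class means. A pilot cohort is simulated,
#' the realized `delta` at the informative wavenumbers is measured on the
#' pre-treated spectra, and the `effect_scale` is scaled (with two fixpoint
#' refinements, since normalization makes the map mildly nonlinear) so the
#' realized distance equals `sqrt(2) * qnorm(target_auc)`.
#'
#' @param target_auc Target AUROC in (0.5, 1).
#' @param cfg A [cohort_config()] describing the cohort family; its
#'   `effect_scale` is the pilot starting point.
#' @param n_pilot Pilot cohort size.
#' @param refine Number of fixpoint refinement passes.
#' @return The calibrated `effect_scale` (numeric scalar, attribute
#'   `delta` = realized Mahalanobis distance at the returned scale).
#' @export
calibrate_effect <- function(target_auc, cfg = cohort_config(),
                             n_pilot = 3000, refine = 3) {
  if (target_auc <= 0.5 || target_auc >= 1) {
    abort("target_auc must lie in (0.5, 1)", class = "mirspec_domain_error")
  }
  delta_target <- sqrt(2) * qnorm(target_auc)
  scale <- if (cfg$effect_scale > 0) cfg$effect_scale else 1
  ratios <- numeric(0)
  for (pass in seq_len(refine + 1)) {
    pilot_cfg <- cfg
    pilot_cfg$n <- n_pilot
    pilot_cfg$effect_scale <- scale
    pilot_cfg$seed <- child_seed(cfg$seed, 1000 + pass)
    sim <- simulate_cohort(pilot_cfg)
    proc <- preprocess_spectra(sim$spectra)
    idx <- informative_columns(proc$grid, sim$truth)
    X <- proc$matrix[, idx, drop = FALSE]
    y <- proc$labels
    delta <- mahalanobis_delta(X, y, debias = TRUE)
    # near the target the map delta(scale) is close to proportional, so the
    # per-pilot ratios can be pooled to average out pilot sampling noise;
    # the first pass only positions the scale and is left out of the pool
    if (pass > 1 || refine == 0) ratios <- c(ratios, delta / scale)
    scale <- scale * delta_target / delta
  }
  scale <- delta_target / mean(ratios)
  structure(scale, delta = mean(ratios) * scale)
}

# Mahalanobis distance between class means under the pooled covariance.
# With debias = TRUE the usual finite-sample inflation of the squared
# distance is removed: E[d^2_hat] ~ (n-2)/(n-p-3) * (d^2 + p(1/n0 + 1/n1)).
mahalanobis_delta <- function(X, y, debias = FALSE) {
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  X0 <- sweep(X[y == 0L, , drop = FALSE], 2, m0)
  X1 <- sweep(X[y == 1L, , drop = FALSE], 2, m1)
  S <- (crossprod(X0) + crossprod(X1)) / (nrow(X) - 2)
  d <- m1 - m0
  d2 <- drop(crossprod(d, solve(S + diag(1e-12, ncol(S)), d)))
  if (debias) {
    n <- nrow(X); p <- ncol(X)
    n0 <- sum(y == 0L); n1 <- sum(y == 1L)
    d2 <- max(0, d2 * (n - p - 3) / (n - 2) - p * (1 / n0 + 1 / n1))
  }
  sqrt(d2)
}

#' MELD score
#'
#' Standard UNOS formula: `9.57 ln(creatinine) + 3.78 ln(bilirubin) +
#' 11.2 ln(INR) + 6.43`, arguments in mg/dL and floored at 1.0, creatinine
#' capped at 4.0 mg/dL; result rounded and capped to 6-40 points. Inputs in
#' laboratory units (creatinine umol/L, bilirubin umol/L) are converted
#' internally.
#'
#' @param creatinine Serum creatinine, umol/L.
#' @param bilirubin Total bilirubin, umol/L.
#' @param inr International normalized ratio.
#' @return Integer MELD score(s) in 6-40.
#' @export
compute_meld <- function(creatinine, bilirubin, inr) {
  if (any(creatinine <= 0) || any(bilirubin <= 0) || any(inr <= 0)) {
    abort("MELD inputs must be positive", class = "mirspec_domain_error")
  }
  creat <- pmin(pmax(creatinine / 88.4, 1), 4)    # umol/L -> mg/dL, floor/cap
  bili <- pmax(bilirubin / 17.1, 1)
  inr <- pmax(inr, 1)
  raw <- 9.57 * log(creat) + 3.78 * log(bili) + 11.2 * log(inr) + 6.43
  as.integer(pmin(pmax(round(raw), 6L), 40L))
}

#' Child-Pugh score
#'
#' Five components banded to 1-3 points each: bilirubin (<34 / 34-50 / >50
#' umol/L), albumin (>35 / 28-35 / <28 g/L), INR (<1.7 / 1.7-2.3 / >2.3),
#' ascites grade and encephalopathy grade (already 1-3). Total in 5-15.
#'
#' @param bilirubin Total bilirubin, umol/L.
#' @param albumin Serum albumin, g/L.
#' @param inr International normalized ratio.
#' @param ascites_grade 1 (none), 2 (mild/moderate), 3 (severe/refractory).
#' @param encephalopathy_grade 1 (none), 2 (grade I-II), 3 (grade III-IV).
#' @return Integer Child-Pugh score(s) in 5-15.
#' @export
compute_child_pugh <- function(bilirubin, albumin, inr,
                               ascites_grade, encephalopathy_grade) {
  if (any(!ascites_grade %in% 1:3) || any(!encephalopathy_grade %in% 1:3)) {
    abort("grades must be 1, 2 or 3", class = "mirspec_domain_error")
  }
  b <- ifelse(bilirubin < 34, 1L, ifelse(bilirubin <= 50, 2L, 3L))
  a <- ifelse(albumin > 35, 1L, ifelse(albumin >= 28, 2L, 3L))
  i <- ifelse(inr < 1.7, 1L, ifelse(inr <= 2.3, 2L, 3L))
  as.integer(b + a + i + ascites_grade + encephalopathy_grade)
}
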