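test_that("band library covers the marker wavenumbers inside the analysis domain", {
  bl <- default_band_library()
  markers <- bl[bl$class_shift != 0, ]
  expect_setequal(markers$center, c(2925, 1496, 1468, 1316, 1078, 1030, 972))
  expect_true(all(grepl("CH2", markers$assignment[markers$center == 2925])))
  expect_true("amide III, protein" %in% markers$assignment)
  # background amide I band is non-discriminative
  expect_equal(bl$class_shift[bl$center == 1650], 0)
  expect_gte(sum(bl$class_shift == 0), 8)
  # every marker centre survives the analysis-domain extraction
  in_domain <- (markers$center >= 962 & markers$center <= 1800) |
    (markers$center >= 2800 & markers$center <= 3188)
  expect_true(all(in_domain))
})

test_that("simulated spectra are reproducible pure Gaussians in the no-noise limit", {
  bl <- default_band_library()[5, ]   # one band
  bl$class_shift <- 0
  cfg <- cohort_config(n = 4, band_library = bl, noise_sd = 0,
                       baseline_order = 0, baseline_sd = 0,
                       group_jitter = c(marker = 0), jitter_idio = 0,
                       co2_amplitude = 0, seed = 5)
  s <- simulate_spectrum(0, cfg, index = 1)
  sig <- bl$fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(s$absorbance,
               bl$amplitude * exp(-0.5 * ((s$wavenumbers - bl$center) / sig)^2),
               tolerance = 1e-12)
  # determinism: identical (seed, index) gives identical draws
  s2 <- simulate_spectrum(0, cohort_config(seed = 9), index = 3)
  s3 <- simulate_spectrum(0, cohort_config(seed = 9), index = 3)
  expect_identical(s2$absorbance, s3$absorbance)
  expect_false(identical(
    s2$absorbance, simulate_spectrum(0, cohort_config(seed = 9), 4)$absorbance))
})

test_that("the CO2 artifact is annihilated by the gap bridge", {
  s <- simulate_spectrum(0, cohort_config(noise_sd = 0, baseline_sd = 0,
                                          co2_amplitude = 0.05, seed = 2))
  g <- replace_co2_gap(s)
  at2349 <- which(abs(g$wavenumbers - 2349) < 1)
  chord <- approx(c(1800, 2800),
                  s$absorbance[s$wavenumbers %in% c(1800, 2800)],
                  xout = g$wavenumbers[at2349])$y
  expect_equal(g$absorbance[at2349], chord, tolerance = 1e-12)
})

test_that("cohorts hit the exact mortality count and are seed-deterministic", {
  sim <- simulate_cohort(cohort_config(n = 116, seed = 13))
  expect_equal(sum(sim$spectra$labels), 23)
  expect_equal(sim$cohort$outcome, sim$spectra$labels)
  sim2 <- simulate_cohort(cohort_config(n = 116, seed = 13))
  expect_identical(sim$spectra$matrix, sim2$spectra$matrix)
  expect_identical(sim$cohort, sim2$cohort)
  expect_error(simulate_cohort(cohort_config(n = 10, prevalence = 0.01)),
               class = "mirspec_validation_error")
})

test_that("cohort covariates reproduce the per-class margins", {
  cfg <- cohort_config(n = 6000, seed = 17)
  sim <- simulate_cohort(cfg)
  dead <- sim$cohort[sim$cohort$outcome == 1, ]
  # deceased-group bilirubin mean 144.6 (SD 183.7), clamped below at 2;
  # clamping shifts the mean up slightly, so allow 4 SE plus clamp drift
  se <- 183.7 / sqrt(nrow(dead))
  expect_lt(abs(mean(dead$bilirubin) - 144.6), 4 * se + 8)
  alive <- sim$cohort[sim$cohort$outcome == 0, ]
  expect_lt(abs(mean(alive$albumin) - 30.0), 4 * 4.6 / sqrt(nrow(alive)))
  expect_true(all(sim$cohort$meld >= 6 & sim$cohort$meld <= 40))
  expect_true(all(sim$cohort$child_pugh >= 5 & sim$cohort$child_pugh <= 15))
})

test_that("all spectra of a default cohort pass the quality test", {
  sim <- simulate_cohort(cohort_config(n = 116, seed = 19))
  proc <- preprocess_spectra(sim$spectra)
  expect_equal(mean(attr(proc, "qc")$passed), 1)
})

test_that("calibrate_effect maps target AUROC to the closed-form distance", {
  # closed-form target mapping
  expect_equal(sqrt(2) * qnorm(pnorm(1)), sqrt(2), tolerance = 1e-12)
  expect_equal(sqrt(2) * qnorm(0.90), 1.8124, tolerance = 1e-4)
  expect_error(calibrate_effect(0.4), class = "mirspec_domain_error")
  expect_error(calibrate_effect(1.0), class = "mirspec_domain_error")
})

test_that("calibrated cohorts realize the requested separability", {
  es <- calibrate_effect(0.90, cohort_config(seed = 23),
                         n_pilot = 1500, refine = 2)
  # realized distance and empirical AUROC on a fresh large cohort
  cfg <- cohort_config(n = 3000, effect_scale = as.numeric(es), seed = 29)
  sim <- simulate_cohort(cfg)
  proc <- preprocess_spectra(sim$spectra)
  idx <- informative_cols(proc, sim$truth)
  expect_equal(mirspec:::mahalanobis_delta(proc$matrix[, idx], proc$labels,
                                           debias = TRUE),
               1.8124, tolerance = 0.12)
  fit <- fit_lda(proc$matrix[, idx], proc$labels)
  auc <- roc_auc(score_samples(fit, proc$matrix[, idx]), proc$labels)$auroc
  expect_gt(auc, 0.90 - 0.02)
  expect_lt(auc, 0.90 + 0.02)
})

test_that("MELD follows the UNOS formula with floors and caps", {
  # all arguments at/below the 1 mg/dL floors: 6.43 -> capped to 6
  expect_equal(compute_meld(80, 15, 0.9), 6L)
  # creatinine cap at 4 mg/dL: 8 mg/dL (707 umol/L) behaves as 4
  expect_equal(compute_meld(707.2, 171, 2), compute_meld(353.6, 171, 2))
  # hand-computed mid-range case
  cr <- 2 * 88.4; bi <- 3 * 17.1; inr <- 1.8
  raw <- 9.57 * log(2) + 3.78 * log(3) + 11.2 * log(1.8) + 6.43
  expect_equal(compute_meld(cr, bi, inr), as.integer(round(raw)))
  expect_error(compute_meld(-1, 10, 1), class = "mirspec_domain_error")
})

test_that("Child-Pugh bands sum to the familiar 5-15 score", {
  expect_equal(compute_child_pugh(10, 40, 1.2, 1, 1), 5L)
  expect_equal(compute_child_pugh(60, 20, 3.0, 3, 3), 15L)
  # 40 umol/L (2) + 30 g/L (2) + INR 1.8 (2) + moderate ascites (2) + none (1)
  expect_equal(compute_child_pugh(40, 30, 1.8, 2, 1), 9L)
  expect_error(compute_child_pugh(40, 30, 1.8, 4, 1),
               class = "mirspec_domain_error")
})
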