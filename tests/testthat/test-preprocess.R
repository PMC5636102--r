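cfgp <- preprocess_config()

test_that("work-domain restriction yields the 1126-point 950-3200 grid", {
  wn <- seq(400, 4000, by = 2)
  s <- new_spectrum("s", wn, sin(wn / 100))
  r <- restrict_to_work_domain(s, cfgp)
  expect_equal(length(r$wavenumbers), 1126)
  expect_equal(range(r$wavenumbers), c(950, 3200))
  # already-restricted input is untouched
  expect_equal(restrict_to_work_domain(r, cfgp), r)
  # insufficient coverage errors
  s2 <- new_spectrum("s", seq(1000, 3000, 2), rep(1, 1001))
  expect_error(restrict_to_work_domain(s2, cfgp),
               class = "mirspec_coverage_error")
})

test_that("CO2 gap bridging interpolates the open interval and is idempotent", {
  wn <- seq(950, 3200, by = 2)
  a <- rep(0.4, length(wn))
  a[wn > 1800] <- 0.2
  a[wn == 1800] <- 0.4
  a[wn == 2300] <- 5        # spike inside the gap
  s <- new_spectrum("s", wn, a)
  g <- replace_co2_gap(s, cfgp)
  # chord from (1800, 0.4) to (2800, 0.2): midpoint at 2300 = 0.3
  expect_equal(g$absorbance[wn == 2300], 0.3)
  expect_equal(g$absorbance[wn == 1800], 0.4)
  expect_equal(g$absorbance[wn == 2800], 0.2)
  expect_equal(replace_co2_gap(g, cfgp)$absorbance, g$absorbance)
  # constant spectrum is unchanged
  cst <- new_spectrum("c", wn, rep(1, length(wn)))
  expect_equal(replace_co2_gap(cst, cfgp)$absorbance, cst$absorbance)
})

test_that("Savitzky-Golay second derivative is exact for quadratics and lines", {
  wn <- seq(950, 3200, by = 2)
  quad <- new_spectrum("q", wn, (wn / 100)^2)
  dq <- second_derivative(quad, cfgp)
  expect_equal(length(dq$wavenumbers), 1126 - 12)
  expect_equal(range(dq$wavenumbers), c(962, 3188))
  expect_equal(dq$absorbance, rep(2 / 100^2, 1114), tolerance = 1e-10)
  lin <- new_spectrum("l", wn, 3 * wn + 7)
  expect_lt(max(abs(second_derivative(lin, cfgp)$absorbance)), 1e-9)
})

test_that("second derivative is a linear operator", {
  wn <- seq(950, 3200, by = 2)
  set.seed(1)
  f <- new_spectrum("f", wn, rnorm(length(wn)))
  g <- new_spectrum("g", wn, rnorm(length(wn)))
  fg <- new_spectrum("fg", wn, 2 * f$absorbance - 3 * g$absorbance)
  d <- function(s) second_derivative(replace_co2_gap(
    new_spectrum(s$sample_id, s$wavenumbers,
                 s$absorbance + seq_along(s$absorbance) * 0),
    cfgp), cfgp)$absorbance
  lhs <- second_derivative(replace_co2_gap(fg, cfgp), cfgp)$absorbance
  rhs <- 2 * second_derivative(replace_co2_gap(f, cfgp), cfgp)$absorbance -
    3 * second_derivative(replace_co2_gap(g, cfgp), cfgp)$absorbance
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("analysis-domain extraction keeps exactly 615 variables", {
  s <- demo_spectrum(seed = 5)
  d <- second_derivative(replace_co2_gap(restrict_to_work_domain(s)), cfgp)
  a <- extract_analysis_domain(d, cfgp)
  expect_equal(length(a$wavenumbers), 615)
  expect_equal(sum(a$wavenumbers <= 1800), 420)
  expect_equal(sum(a$wavenumbers >= 2800), 195)
  expect_true(1800 %in% a$wavenumbers)   # gap endpoints retained
  expect_true(2800 %in% a$wavenumbers)
  expect_false(any(a$wavenumbers > 1800 & a$wavenumbers < 2800))
})

test_that("vector normalization gives unit norm, scale invariance, errors on zero", {
  s <- demo_spectrum(seed = 6)
  a <- extract_analysis_domain(second_derivative(replace_co2_gap(
    restrict_to_work_domain(s))))
  v <- vector_normalize(a)
  expect_equal(sqrt(sum(v$absorbance^2)), 1, tolerance = 1e-12)
  a2 <- a; a2$absorbance <- 7.3 * a$absorbance
  expect_equal(vector_normalize(a2)$absorbance, v$absorbance,
               tolerance = 1e-12)
  toy <- a; toy$absorbance <- c(3, 4, rep(0, 613))
  expect_equal(vector_normalize(toy)$absorbance[1:2], c(0.6, 0.8))
  z <- a; z$absorbance <- rep(0, 615)
  expect_error(vector_normalize(z), class = "mirspec_degenerate_error")
})

test_that("the full chain maps any conforming raw spectrum to a unit 615-vector", {
  sim <- simulate_cohort(cohort_config(n = 12, seed = 21))
  proc <- preprocess_spectra(sim$spectra)
  expect_equal(ncol(proc$matrix), 615)
  expect_equal(unname(apply(proc$matrix, 1, function(r) sqrt(sum(r^2)))),
               rep(1, 12), tolerance = 1e-10)
  expect_equal(proc$labels, sim$spectra$labels)
})

test_that("quality test passes clean spectra and flags pathologies", {
  s <- demo_spectrum(seed = 9)
  qc <- quality_test(s)
  expect_true(qc$passed)
  expect_identical(qc$reasons, "")
  # detector saturation
  s2 <- s; s2$absorbance <- s$absorbance * 100
  qc2 <- quality_test(s2)
  expect_false(qc2$passed)
  expect_match(qc2$reasons, "signal_too_high")
  # excessive noise
  set.seed(2)
  s3 <- s
  s3$absorbance <- s3$absorbance + rnorm(length(s3$absorbance), 0, 0.02)
  expect_match(quality_test(s3)$reasons, "noise_too_high")
})

test_that("PCA outlier screen is calibrated and catches planted outliers", {
  set.seed(31)
  n <- 200
  X <- matrix(rnorm(n * 40), n, 40)
  set1 <- new_spectra_set(sprintf("s%03d", 1:n),
                          seq(1000, by = 2, length.out = 40), X)
  flagged <- pca_outlier_screen(set1)
  # nominal rate 2.5%: expect about 5 of 200, within ~3 binomial Sds
  expect_lte(length(flagged), 12)
  # plant a gross outlier along the first principal axis
  pc1 <- prcomp(X)$rotation[, 1]
  X2 <- X
  X2[7, ] <- X2[7, ] + 10 * sd(prcomp(X)$x[, 1]) * pc1
  set2 <- new_spectra_set(set1$samples, set1$grid, X2)
  expect_true("s007" %in% pca_outlier_screen(set2))
  # contract: more components than samples
  small <- new_spectra_set(sprintf("t%d", 1:5),
                           seq(1000, by = 2, length.out = 40), X[1:5, ])
  expect_error(pca_outlier_screen(small), class = "mirspec_validation_error")
})
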