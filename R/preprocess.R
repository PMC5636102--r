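# Pre-treatment chain for serum MIR absorbance spectra:
# work-domain restriction -> CO2 gap bridging -> Savitzky-Golay second
# derivative -> analysis-domain extraction -> vector normalization,
# plus quality control and a PCA outlier screen.

#' Pre-treatment configuration
#'
#' Defaults reproduce the standard serum fingerprint workflow: a 3200-950
#' cm^-1 working domain on a 2 cm^-1 grid, the ambient-CO2 region 2800-1800
#' cm^-1 bridged by a straight line, a 13-point Savitzky-Golay second
#' derivative (polynomial order 2, no edge padding), and unit-Euclidean-norm
#' scaling of the resulting 615-point analysis vector.
#'
#' @param grid_step Grid spacing in cm^-1.
#' @param work_domain Closed working interval, cm^-1 (stored ascending).
#' @param gap Open interval replaced by a chord to suppress CO2 interference.
#' @param sg_window Savitzky-Golay window length (odd, > `sg_polyorder`).
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param qc_signal_band Band whose peak absorbance must sit in the detector
#'   range, cm^-1.
#' @param qc_signal_range Acceptable peak absorbance, AU.
#' @param qc_noise_band Band whose detrended RMS measures noise, cm^-1.
#' @param qc_noise_max Maximum acceptable noise RMS, AU.
#' @param pca_components Number of leading components in the outlier screen.
#' @param pca_alpha Nominal flagging rate of the Hotelling T-squared screen.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(grid_step = 2,
                              work_domain = c(950, 3200),
                              gap = c(1800, 2800),
                              sg_window = 13,
                              sg_polyorder = 2,
                              qc_signal_band = c(1600, 1700),
                              qc_signal_range = c(0.05, 2.0),
                              qc_noise_band = c(2000, 2200),
                              qc_noise_max = 0.005,
                              pca_components = 10,
                              pca_alpha = 0.025) {
  work_domain <- sort(work_domain)
  gap <- sort(gap)
  stopifnot(grid_step > 0,
            sg_window %% 2 == 1, sg_window > sg_polyorder,
            gap[1] > work_domain[1], gap[2] < work_domain[2])
  structure(list(grid_step = grid_step, work_domain = work_domain, gap = gap,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 qc_signal_band = qc_signal_band,
                 qc_signal_range = qc_signal_range,
                 qc_noise_band = qc_noise_band, qc_noise_max = qc_noise_max,
                 pca_components = pca_components, pca_alpha = pca_alpha),
            class = "preprocess_config")
}

check_grid_step <- function(s, cfg) {
  if (any(abs(diff(s$wavenumbers) - cfg$grid_step) > 1e-8)) {
    abort(sprintf("grid spacing must be %g cm^-1", cfg$grid_step),
          class = "mirspec_grid_error")
  }
}

#' Restrict a spectrum to the working domain
#'
#' Keeps the contiguous 950-3200 cm^-1 stretch (1126 points at 2 cm^-1).
#'
#' @param s A `mir_spectrum` covering the working domain.
#' @param cfg A [preprocess_config()].
#' @return The restricted `mir_spectrum`; stage unchanged.
#' @export
restrict_to_work_domain <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "mir_spectrum"))
  check_grid_step(s, cfg)
  lo <- cfg$work_domain[1]; hi <- cfg$work_domain[2]
  if (min(s$wavenumbers) > lo + 1e-9 || max(s$wavenumbers) < hi - 1e-9) {
    abort(sprintf("grid %.0f-%.0f does not cover [%g, %g]",
                  min(s$wavenumbers), max(s$wavenumbers), lo, hi),
          class = "mirspec_coverage_error")
  }
  keep <- s$wavenumbers >= lo - 1e-9 & s$wavenumbers <= hi + 1e-9
  new_spectrum(s$sample_id, s$wavenumbers[keep], s$absorbance[keep],
               stage = s$stage)
}

#' Bridge the CO2 gap with a straight line
#'
#' Replaces the absorbance strictly inside the gap (default 2800-1800 cm^-1)
#' by linear interpolation between the values at the gap endpoints,
#' eliminating ambient-air CO2 interference. Endpoints are preserved
#' verbatim; the operation is idempotent.
#'
#' @inheritParams restrict_to_work_domain
#' @return The gap-bridged `mir_spectrum`, stage `"gap_replaced"`.
#' @export
replace_co2_gap <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "mir_spectrum"))
  lo <- cfg$gap[1]; hi <- cfg$gap[2]
  i_lo <- which(abs(s$wavenumbers - lo) < 1e-9)
  i_hi <- which(abs(s$wavenumbers - hi) < 1e-9)
  if (length(i_lo) != 1L || length(i_hi) != 1L) {
    abort(sprintf("gap endpoints %g and %g must lie on the grid", lo, hi),
          class = "mirspec_grid_error")
  }
  inside <- s$wavenumbers > lo & s$wavenumbers < hi
  a <- s$absorbance
  a[inside] <- a[i_lo] + (a[i_hi] - a[i_lo]) *
    (s$wavenumbers[inside] - lo) / (hi - lo)
  new_spectrum(s$sample_id, s$wavenumbers, a, stage = "gap_replaced")
}

# Central Savitzky-Golay derivative coefficients, scaled for the grid step.
sg_coefficients <- function(window, polyorder, deriv, step) {
  F <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = step)
  unclass(F)[(window + 1L) / 2L, ]
}

#' Savitzky-Golay second derivative
#'
#' Applies a single smoothed second-derivative filter (window 13, polynomial
#' order 2 by default), scaled by 1/step^2 so values carry AU/(cm^-1)^2
#' units. No edge padding: (window-1)/2 points are dropped at each end, so
#' 1126 points in give 1114 out. Exact for polynomials up to the filter
#' order: the second derivative of a quadratic is recovered without error.
#'
#' @param s A gap-bridged `mir_spectrum` (length >= window).
#' @param cfg A [preprocess_config()].
#' @return The derivative `mir_spectrum`, stage `"derivative"`.
#' @export
second_derivative <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "mir_spectrum"))
  check_grid_step(s, cfg)
  n <- length(s$absorbance)
  w <- cfg$sg_window
  if (n < w) {
    abort(sprintf("spectrum length %d below filter window %d", n, w),
          class = "mirspec_grid_error")
  }
  co <- sg_coefficients(w, cfg$sg_polyorder, 2L, cfg$grid_step)
  half <- (w - 1L) / 2L
  # filter() applies the window centred on each point; embed() is fastest here
  segs <- stats::embed(s$absorbance, w)   # rows: reversed windows
  d2 <- as.vector(segs %*% rev(co))
  keep <- seq.int(half + 1L, n - half)
  new_spectrum(s$sample_id, s$wavenumbers[keep], d2, stage = "derivative")
}

#' Extract the analysis domain
#'
#' Keeps derivative points in [962, 1800] and [2800, 3188] cm^-1: the
#' edge-trimmed working domain minus the open CO2 gap, whose endpoints are
#' retained. On the standard grid this yields exactly 615 variables
#' (420 + 195).
#'
#' @inheritParams second_derivative
#' @return The restricted `mir_spectrum`.
#' @export
extract_analysis_domain <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "mir_spectrum"))
  if (!identical(s$stage, "derivative")) {
    abort("extract_analysis_domain expects a derivative spectrum",
          class = "mirspec_stage_error")
  }
  half <- (cfg$sg_window - 1L) / 2L
  lo <- cfg$work_domain[1] + half * cfg$grid_step
  hi <- cfg$work_domain[2] - half * cfg$grid_step
  if (abs(min(s$wavenumbers) - lo) > 1e-9 || abs(max(s$wavenumbers) - hi) > 1e-9) {
    abort(sprintf("unexpected derivative grid %.0f-%.0f (expected %g-%g)",
                  min(s$wavenumbers), max(s$wavenumbers), lo, hi),
          class = "mirspec_grid_error")
  }
  wn <- s$wavenumbers
  keep <- (wn <= cfg$gap[1] + 1e-9) | (wn >= cfg$gap[2] - 1e-9)
  new_spectrum(s$sample_id, wn[keep], s$absorbance[keep], stage = "derivative")
}

#' Vector normalization
#'
#' Scales the analysis-domain derivative vector to unit Euclidean norm,
#' removing optical-pathlength and amount effects while preserving direction.
#'
#' @param s A `mir_spectrum` (derivative, analysis domain).
#' @return The normalized `mir_spectrum`, stage `"normalized"`.
#' @export
vector_normalize <- function(s) {
  stopifnot(inherits(s, "mir_spectrum"))
  nrm <- sqrt(sum(s$absorbance^2))
  if (nrm == 0) {
    abort("cannot normalize an all-zero spectrum",
          class = "mirspec_degenerate_error")
  }
  new_spectrum(s$sample_id, s$wavenumbers, s$absorbance / nrm,
               stage = "normalized")
}

#' Spectrum quality test
#'
#' Screens a raw spectrum before modelling: (i) peak absorbance in the
#' protein signal band (1700-1600 cm^-1) must sit inside the detector range;
#' (ii) the RMS of the linearly detrended, band-free noise window
#' (2200-2000 cm^-1) must not exceed `qc_noise_max`; (iii) all values finite.
#' Thresholds are configurable; the defaults describe a well-conditioned
#' FTIR serum measurement.
#'
#' @param raw A raw `mir_spectrum` on the working domain.
#' @param cfg A [preprocess_config()].
#' @return A one-row tibble: `sample_id`, `passed`, `signal_amplitude`,
#'   `noise_rms`, `reasons` (comma-separated codes, empty iff passed).
#' @export
quality_test <- function(raw, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "mir_spectrum"))
  reasons <- character(0)
  wn <- raw$wavenumbers; a <- raw$absorbance
  sig_idx <- wn >= cfg$qc_signal_band[1] & wn <= cfg$qc_signal_band[2]
  sig <- max(a[sig_idx])
  if (sig < cfg$qc_signal_range[1]) reasons <- c(reasons, "signal_too_low")
  if (sig > cfg$qc_signal_range[2]) reasons <- c(reasons, "signal_too_high")
  noise_idx <- wn >= cfg$qc_noise_band[1] & wn <= cfg$qc_noise_band[2]
  x <- wn[noise_idx]; y <- a[noise_idx]
  res <- stats::lm.fit(cbind(1, x), y)$residuals
  noise <- sqrt(mean(res^2))
  if (noise > cfg$qc_noise_max) reasons <- c(reasons, "noise_too_high")
  if (any(!is.finite(a))) reasons <- c(reasons, "non_finite")
  tibble::tibble(sample_id = raw$sample_id,
                 passed = length(reasons) == 0L,
                 signal_amplitude = sig,
                 noise_rms = noise,
                 reasons = paste(reasons, collapse = ","))
}

#' PCA outlier screen (Hotelling T-squared)
#'
#' Automates the visual PCA homogeneity check: samples whose Hotelling
#' T-squared over the first `pca_components` scores exceeds the
#' (1 - `pca_alpha`) quantile of the F-based reference distribution are
#' flagged. Deterministic; flagged samples are reported, not removed.
#'
#' @param x A `mir_spectra_set` of normalized spectra (>= 10 samples).
#' @param cfg A [preprocess_config()].
#' @return Character vector of flagged sample ids.
#' @export
pca_outlier_screen <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "mir_spectra_set"))
  n <- length(x$samples)
  k <- cfg$pca_components
  if (n <= k) {
    abort(sprintf("need more samples (%d) than components (%d)", n, k),
          class = "mirspec_validation_error")
  }
  pc <- prcomp(x$matrix, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  t2 <- rowSums(sweep(pc$x[, seq_len(k), drop = FALSE]^2, 2,
                      pc$sdev[seq_len(k)]^2, "/"))
  crit <- k * (n - 1) * (n + 1) / (n * (n - k)) *
    qf(1 - cfg$pca_alpha, k, n - k)
  x$samples[t2 > crit]
}

#' Run the full pre-treatment chain on a set of spectra
#'
#' restrict -> CO2 gap bridge -> Savitzky-Golay second derivative ->
#' analysis-domain extraction -> vector normalization, applied per spectrum.
#' The output matrix has exactly 615 columns on the standard grid.
#'
#' @param x A raw `mir_spectra_set` covering the working domain.
#' @param cfg A [preprocess_config()].
#' @return A `mir_spectra_set` of unit-norm analysis vectors with a `qc`
#'   attribute holding the per-sample [quality_test()] table.
#' @export
preprocess_spectra <- function(x, cfg = preprocess_config()) {
  stopifnot(inherits(x, "mir_spectra_set"))
  restricted <- map_spectra(x, restrict_to_work_domain, cfg = cfg)
  qc <- dplyr::bind_rows(lapply(seq_along(restricted$samples), function(i) {
    quality_test(get_spectrum(restricted, i), cfg)
  }))
  out <- map_spectra(restricted, function(s) {
    vector_normalize(
      extract_analysis_domain(
        second_derivative(
          replace_co2_gap(s, cfg), cfg), cfg))
  })
  attr(out, "qc") <- qc
  out
}
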