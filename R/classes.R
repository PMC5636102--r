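#' Single mid-infrared spectrum
#'
#' Lightweight container for one absorbance spectrum. Wavenumbers are stored
#' ascending in cm^-1; plots may display them descending, as spectroscopists
#' expect. The `stage` field tracks the pre-treatment state of the values.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param wavenumbers Numeric vector of strictly monotonic wavenumbers (cm^-1).
#'   Descending input is reversed to ascending storage.
#' @param absorbance Numeric vector of the same length (absorbance units).
#' @param stage One of `"raw"`, `"gap_replaced"`, `"derivative"`, `"normalized"`.
#' @return An object of class `mir_spectrum`.
#' @export
new_spectrum <- function(sample_id, wavenumbers, absorbance, stage = "raw") {
  stage <- match.arg(stage, c("raw", "gap_replaced", "derivative", "normalized"))
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    abort("wavenumbers and absorbance must have equal length",
          class = "mirspec_format_error")
  }
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
    d <- -rev(d)
  }
  if (any(d <= 0)) {
    abort("wavenumbers must be strictly monotonic",
          class = "mirspec_format_error")
  }
  if (any(!is.finite(absorbance)) || any(!is.finite(wavenumbers))) {
    abort("non-finite values in spectrum", class = "mirspec_format_error")
  }
  structure(
    list(sample_id = as.character(sample_id),
         wavenumbers = wavenumbers,
         absorbance = absorbance,
         stage = stage),
    class = "mir_spectrum"
  )
}

#' @export
print.mir_spectrum <- function(x, ...) {
  cat(sprintf("<mir_spectrum> %s: %d points, %.0f-%.0f cm^-1, stage %s\n",
              x$sample_id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers), x$stage))
  invisible(x)
}

#' @export
tidy.mir_spectrum <- function(x, ...) {
  tibble::tibble(sample_id = x$sample_id,
                 wavenumber = x$wavenumbers,
                 absorbance = x$absorbance,
                 stage = x$stage)
}

#' Aligned set of spectra
#'
#' A sample-by-wavenumber absorbance matrix on a shared ascending grid, with
#' optional binary 6-month outcome labels (0 = alive, 1 = deceased).
#'
#' @param samples Character vector of unique sample ids (row order).
#' @param grid Shared ascending wavenumber grid (cm^-1).
#' @param matrix Numeric matrix, `length(samples)` rows by `length(grid)`
#'   columns.
#' @param labels Optional integer vector of 0/1 outcomes, one per sample.
#' @param stage Pre-treatment stage shared by all rows.
#' @return An object of class `mir_spectra_set`.
#' @export
new_spectra_set <- function(samples, grid, matrix, labels = NULL,
                            stage = "raw") {
  samples <- as.character(samples)
  grid <- as.numeric(grid)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (anyDuplicated(samples)) {
    abort("duplicate sample ids", class = "mirspec_format_error")
  }
  if (nrow(matrix) != length(samples) || ncol(matrix) != length(grid)) {
    abort("matrix dimensions do not match samples/grid",
          class = "mirspec_format_error")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    o <- order(grid)
    grid <- grid[o]
    matrix <- matrix[, o, drop = FALSE]
    if (is.unsorted(grid, strictly = TRUE)) {
      abort("grid has duplicate wavenumbers", class = "mirspec_format_error")
    }
  }
  if (any(!is.finite(matrix))) {
    abort("non-finite absorbance values", class = "mirspec_format_error")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(samples) || !all(labels %in% c(0L, 1L))) {
      abort("labels must be one 0/1 value per sample",
            class = "mirspec_label_error")
    }
  }
  dimnames(matrix) <- list(samples, format(grid, trim = TRUE))
  structure(
    list(samples = samples, grid = grid, matrix = matrix,
         labels = labels, stage = stage),
    class = "mir_spectra_set"
  )
}

#' @export
print.mir_spectra_set <- function(x, ...) {
  cat(sprintf(
    "<mir_spectra_set> %d spectra x %d wavenumbers (%.0f-%.0f cm^-1), stage %s%s\n",
    length(x$samples), length(x$grid), min(x$grid), max(x$grid), x$stage,
    if (is.null(x$labels)) "" else
      sprintf(", %d deceased / %d alive", sum(x$labels), sum(1 - x$labels))))
  invisible(x)
}

#' @export
tidy.mir_spectra_set <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$samples, each = length(x$grid)),
    wavenumber = rep(x$grid, times = length(x$samples)),
    absorbance = as.vector(t(x$matrix)),
    stage = x$stage
  )
}

#' @export
as.matrix.mir_spectra_set <- function(x, ...) x$matrix

# Extract the i-th spectrum of a set.
#' Extract one spectrum from a set
#' @param x A `mir_spectra_set`.
#' @param i Row index or sample id.
#' @return A `mir_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  stopifnot(inherits(x, "mir_spectra_set"))
  if (is.character(i)) i <- match(i, x$samples)
  new_spectrum(x$samples[i], x$grid, x$matrix[i, ], stage = x$stage)
}

# Apply a per-spectrum operation to every row of a set, preserving labels.
map_spectra <- function(x, f, ...) {
  specs <- lapply(seq_along(x$samples), function(i) f(get_spectrum(x, i), ...))
  grid <- specs[[1]]$wavenumbers
  mat <- do.call(rbind, lapply(specs, `[[`, "absorbance"))
  new_spectra_set(x$samples, grid, mat, labels = x$labels,
                  stage = specs[[1]]$stage)
}

# Columns the cohort table must carry, with physiological ranges used both
# for validation and as clamping floors in the generator.
cohort_columns <- function() {
  tibble::tribble(
    ~column,              ~unit,      ~min,  ~max,
    "age",                "years",      18,   110,
    "sex",                "F/M",        NA,    NA,
    "creatinine",         "umol/L",      10,  2000,
    "albumin",            "g/L",         10,    60,
    "bilirubin",          "umol/L",       2,  1000,
    "prothrombin_ratio",  "%",           5,   150,
    "inr",                "ratio",      0.8,    10,
    "sodium",             "mmol/L",    110,   160,
    "ast",                "IU/L",         5,  3000,
    "alt",                "IU/L",         5,  3000,
    "ggt",                "IU/L",         5,  3000,
    "crp",                "mg/L",         0,   500,
    "alp",                "IU/L",        10,  2000,
    "beta_blockers",      "bool",        NA,    NA,
    "meld",               "points",       6,    40,
    "child_pugh",         "points",       5,    15,
    "outcome",            "0/1",          0,     1
  )
}

#' Validate a cohort table
#'
#' Checks that a clinical covariate table carries the expected columns with
#' in-range values (MELD in 6-40, Child-Pugh in 5-15, 0/1 outcome). Unknown
#' columns are carried through untouched.
#'
#' @param data A data frame of per-sample clinical covariates.
#' @param require_outcome If `TRUE` (default) an `outcome` column is required.
#' @return The validated table as a tibble of class `mir_cohort`.
#' @export
validate_cohort <- function(data, require_outcome = TRUE) {
  data <- tibble::as_tibble(data)
  spec <- cohort_columns()
  need <- setdiff(spec$column, c("outcome", names(data)))
  if (length(need) > 0) {
    abort(paste0("missing cohort columns: ", paste(need, collapse = ", ")),
          class = "mirspec_validation_error")
  }
  if (require_outcome && !"outcome" %in% names(data)) {
    abort("outcome column required but absent",
          class = "mirspec_validation_error")
  }
  for (i in seq_len(nrow(spec))) {
    cl <- spec$column[i]
    if (!cl %in% names(data) || is.na(spec$min[i])) next
    v <- data[[cl]]
    bad <- which(is.finite(v) & (v < spec$min[i] | v > spec$max[i]))
    if (length(bad) > 0) {
      abort(sprintf("column %s out of range [%g, %g] in row %d (value %g)",
                    cl, spec$min[i], spec$max[i], bad[1], v[bad[1]]),
            class = "mirspec_validation_error")
    }
  }
  if ("outcome" %in% names(data) && !all(data$outcome %in% c(0, 1))) {
    abort("outcome must be 0/1", class = "mirspec_validation_error")
  }
  class(data) <- c("mir_cohort", class(data))
  data
}
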