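# Readers/writers for the package's plain-text exchange formats:
# wide CSV spectral matrices, delimited cohort tables, JCAMP-DX spectra.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    abort("empty file", class = "mirspec_format_error")
  }
  n_semi <- lengths(regmatches(first, gregexpr(";", first)))
  n_comma <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_semi > n_comma) ";" else ","
}

#' Read a spectral matrix from CSV
#'
#' Expects a wide layout: first row the wavenumber grid (ascending or
#' descending), first column the sample ids, numeric absorbance body.
#' Comma or semicolon delimiters are auto-detected; decimal separator is
#' always the point. An optional `outcome` column in a companion cohort table
#' supplies labels via [attach_labels()].
#'
#' @param path Path to the CSV file.
#' @return A [new_spectra_set()] object with an ascending grid (columns are
#'   reordered if the file is descending).
#' @export
read_spectra_csv <- function(path) {
  delim <- detect_delim(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, delim, fixed = TRUE)
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L) {
    abort(sprintf("ragged rows: row lengths %s",
                  paste(unique(lens), collapse = ", ")),
          class = "mirspec_format_error")
  }
  header <- cells[[1]]
  grid <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(grid))) {
    abort("header row must be numeric wavenumbers",
          class = "mirspec_parse_error")
  }
  body <- cells[-1]
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample id: %s", ids[duplicated(ids)][1]),
          class = "mirspec_format_error")
  }
  mat <- matrix(NA_real_, length(body), length(grid))
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]][-1]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      abort(sprintf("non-numeric cell at row %d (sample %s), column %d",
                    r + 1L, ids[r], bad + 1L),
            class = "mirspec_parse_error")
    }
    mat[r, ] <- v
  }
  new_spectra_set(ids, grid, mat)
}

#' Write a spectral matrix to CSV
#'
#' Inverse of [read_spectra_csv()]: wavenumber header row, sample-id first
#' column, comma delimiter, numbers at full precision (round-trips values to
#' at least 10 significant digits).
#'
#' @param x A `mir_spectra_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "mir_spectra_set"))
  header <- paste(c("sample_id", format(x$grid, trim = TRUE)), collapse = ",")
  rows <- vapply(seq_along(x$samples), function(i) {
    paste(c(x$samples[i],
            formatC(x$matrix[i, ], format = "g", digits = 15)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Attach outcome labels from a cohort table
#'
#' @param x A `mir_spectra_set`.
#' @param cohort A cohort table with `sample_id` and `outcome` columns.
#' @return `x` with labels filled in, rows matched by sample id.
#' @export
attach_labels <- function(x, cohort) {
  stopifnot(inherits(x, "mir_spectra_set"))
  if (!all(c("sample_id", "outcome") %in% names(cohort))) {
    abort("cohort must carry sample_id and outcome",
          class = "mirspec_validation_error")
  }
  m <- match(x$samples, cohort$sample_id)
  if (anyNA(m)) {
    abort("spectra contain sample ids absent from the cohort table",
          class = "mirspec_validation_error")
  }
  new_spectra_set(x$samples, x$grid, x$matrix,
                  labels = cohort$outcome[m], stage = x$stage)
}

#' Read a clinical cohort table
#'
#' Reads a comma- or semicolon-delimited table whose header names the
#' clinical covariates (age, sex, creatinine, albumin, bilirubin,
#' prothrombin_ratio, inr, sodium, ast, alt, ggt, crp, alp, beta_blockers,
#' meld, child_pugh) plus `sample_id` and optionally `outcome`. Unknown
#' columns are carried through unchanged.
#'
#' @param path Path to the delimited file.
#' @param require_outcome Require an `outcome` column (default `TRUE`).
#' @return A validated `mir_cohort` tibble.
#' @export
read_cohort_table <- function(path, require_outcome = TRUE) {
  delim <- detect_delim(path)
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  validate_cohort(data, require_outcome = require_outcome)
}

#' Write a cohort table to CSV
#' @param data A cohort table (data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

# ---- JCAMP-DX ---------------------------------------------------------------

jdx_records <- function(lines) {
  # Collapse the file into labelled data records (##LABEL=value + payload).
  starts <- grep("^##", lines)
  recs <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    head <- sub("^##([^=]*)=(.*)$", "\\1\r\\2", lines[from])
    parts <- strsplit(head, "\r", fixed = TRUE)[[1]]
    label <- toupper(gsub("[ _-]", "", parts[1]))
    value <- if (length(parts) > 1) trimws(parts[2]) else ""
    recs[[label]] <- list(value = value,
                          payload = lines[seq.int(from + 1L, length.out = max(0L, to - from))])
  }
  recs
}

#' Read a JCAMP-DX spectrum
#'
#' Parses a single-spectrum JCAMP-DX 4.24 file with an AFFN (plain numeric)
#' `##XYDATA=(X++(Y..Y))` table or `##XYPOINTS` pairs. X values are
#' reconstructed from FIRSTX/LASTX/NPOINTS with Y scaled by YFACTOR; only
#' `##XUNITS=1/CM` is supported. Compressed (SQZ/DIF) tables are not.
#'
#' @param path Path to the JCAMP-DX file.
#' @return A [new_spectrum()] with ascending wavenumbers.
#' @export
read_jcampdx <- function(path) {
  lines <- trimws(readLines(path))
  recs <- jdx_records(lines)
  if (is.null(recs$XUNITS)) {
    abort("missing ##XUNITS record", class = "mirspec_format_error")
  }
  if (toupper(recs$XUNITS$value) != "1/CM") {
    abort(sprintf("unsupported XUNITS: %s (only 1/CM)", recs$XUNITS$value),
          class = "mirspec_unit_error")
  }
  title <- if (!is.null(recs$TITLE)) recs$TITLE$value else basename(path)
  yfac <- if (!is.null(recs$YFACTOR)) as.numeric(recs$YFACTOR$value) else 1
  xfac <- if (!is.null(recs$XFACTOR)) as.numeric(recs$XFACTOR$value) else 1

  if (!is.null(recs$XYDATA)) {
    payload <- recs$XYDATA$payload
    payload <- payload[nzchar(payload) & !startsWith(payload, "##")]
    if (grepl("SQZ|DIF|DUP", recs$XYDATA$value, ignore.case = TRUE) ||
        any(grepl("[@%A-Za-z]", gsub("[eE][+-]?[0-9]+", "", payload)))) {
      abort("compressed (SQZ/DIF) JCAMP tables are not supported",
            class = "mirspec_format_error")
    }
    if (is.null(recs$FIRSTX) || is.null(recs$NPOINTS)) {
      abort("XYDATA requires ##FIRSTX and ##NPOINTS",
            class = "mirspec_format_error")
    }
    firstx <- as.numeric(recs$FIRSTX$value) * xfac
    npts <- as.integer(recs$NPOINTS$value)
    deltax <- if (!is.null(recs$DELTAX)) {
      as.numeric(recs$DELTAX$value)
    } else if (!is.null(recs$LASTX)) {
      (as.numeric(recs$LASTX$value) * xfac - firstx) / (npts - 1)
    } else {
      abort("XYDATA requires ##DELTAX or ##LASTX",
            class = "mirspec_format_error")
    }
    ys <- numeric(0)
    for (ln in payload) {
      num <- strsplit(ln, "[,;[:space:]]+")[[1]]
      num <- num[nzchar(num)]
      # first number on each line is the line's X check value; the rest are Y
      ys <- c(ys, as.numeric(num[-1]))
    }
    if (length(ys) < npts) {
      abort(sprintf("XYDATA has %d Y values, NPOINTS says %d",
                    length(ys), npts),
            class = "mirspec_format_error")
    }
    ys <- ys[seq_len(npts)]
    x <- firstx + deltax * (seq_len(npts) - 1)
    y <- ys * yfac
  } else if (!is.null(recs$XYPOINTS)) {
    payload <- recs$XYPOINTS$payload
    payload <- payload[nzchar(payload) & !startsWith(payload, "##")]
    num <- as.numeric(unlist(strsplit(paste(payload, collapse = " "),
                                      "[,;[:space:]]+")))
    num <- num[!is.na(num)]
    x <- num[seq(1, length(num), by = 2)] * xfac
    y <- num[seq(2, length(num), by = 2)] * yfac
  } else {
    abort("missing ##XYDATA or ##XYPOINTS record",
          class = "mirspec_format_error")
  }
  new_spectrum(title, x, y, stage = "raw")
}
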