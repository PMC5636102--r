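# Pooled-covariance linear discriminant classifier on selected wavenumbers,
# posterior-probability scoring, Youden cut-off, and 90/10 Monte Carlo
# cross-validation.

#' Fit a pooled-covariance LDA model
#'
#' Two-class linear discriminant analysis: class means, pooled within-class
#' covariance (with a ridge for numerical safety), and the derived linear
#' weights `solve(Sigma, mu1 - mu0)`. Scores are on the posterior
#' probability scale via the logistic link (see [score_samples()]).
#'
#' @param X Numeric matrix (samples by selected wavenumbers) or data frame.
#' @param y 0/1 outcome labels (1 = deceased).
#' @param priors Length-2 class prior probabilities `c(p0, p1)`; default the
#'   empirical class frequencies.
#' @param ridge Ridge added to the covariance diagonal.
#' @return An object of class `mir_lda`.
#' @export
fit_lda <- function(X, y, priors = NULL, ridge = 1e-8) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 < 2L || n1 < 2L) {
    abort("need at least 2 samples per class", class = "mirspec_label_error")
  }
  if (ncol(X) > nrow(X) - 2L) {
    abort("more variables than n - 2 samples; select fewer wavenumbers",
          class = "mirspec_validation_error")
  }
  if (is.null(priors)) priors <- c(n0, n1) / length(y)
  stopifnot(length(priors) == 2, all(priors > 0), abs(sum(priors) - 1) < 1e-8)
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  X0 <- sweep(X[y == 0L, , drop = FALSE], 2, m0)
  X1 <- sweep(X[y == 1L, , drop = FALSE], 2, m1)
  S <- (crossprod(X0) + crossprod(X1)) / (length(y) - 2) +
    diag(ridge, ncol(X))
  w <- tryCatch(solve(S, m1 - m0), error = function(e) {
    abort("pooled covariance is singular even after ridge",
          class = "mirspec_singular_error")
  })
  intercept <- -sum(w * (m0 + m1)) / 2 + log(priors[2] / priors[1])
  structure(
    list(means = rbind(alive = m0, deceased = m1), covariance = S,
         priors = priors, weights = w, intercept = intercept,
         wavenumbers = if (!is.null(colnames(X)))
           suppressWarnings(as.numeric(colnames(X))) else NULL,
         n = c(n0 = n0, n1 = n1)),
    class = "mir_lda"
  )
}

#' @export
print.mir_lda <- function(x, ...) {
  cat(sprintf("<mir_lda> %d variables, n = %d alive / %d deceased\n",
              length(x$weights), x$n["n0"], x$n["n1"]))
  invisible(x)
}

#' @export
tidy.mir_lda <- function(x, ...) {
  tibble::tibble(
    term = if (!is.null(x$wavenumbers) && !anyNA(x$wavenumbers))
      format(x$wavenumbers, trim = TRUE) else
        paste0("x", seq_along(x$weights)),
    wavenumber = if (!is.null(x$wavenumbers)) x$wavenumbers else NA_real_,
    weight = unname(x$weights),
    mean_alive = unname(x$means["alive", ]),
    mean_deceased = unname(x$means["deceased", ])
  )
}

#' @export
glance.mir_lda <- function(x, ...) {
  tibble::tibble(n_variables = length(x$weights),
                 n_alive = unname(x$n["n0"]),
                 n_deceased = unname(x$n["n1"]),
                 prior_deceased = x$priors[2])
}

#' Score samples with a fitted LDA model
#'
#' Posterior probability of the deceased class: logistic of the linear
#' discriminant difference plus the log-prior offset. Values lie in (0, 1);
#' a sample midway between the class means with equal priors scores 0.5.
#'
#' @param model A `mir_lda` from [fit_lda()].
#' @param X Matrix with the model's variables as columns.
#' @return Numeric vector of probabilities.
#' @export
score_samples <- function(model, X) {
  stopifnot(inherits(model, "mir_lda"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights)) {
    abort("column count does not match the model's selected wavenumbers",
          class = "mirspec_validation_error")
  }
  if (!is.null(colnames(X)) && !is.null(model$wavenumbers) &&
      !anyNA(model$wavenumbers)) {
    xw <- suppressWarnings(as.numeric(colnames(X)))
    if (!anyNA(xw) && !isTRUE(all.equal(xw, model$wavenumbers))) {
      abort("wavenumber mismatch between model and data",
            class = "mirspec_validation_error")
    }
  }
  plogis(drop(X %*% model$weights) + model$intercept)
}

#' Youden-optimal cut-off
#'
#' Exhaustive scan over the midpoints of adjacent sorted unique scores plus
#' the two infinite sentinels; returns the cut-off maximizing
#' `J = sensitivity + specificity - 1` under the rule "positive iff
#' score > cutoff". Ties are broken toward higher specificity, then toward
#' the lower cut-off.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return A list with `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  # integer-count comparison (J maximal iff tp*n0 + tn*n1 maximal) makes the
  # tie policy exact under floating point
  best <- NULL
  for (ct in cand) {
    tp <- sum(scores > ct & labels == 1L)
    tn <- sum(scores <= ct & labels == 0L)
    jn <- tp * n0 + tn * n1
    if (is.null(best) || jn > best$jn ||
        (jn == best$jn && (tn > best$tn ||
                           (tn == best$tn && ct < best$cutoff)))) {
      best <- list(cutoff = ct, jn = jn, tn = tn, tp = tp)
    }
  }
  list(cutoff = best$cutoff,
       j = best$jn / (n1 * n0) - 1,
       sensitivity = best$tp / n1,
       specificity = best$tn / n0)
}

#' Monte Carlo cross-validation configuration
#' @param train_fraction Fraction of samples in each training split.
#' @param n_runs Number of random splits.
#' @param stratified Stratify splits by outcome (default `TRUE`).
#' @param seed Integer seed.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(train_fraction = 0.9, n_runs = 100,
                      stratified = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_runs >= 2)
  structure(list(train_fraction = train_fraction, n_runs = n_runs,
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_config")
}

#' Monte Carlo cross-validated LDA performance
#'
#' Repeats a stratified random 90/10 split `n_runs` times: fit on the
#' training part, score the holdout, record the holdout AUROC and the
#' holdout Youden cut-off. Sensitivity and specificity are then recomputed
#' per run at the across-run mean cut-off (the operating point a study
#' would publish). Per-sample held-out and misclassification counts (at the
#' mean cut-off) are tracked. Runs whose holdout lacks a class (possible
#' only with `stratified = FALSE`) are dropped with a warning, not imputed.
#'
#' @param X Matrix of selected-wavenumber values.
#' @param y 0/1 outcome labels.
#' @param cfg A [cv_config()].
#' @return An object of class `mir_cv`: list with `runs` (tibble of per-run
#'   AUROC, cut-off, sensitivity, specificity), `summary` (one-row tibble of
#'   means and percentile CI95s, incl. `mean_cutoff`), and `samples`
#'   (tibble of per-sample held-out / misclassified counts).
#' @export
mc_cross_validate <- function(X, y, cfg = cv_config()) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  n <- length(y)
  if (n < 20L) {
    abort("need at least 20 samples for Monte Carlo CV",
          class = "mirspec_validation_error")
  }
  holdouts <- vector("list", cfg$n_runs)
  scores <- vector("list", cfg$n_runs)
  with_local_seed(cfg$seed, {
    for (r in seq_len(cfg$n_runs)) {
      hold <- if (cfg$stratified) {
        stratified_holdout(y, 1 - cfg$train_fraction)
      } else {
        sample(n, round((1 - cfg$train_fraction) * n))
      }
      holdouts[[r]] <- hold
      if (length(unique(y[-hold])) < 2L) {
        abort("training split lost a class", class = "mirspec_split_error")
      }
      fit <- fit_lda(X[-hold, , drop = FALSE], y[-hold])
      scores[[r]] <- score_samples(fit, X[hold, , drop = FALSE])
    }
  })
  ok <- vapply(seq_len(cfg$n_runs),
               function(r) length(unique(y[holdouts[[r]]])) == 2L, logical(1))
  if (!all(ok)) {
    warn(sprintf("%d run(s) dropped: single-class holdout", sum(!ok)))
  }
  runs_idx <- which(ok)
  per_run <- purrr::map_dfr(runs_idx, function(r) {
    yc <- youden_cutoff(scores[[r]], y[holdouts[[r]]])
    tibble::tibble(run = r,
                   auroc = roc_auc(scores[[r]], y[holdouts[[r]]])$auroc,
                   cutoff = yc$cutoff, j = yc$j)
  })
  mean_cutoff <- mean(per_run$cutoff[is.finite(per_run$cutoff)])
  # second pass: operating characteristics at the common mean cut-off
  held <- integer(n); miscls <- integer(n)
  op <- purrr::map_dfr(runs_idx, function(r) {
    hold <- holdouts[[r]]; sc <- scores[[r]]; yy <- y[hold]
    pred <- as.integer(sc > mean_cutoff)
    held[hold] <<- held[hold] + 1L
    miscls[hold] <<- miscls[hold] + as.integer(pred != yy)
    tibble::tibble(run = r,
                   sensitivity = sum(pred == 1L & yy == 1L) / sum(yy == 1L),
                   specificity = sum(pred == 0L & yy == 0L) / sum(yy == 0L))
  })
  runs <- dplyr::left_join(per_run, op, by = "run")
  ci_a <- percentile_ci(runs$auroc); ci_se <- percentile_ci(runs$sensitivity)
  ci_sp <- percentile_ci(runs$specificity)
  summary <- tibble::tibble(
    n_runs = nrow(runs),
    mean_auroc = mean(runs$auroc),
    auroc_lo = ci_a[1], auroc_hi = ci_a[2],
    mean_cutoff = mean_cutoff,
    mean_sensitivity = mean(runs$sensitivity),
    sensitivity_lo = ci_se[1], sensitivity_hi = ci_se[2],
    mean_specificity = mean(runs$specificity),
    specificity_lo = ci_sp[1], specificity_hi = ci_sp[2]
  )
  samples <- tibble::tibble(
    sample = if (!is.null(rownames(X))) rownames(X) else as.character(seq_len(n)),
    outcome = y, times_held_out = held, times_misclassified = miscls
  )
  structure(list(runs = runs, summary = summary, samples = samples,
                 config = cfg),
            class = "mir_cv")
}

#' @export
print.mir_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<mir_cv> %d runs: mean AUROC %.3f (CI95 %.3f-%.3f), ",
           "mean cut-off %.3f,\n  sensitivity %.3f (%.3f-%.3f), ",
           "specificity %.3f (%.3f-%.3f) at the mean cut-off\n"),
    s$n_runs, s$mean_auroc, s$auroc_lo, s$auroc_hi, s$mean_cutoff,
    s$mean_sensitivity, s$sensitivity_lo, s$sensitivity_hi,
    s$mean_specificity, s$specificity_lo, s$specificity_hi))
  invisible(x)
}

#' @export
tidy.mir_cv <- function(x, ...) x$runs

#' @export
glance.mir_cv <- function(x, ...) x$summary

#' @export
augment.mir_cv <- function(x, ...) x$samples
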