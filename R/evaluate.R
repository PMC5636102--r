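# ROC/AUROC with the Mann-Whitney estimator, percentile CIs over CV runs,
# DeLong comparison of correlated ROC curves, and the Spearman marker
# network between spectral variables and clinical covariates.

#' ROC curve and AUROC
#'
#' AUROC by the Mann-Whitney pair-counting estimator (ties counted one
#' half), computed from mid-ranks; the curve by a threshold sweep over the
#' unique scores.
#'
#' @param scores Numeric scores (higher = more likely deceased).
#' @param labels 0/1 labels.
#' @return An object of class `mir_roc`: list with `auroc`, `n_pos`,
#'   `n_neg`, and `curve` (tibble of `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  structure(list(auroc = auroc, n_pos = n1, n_neg = n0,
                 curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "mir_roc")
}

#' @export
print.mir_roc <- function(x, ...) {
  cat(sprintf("<mir_roc> AUROC %.4f (%d deceased / %d alive)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.mir_roc <- function(x, ...) x$curve

#' @export
glance.mir_roc <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Mean AUROC and percentile CI over CV runs
#'
#' Mean plus the empirical 2.5/97.5 percentiles across runs, using the
#' type-7 linear-interpolation quantile rule.
#'
#' @param aurocs Numeric vector of per-run AUROCs (length >= 2).
#' @return One-row tibble: `mean`, `ci_lo`, `ci_hi`, `n_runs`.
#' @export
auc_ci_over_runs <- function(aurocs) {
  stopifnot(length(aurocs) >= 2)
  ci <- percentile_ci(aurocs)
  tibble::tibble(mean = mean(aurocs), ci_lo = ci[1], ci_hi = ci[2],
                 n_runs = length(aurocs))
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties half); and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n            # per-positive placements
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m    # per-negative placements
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance and confidence interval for a single AUROC
#'
#' Placement-value (DeLong) estimate of the sampling variance of the
#' Mann-Whitney AUROC, with the normal-approximation CI. This is the CI
#' construction usually reported for a full-cohort ROC curve, as opposed to
#' the percentile interval across CV runs of [auc_ci_over_runs()].
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param level Confidence level.
#' @return One-row tibble: `auroc`, `variance`, `ci_lo`, `ci_hi`.
#' @export
auc_ci_delong <- function(scores, labels, level = 0.95) {
  labels <- check_binary_labels(labels)
  pl <- delong_placements(scores, labels)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(auroc = pl$auc, variance = v,
                 ci_lo = max(0, pl$auc - z * sqrt(v)),
                 ci_hi = min(1, pl$auc + z * sqrt(v)))
}

#' DeLong comparison of two correlated ROC curves
#'
#' Computes both AUROCs on the same samples, the variance of their paired
#' difference from the placement-value covariance structure, a z statistic,
#' and a two-sided normal p-value. If the variance is zero and the AUROCs
#' equal (e.g. identical scores), p = 1.
#'
#' @param scores_a,scores_b Two score vectors on the same samples.
#' @param labels 0/1 labels.
#' @return An object of class `mir_delong`: list with `auc_a`, `auc_b`,
#'   `var_diff`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    abort("score vectors must cover the same samples",
          class = "mirspec_validation_error")
  }
  labels <- check_binary_labels(labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- var(pa$v10 - pb$v10)   # covariance structure of the difference
  s01 <- var(pa$v01 - pb$v01)
  var_diff <- s10 / m + s01 / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p = p),
            class = "mir_delong")
}

#' @export
print.mir_delong <- function(x, ...) {
  cat(sprintf("<mir_delong> AUROC %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' @export
tidy.mir_delong <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, var_diff = x$var_diff,
                 z = x$z, p = x$p)
}

#' Compare prognostic models on a common cohort
#'
#' Pairwise DeLong comparisons of named score vectors (e.g. the spectral
#' model posterior, MELD, Child-Pugh) against the same outcome, plus each
#' model's ROC curve for overlay plotting. Raw p-values are reported without
#' multiplicity correction.
#'
#' @param scores Named list of score vectors on the same samples.
#' @param labels 0/1 labels.
#' @return An object of class `mir_model_comparison`: list with `aurocs`
#'   (tibble of model AUROCs), `pairs` (tibble of pairwise DeLong results),
#'   `curves` (long tibble of ROC points per model).
#' @export
compare_models <- function(scores, labels) {
  stopifnot(is.list(scores), !is.null(names(scores)), length(scores) >= 2)
  labels <- check_binary_labels(labels)
  rocs <- purrr::map(scores, roc_auc, labels = labels)
  aurocs <- tibble::tibble(model = names(scores),
                           auroc = purrr::map_dbl(rocs, "auroc"))
  pairs <- purrr::map_dfr(utils::combn(names(scores), 2, simplify = FALSE),
                          function(pr) {
    d <- delong_compare(scores[[pr[1]]], scores[[pr[2]]], labels)
    tibble::tibble(model_a = pr[1], model_b = pr[2],
                   auc_a = d$auc_a, auc_b = d$auc_b, z = d$z, p = d$p)
  })
  curves <- purrr::map_dfr(names(scores), function(nm) {
    dplyr::mutate(rocs[[nm]]$curve, model = nm, .before = 1)
  })
  structure(list(aurocs = aurocs, pairs = pairs, curves = curves),
            class = "mir_model_comparison")
}

#' @export
print.mir_model_comparison <- function(x, ...) {
  cat("<mir_model_comparison>\n")
  print(x$aurocs)
  print(x$pairs[, c("model_a", "model_b", "auc_a", "auc_b", "p")])
  invisible(x)
}

#' @export
tidy.mir_model_comparison <- function(x, ...) x$pairs

#' Spearman correlation network of spectral markers and clinical covariates
#'
#' Tests every spectral-spectral and spectral-clinical pair with Spearman's
#' rank correlation (mid-rank ties, asymptotic t-approximation p-value) and
#' keeps edges with `p < alpha`. Raw p-values by default, matching the
#' exploratory usage; `adjust = "BH"` switches to Benjamini-Hochberg.
#' Constant variables yield an undefined correlation and are skipped with a
#' warning.
#'
#' @param spectral Matrix or data frame of selected-wavenumber values,
#'   columns named by wavenumber.
#' @param clinical Data frame of clinical covariates (numeric columns used).
#' @param alpha Significance threshold for retaining an edge.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble of edges: `node_a`, `node_b`, `type`
#'   (spectral-spectral / spectral-clinical), `rho`, `p`, `sign`.
#' @export
spearman_network <- function(spectral, clinical, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  spectral <- as.matrix(spectral)
  if (is.null(colnames(spectral))) {
    colnames(spectral) <- paste0("wn", seq_len(ncol(spectral)))
  }
  clin <- clinical[vapply(clinical, is.numeric, logical(1))]
  clin <- clin[setdiff(names(clin), "outcome")]
  pairs <- list()
  sp_names <- colnames(spectral)
  add_pair <- function(a, b, xa, xb, type) {
    keep <- is.finite(xa) & is.finite(xb)
    if (sum(keep) < 10) return(NULL)
    if (sd(xa[keep]) == 0 || sd(xb[keep]) == 0) {
      warn(sprintf("constant variable in pair (%s, %s); edge skipped", a, b))
      return(NULL)
    }
    ct <- suppressWarnings(cor.test(xa[keep], xb[keep], method = "spearman",
                                    exact = FALSE))
    tibble::tibble(node_a = a, node_b = b, type = type,
                   rho = unname(ct$estimate), p = ct$p.value)
  }
  for (i in seq_along(sp_names)) {
    for (j in seq_along(sp_names)) {
      if (j <= i) next
      pairs <- c(pairs, list(add_pair(sp_names[i], sp_names[j],
                                      spectral[, i], spectral[, j],
                                      "spectral-spectral")))
    }
    for (cl in names(clin)) {
      pairs <- c(pairs, list(add_pair(sp_names[i], cl,
                                      spectral[, i], clin[[cl]],
                                      "spectral-clinical")))
    }
  }
  edges <- dplyr::bind_rows(pairs)
  if (nrow(edges) == 0) return(edges)
  if (adjust == "BH") edges$p <- stats::p.adjust(edges$p, method = "BH")
  edges <- dplyr::filter(edges, .data$p < alpha)
  dplyr::mutate(edges, sign = ifelse(.data$rho >= 0, "positive", "negative"))
}
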