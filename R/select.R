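# Two-phase wavenumber selection: repeated factor-adjusted greedy selection
# with an LDA-error fitness over Monte Carlo subsamples, frequency-based
# retention, then supervised backward optimization under Monte Carlo CV
# AUROC.

#' Selection configuration
#'
#' Defaults mirror the published workflow: the selector is run 200 times on
#' random stratified 90% subsamples, the most frequently selected
#' wavenumbers (about 30) are retained, and a supervised backward pass under
#' 100-run 90/10 Monte Carlo CV reduces them to a final set of 7-12.
#'
#' @param n_runs Number of outer selection runs.
#' @param holdout_fraction Fraction left out of each run's subsample.
#' @param max_factors Upper bound for the latent-factor count.
#' @param max_subset_size Cap on each run's greedy forward subset.
#' @param retain_target Approximate size of the retained candidate set.
#' @param frequency_threshold Minimum selection frequency (fraction of runs)
#'   for retention; `NULL` (default) picks the count that yields
#'   `retain_target` variables — the histogram's red line.
#' @param final_size_range Target size range of the optimized final set.
#' @param fitness_folds Stratified CV folds inside the greedy selector.
#' @param inner_cv_runs Monte Carlo CV runs of the backward optimizer.
#' @param inner_train_fraction Training fraction of those runs.
#' @param ridge Ridge added to covariance diagonals in the fitness LDA.
#' @param seed Integer seed for the whole two-phase procedure.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(n_runs = 200,
                             holdout_fraction = 0.10,
                             max_factors = 8,
                             max_subset_size = 15,
                             retain_target = 30,
                             frequency_threshold = NULL,
                             final_size_range = c(7, 12),
                             fitness_folds = 5,
                             inner_cv_runs = 100,
                             inner_train_fraction = 0.9,
                             ridge = 1e-6,
                             seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 0.5,
            final_size_range[1] >= 1, final_size_range[1] <= final_size_range[2],
            final_size_range[2] <= retain_target)
  structure(list(n_runs = n_runs, holdout_fraction = holdout_fraction,
                 max_factors = max_factors, max_subset_size = max_subset_size,
                 retain_target = retain_target,
                 frequency_threshold = frequency_threshold,
                 final_size_range = final_size_range,
                 fitness_folds = fitness_folds, inner_cv_runs = inner_cv_runs,
                 inner_train_fraction = inner_train_fraction,
                 ridge = ridge, seed = as.integer(seed)),
            class = "selection_config")
}

# Within-class standardization + SVD shared by the factor operations.
# Returns centers (class means), pooled scales, standardized Z, right
# singular vectors V and within-class correlation eigenvalues lam.
factor_decomp <- function(X, y) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  n <- nrow(X)
  centers <- rbind(`0` = colMeans(X[y == 0L, , drop = FALSE]),
                   `1` = colMeans(X[y == 1L, , drop = FALSE]))
  Xc <- X - centers[as.character(y), , drop = FALSE]
  scales <- sqrt(colSums(Xc^2) / (n - 2))
  scales[scales < 1e-12] <- 1e-12
  Z <- sweep(Xc, 2, scales, "/")
  sv <- La.svd(Z, nu = 0)
  lam <- sv$d^2 / (n - 2)
  list(centers = centers, scales = scales, Z = Z,
       V = t(sv$vt), lam = lam, n = n, p = ncol(X))
}

# Mean squared off-diagonal of the residual within-class correlation after
# removing k factors (residual rescaled to unit diagonal).
residual_msq <- function(R, V, lam, k) {
  if (k == 0) {
    p <- nrow(R)
    return((sum(R^2) - sum(diag(R)^2)) / (p * (p - 1)))
  }
  L <- V[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam[seq_len(k)]), k)
  Rk <- R - tcrossprod(L)
  d <- pmax(diag(Rk), 1e-8)
  Rk <- Rk / sqrt(outer(d, d))
  p <- nrow(Rk)
  (sum(Rk^2) - sum(diag(Rk)^2)) / (p * (p - 1))
}

choose_k_from_decomp <- function(dec, max_factors) {
  if (max_factors <= 0) return(0L)
  R <- crossprod(dec$Z) / (dec$n - 2)
  kmax <- min(max_factors, length(dec$lam) - 1L, dec$n - 3L)
  m <- vapply(0:kmax, function(k) residual_msq(R, dec$V, dec$lam, k),
              numeric(1))
  for (k in 0:(kmax - 1L)) {
    if (m[k + 1] <= 0) return(k)
    drop <- (m[k + 1] - m[k + 2]) / m[k + 1]
    if (drop < 0.05) return(as.integer(k))
  }
  as.integer(kmax)
}

#' Choose the number of latent factors
#'
#' Elbow rule on the mean squared off-diagonal of the residual within-class
#' correlation: the smallest `k` whose marginal relative drop when adding a
#' further factor falls below 5%. Independent variables give `k = 0` (no
#' adjustment).
#'
#' @param X Processed variable matrix.
#' @param y 0/1 labels.
#' @param max_factors Upper bound for `k`.
#' @return Integer factor count in `[0, max_factors]`.
#' @export
choose_n_factors <- function(X, y, max_factors = 8) {
  choose_k_from_decomp(factor_decomp(X, y), max_factors)
}

#' Fit a within-class latent factor model
#'
#' Loadings are the first `k` principal axes of the pooled within-class
#' correlation matrix, scaled by the root eigenvalues (sign convention:
#' the largest-magnitude entry of each loading is positive); uniquenesses
#' are the residual diagonal. Deterministic given `X` and `y`.
#'
#' @param X Processed variable matrix (n by p).
#' @param y 0/1 labels (class means are removed before estimation).
#' @param k Number of factors (`0` = no adjustment).
#' @return An object of class `mir_factor_model`: loadings (p by k),
#'   uniquenesses, `k`, and the standardization (class centers, scales).
#' @export
fit_factor_model <- function(X, y, k) {
  dec <- factor_decomp(X, y)
  if (k >= min(dec$n - 2L, dec$p)) {
    abort(sprintf("k = %d must be below min(n - 2, p) = %d",
                  k, min(dec$n - 2L, dec$p)),
          class = "mirspec_validation_error")
  }
  if (k > 0) {
    L <- dec$V[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(dec$lam[seq_len(k)]), k)
    for (j in seq_len(k)) {
      if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
    }
  } else {
    L <- matrix(0, dec$p, 0)
  }
  structure(
    list(loadings = L,
         uniquenesses = pmax(1 - rowSums(L^2), 1e-6),
         k = as.integer(k),
         centers = dec$centers, scales = dec$scales),
    class = "mir_factor_model"
  )
}

#' @export
print.mir_factor_model <- function(x, ...) {
  cat(sprintf("<mir_factor_model> %d factor(s), %d variables\n",
              x$k, length(x$uniquenesses)))
  invisible(x)
}

#' Remove the latent-factor component from a matrix
#'
#' Subtracts the reconstruction from per-sample factor scores (ordinary
#' regression of each standardized sample on the loadings — an orthogonal
#' projection, hence exactly idempotent). Class means are restored, so the
#' class-mean structure is preserved.
#'
#' @param X Matrix on the factor model's variable set.
#' @param fm A [fit_factor_model()] object.
#' @param y Optional 0/1 labels; with labels the model's class centers are
#'   used for standardization, without them the prior-weighted overall
#'   center.
#' @return The adjusted matrix, same shape as `X`.
#' @export
factor_adjust <- function(X, fm, y = NULL) {
  stopifnot(inherits(fm, "mir_factor_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(fm$scales)) {
    abort("variable count does not match the factor model",
          class = "mirspec_validation_error")
  }
  if (fm$k == 0) return(X)
  centers <- if (!is.null(y)) {
    fm$centers[as.character(as.integer(y)), , drop = FALSE]
  } else {
    matrix(colMeans(fm$centers), nrow(X), ncol(X), byrow = TRUE)
  }
  Z <- sweep(X - centers, 2, fm$scales, "/")
  L <- fm$loadings
  Fhat <- Z %*% L %*% solve(crossprod(L))
  Zadj <- Z - Fhat %*% t(L)
  sweep(Zadj, 2, fm$scales, "*") + centers
}

# Vectorized greedy-step fitness: misclassification counts on one holdout
# fold for every candidate extension of the current set S, via partitioned
# inverses of the pooled covariance. Also returns the normalized holdout
# margin (class separation of the discriminant in training-metric units),
# used to order candidates whose 0/1 error counts tie exactly.
step_fold_errors <- function(Xtr, ytr, Xte, yte, S, cand, ridge) {
  n0 <- sum(ytr == 0L); n1 <- sum(ytr == 1L)
  m0 <- colMeans(Xtr[ytr == 0L, , drop = FALSE])
  m1 <- colMeans(Xtr[ytr == 1L, , drop = FALSE])
  Xc <- Xtr - rbind(m0, m1)[ytr + 1L, , drop = FALSE]
  df <- nrow(Xtr) - 2
  delta <- m1 - m0
  mid <- (m0 + m1) / 2
  logprior <- log(n1 / n0)
  diagS <- colSums(Xc^2) / df + ridge
  if (length(S) == 0) {
    wjj <- delta[cand] / diagS[cand]
    sc <- sweep(Xte[, cand, drop = FALSE], 2, wjj, "*")
    b <- -wjj * mid[cand] + logprior
    pred <- sweep(sc, 2, b, "+") > 0
    delta2 <- delta[cand] * wjj
  } else {
    SS <- crossprod(Xc[, S, drop = FALSE]) / df + diag(ridge, length(S))
    Cc <- crossprod(Xc[, S, drop = FALSE], Xc[, cand, drop = FALSE]) / df
    A <- solve(SS, Cc)                               # |S| x m
    s <- pmax(diagS[cand] - colSums(Cc * A), ridge)  # Schur complements
    w0 <- solve(SS, delta[S])
    wjj <- (delta[cand] - drop(crossprod(Cc, w0))) / s
    base <- drop(Xte[, S, drop = FALSE] %*% w0)      # n_te
    G <- Xte[, S, drop = FALSE] %*% A                # n_te x m
    sc <- base + sweep(Xte[, cand, drop = FALSE] - G, 2, wjj, "*")
    base_mid <- sum(mid[S] * w0)
    g_mid <- drop(mid[S] %*% A)
    b <- -(base_mid + wjj * (mid[cand] - g_mid)) + logprior
    pred <- sweep(sc, 2, b, "+") > 0
    delta2 <- sum(delta[S] * w0) +
      wjj * (delta[cand] - drop(crossprod(Cc, w0)))
  }
  sep <- colMeans(sc[yte == 1L, , drop = FALSE]) -
    colMeans(sc[yte == 0L, , drop = FALSE])
  list(errors = colSums(pred != (yte == 1L)),
       margin = sep / sqrt(pmax(delta2, ridge)))
}

#' Greedy forward variable selection with an LDA fitness
#'
#' Adds, at each step, the variable minimizing the mean LDA
#' misclassification rate under internal stratified cross-validation; stops
#' when no addition strictly reduces the error or `max_subset_size` is
#' reached. Ties break toward the lower wavenumber (leftmost column).
#'
#' @param X Adjusted variable matrix (columns in ascending wavenumber order).
#' @param y 0/1 labels (>= 2 samples per class).
#' @param max_subset_size Maximum subset size.
#' @param n_folds Stratified CV folds for the fitness.
#' @param ridge Covariance ridge.
#' @param seed Optional seed for the fold assignment.
#' @return Integer vector of selected column indices, in selection order.
#' @export
forward_select <- function(X, y, max_subset_size = 15, n_folds = 5,
                           ridge = 1e-6, seed = NULL) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  if (min(sum(y == 0L), sum(y == 1L)) < n_folds) {
    abort("need at least n_folds samples per class",
          class = "mirspec_label_error")
  }
  with_local_seed(seed, {
    fold <- stratified_folds(y, n_folds)
    n <- length(y)
    S <- integer(0)
    best_err <- min(sum(y == 0L), sum(y == 1L)) / n   # majority-rule baseline
    repeat {
      if (length(S) >= max_subset_size) break
      cand <- setdiff(seq_len(ncol(X)), S)
      errs <- numeric(length(cand))
      marg <- numeric(length(cand))
      for (f in seq_len(n_folds)) {
        te <- which(fold == f)
        sf <- step_fold_errors(X[-te, , drop = FALSE], y[-te],
                               X[te, , drop = FALSE], y[te],
                               S, cand, ridge)
        errs <- errs + sf$errors
        marg <- marg + sf$margin
      }
      errs <- errs / n
      # minimum error; exact ties resolved by the larger held-out margin,
      # remaining ties by the lower wavenumber (leftmost column)
      tied <- which(errs <= min(errs))
      j <- tied[which.max(marg[tied])]
      if (errs[j] >= best_err) break
      best_err <- errs[j]
      S <- c(S, cand[j])
    }
    S
  })
}

#' Repeated factor-adjusted selection
#'
#' Runs the full selector `n_runs` times, each on a random stratified
#' subsample holding out `holdout_fraction` of the cohort: choose the factor
#' count, fit and apply the within-class factor adjustment, then greedy
#' forward selection. Selection counts across runs form the histogram; the
#' retained set is cut at `frequency_threshold` (or at the count that yields
#' `retain_target` variables), ordered by count descending with ties broken
#' by ascending wavenumber.
#'
#' With `null_permute = TRUE` the training labels are freshly permuted in
#' every run, giving the permutation-null reference distribution of
#' selection frequencies against which the retention threshold (the
#' histogram's red line) can be judged.
#'
#' @param X Processed variable matrix (e.g. the 615-column analysis matrix).
#' @param y 0/1 labels.
#' @param cfg A [selection_config()].
#' @param null_permute Permute labels independently in each run (default
#'   `FALSE`).
#' @return An object of class `mir_selection`: `histogram` (tibble of
#'   `wavenumber`, `column`, `count`, `frequency`), `retained` (tibble
#'   subset, ordered), `threshold` (count cut actually used) and `config`.
#' @export
repeated_selection <- function(X, y, cfg = selection_config(),
                               null_permute = FALSE) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  wn <- suppressWarnings(as.numeric(colnames(X)))
  if (anyNA(wn)) wn <- seq_len(ncol(X))
  counts <- integer(ncol(X))
  for (run in seq_len(cfg$n_runs)) {
    sel <- with_local_seed(child_seed(cfg$seed, run), {
      yr <- if (null_permute) sample(y) else y
      hold <- stratified_holdout(yr, cfg$holdout_fraction)
      Xtr <- X[-hold, , drop = FALSE]
      ytr <- yr[-hold]
      dec <- factor_decomp(Xtr, ytr)
      k <- choose_k_from_decomp(dec, cfg$max_factors)
      fm <- fit_factor_model(Xtr, ytr, k)
      Xadj <- factor_adjust(Xtr, fm, ytr)
      colnames(Xadj) <- colnames(X)
      forward_select(Xadj, ytr, cfg$max_subset_size,
                     n_folds = cfg$fitness_folds, ridge = cfg$ridge)
    })
    counts[sel] <- counts[sel] + 1L
  }
  hist <- tibble::tibble(wavenumber = wn, column = seq_len(ncol(X)),
                         count = counts, frequency = counts / cfg$n_runs)
  ord <- order(-hist$count, hist$wavenumber)
  ranked <- hist[ord, ]
  if (is.null(cfg$frequency_threshold)) {
    nz <- ranked[ranked$count > 0, ]
    m <- min(cfg$retain_target, nrow(nz))
    threshold <- nz$count[m]
    retained <- nz[seq_len(m), ]
  } else {
    threshold <- cfg$frequency_threshold * cfg$n_runs
    retained <- ranked[ranked$count >= threshold, ]
  }
  structure(list(histogram = hist, retained = retained,
                 threshold = threshold, config = cfg),
            class = "mir_selection")
}

#' @export
print.mir_selection <- function(x, ...) {
  cat(sprintf(
    "<mir_selection> %d runs over %d variables; %d retained (count >= %g)\n",
    x$config$n_runs, nrow(x$histogram), nrow(x$retained), x$threshold))
  print(utils::head(x$retained, 10))
  invisible(x)
}

#' @export
tidy.mir_selection <- function(x, ...) x$histogram

#' Supervised backward optimization of the candidate set
#'
#' Starting from the retained candidates (about 30), repeatedly drops the
#' variable whose removal maximizes the mean holdout AUROC under Monte
#' Carlo 90/10 cross-validation with fixed splits. Removal is forced while
#' the set is larger than the upper end of `final_size_range`; below that,
#' elimination continues only while the mean AUROC does not drop by more
#' than 0.005, and never below the lower end.
#'
#' @param candidates Integer column indices (e.g. `retained$column` of a
#'   [repeated_selection()] result).
#' @param X Processed variable matrix.
#' @param y 0/1 labels.
#' @param cfg A [selection_config()].
#' @return Integer vector of final column indices (ascending).
#' @export
optimize_subset <- function(candidates, X, y, cfg = selection_config()) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0) {
    abort("candidate set is empty", class = "mirspec_validation_error")
  }
  lo <- cfg$final_size_range[1]; hi <- cfg$final_size_range[2]
  splits <- with_local_seed(child_seed(cfg$seed, -7L), {
    lapply(seq_len(cfg$inner_cv_runs), function(r) {
      stratified_holdout(y, 1 - cfg$inner_train_fraction)
    })
  })
  fitness <- function(cols) {
    mean(vapply(splits, function(hold) {
      auc_fast(lda_scores_fast(X[-hold, cols, drop = FALSE], y[-hold],
                               X[hold, cols, drop = FALSE], cfg$ridge),
               y[hold])
    }, numeric(1)))
  }
  current <- candidates
  cur_auc <- fitness(current)
  while (length(current) > lo) {
    aucs <- vapply(seq_along(current),
                   function(i) fitness(current[-i]), numeric(1))
    i <- which.max(aucs)
    if (length(current) > hi || aucs[i] >= cur_auc - 0.005) {
      current <- current[-i]
      cur_auc <- aucs[i]
    } else {
      break
    }
  }
  current
}

# Minimal internal LDA scorer and AUROC for fitness loops (no validation).
lda_scores_fast <- function(Xtr, ytr, Xte, ridge) {
  m0 <- colMeans(Xtr[ytr == 0L, , drop = FALSE])
  m1 <- colMeans(Xtr[ytr == 1L, , drop = FALSE])
  Xc <- Xtr - rbind(m0, m1)[ytr + 1L, , drop = FALSE]
  S <- crossprod(Xc) / (nrow(Xtr) - 2) + diag(ridge, ncol(Xtr))
  w <- solve(S, m1 - m0)
  drop(Xte %*% w)
}

auc_fast <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' End-to-end wavenumber selection
#'
#' Convenience wrapper chaining [repeated_selection()] and
#' [optimize_subset()].
#'
#' @inheritParams repeated_selection
#' @return A list: `selection` (the `mir_selection`), `final` (tibble of the
#'   final wavenumbers, ascending).
#' @export
select_wavenumbers <- function(X, y, cfg = selection_config()) {
  sel <- repeated_selection(X, y, cfg)
  final_cols <- optimize_subset(sel$retained$column, X, y, cfg)
  list(selection = sel,
       final = sel$histogram[sel$histogram$column %in% final_cols, ])
}
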