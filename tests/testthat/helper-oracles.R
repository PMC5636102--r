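# Independent oracles and data constructors shared across the test files.

# Brute-force pair-counting AUROC (ties count one half).
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every candidate cut (all midpoints and the
# infinite sentinels), with the tie policy spelled out longhand.
youden_exhaustive <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  res <- data.frame(cut = cand, jn = NA_real_, tn = NA_real_)
  for (i in seq_along(cand)) {
    tp <- sum(scores > cand[i] & labels == 1)
    tn <- sum(scores <= cand[i] & labels == 0)
    res$jn[i] <- tp * n0 + tn * n1    # integer-count ordering, float-proof
    res$tn[i] <- tn
  }
  res <- res[order(-res$jn, -res$tn, res$cut), ]
  list(cutoff = res$cut[1], j = res$jn[1] / (n1 * n0) - 1)
}

# Abstract planted-variable cohort: p variables with one global latent
# factor (within-class equicorrelation rho); the planted columns carry a
# common-mode class shift whose 5-column Mahalanobis distance is `delta_m`.
make_planted <- function(n, p, planted, delta_m, rho = 0.45, seed,
                         balanced = TRUE) {
  set.seed(seed)
  y <- if (balanced) {
    c(rep(0L, n %/% 2), rep(1L, n - n %/% 2))
  } else {
    c(rep(0L, round(0.8 * n)), rep(1L, n - round(0.8 * n)))
  }
  g <- rnorm(n)
  X <- sqrt(rho) * g %*% t(rep(1, p)) +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
  shift <- delta_m * sqrt((1 + (length(planted) - 1) * rho) / length(planted))
  X[y == 1L, planted] <- X[y == 1L, planted] + shift
  colnames(X) <- as.character(seq(962, by = 2, length.out = p))
  list(X = X, y = y, shift = shift)
}

# Two-factor construction used by the factor-model tests.
make_two_factor <- function(n = 400, p = 100, seed = 1) {
  set.seed(seed)
  Fm <- matrix(rnorm(n * 2), n, 2)
  L <- matrix(runif(p * 2, 0.4, 0.8) * sample(c(-1, 1), p * 2, TRUE), p, 2)
  X <- Fm %*% t(L) + matrix(rnorm(n * p), n, p)
  y <- rep(c(0L, 1L), length.out = n)
  list(X = X, y = y)
}

# Pooled within-class standardized mean difference per column.
uni_d <- function(M, y) {
  m0 <- colMeans(M[y == 0, , drop = FALSE])
  m1 <- colMeans(M[y == 1, , drop = FALSE])
  v0 <- apply(M[y == 0, , drop = FALSE], 2, var)
  v1 <- apply(M[y == 1, , drop = FALSE], 2, var)
  s <- sqrt((v0 * (sum(y == 0) - 1) + v1 * (sum(y == 1) - 1)) / (length(y) - 2))
  (m1 - m0) / s
}

# Raw spectrum covering the work domain, built from the generator.
demo_spectrum <- function(seed = 1, label = 0) {
  simulate_spectrum(label, cohort_config(seed = seed), index = 1L)
}

informative_cols <- function(proc, truth) {
  vapply(truth$informative_wavenumbers,
         function(w) which.min(abs(proc$grid - w)), integer(1))
}
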