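# Internal helpers: seeded RNG scoping and stratified resampling.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic entry points funnel
# through this so that a seed argument fully determines the result without
# clobbering the user's session RNG.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from (seed, index), kept inside 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483587)
}

# Stratified holdout: returns indices of the holdout set. Total holdout size
# is round(frac * n); the minority-class share is proportional (rounded) and
# clamped so both classes keep at least one held-out and two training samples.
stratified_holdout <- function(y, frac) {
  n <- length(y)
  m <- round(frac * n)
  idx1 <- which(y == 1L)
  idx0 <- which(y == 0L)
  m1 <- min(max(round(m * length(idx1) / n), 1L), m - 1L)
  m0 <- m - m1
  if (m0 < 1L || m1 < 1L ||
      length(idx0) - m0 < 2L || length(idx1) - m1 < 2L) {
    abort("holdout would leave fewer than 2 training samples in a class",
          class = "mirspec_split_error")
  }
  c(sample(idx0, m0), sample(idx1, m1))
}

# Stratified k-fold assignment (per-class round robin on a shuffled order).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

check_binary_labels <- function(y) {
  if (!all(y %in% c(0L, 1L))) {
    abort("labels must be 0 (alive) or 1 (deceased)",
          class = "mirspec_label_error")
  }
  if (length(unique(y)) < 2L) {
    abort("both outcome classes must be present",
          class = "mirspec_label_error")
  }
  invisible(as.integer(y))
}

# Percentile CI across runs (type-7 linear interpolation, stated in docs).
percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, probs = c(a, 1 - a), type = 7, names = FALSE))
}
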