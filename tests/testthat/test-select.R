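test_that("factor count selection finds planted factor structure", {
  tf <- make_two_factor(n = 400, p = 100, seed = 41)
  expect_equal(choose_n_factors(tf$X, tf$y, max_factors = 6), 2L)
  set.seed(42)
  noise <- matrix(rnorm(400 * 100), 400, 100)
  expect_equal(choose_n_factors(noise, tf$y, max_factors = 6), 0L)
  expect_equal(choose_n_factors(tf$X, tf$y, max_factors = 0), 0L)
})

test_that("factor model removes planted correlation and is deterministic", {
  tf <- make_two_factor(n = 400, p = 100, seed = 43)
  fm <- fit_factor_model(tf$X, tf$y, 2)
  Xa <- factor_adjust(tf$X, fm, tf$y)
  # residual within-class correlation is near diagonal
  Z <- scale(Xa)
  R <- crossprod(Z) / (nrow(Z) - 1)
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)
  # determinism
  fm2 <- fit_factor_model(tf$X, tf$y, 2)
  expect_identical(fm$loadings, fm2$loadings)
  expect_error(fit_factor_model(tf$X[1:5, ], tf$y[1:5], 4),
               class = "mirspec_validation_error")
})

test_that("adjustment on independent noise barely changes the correlation structure", {
  set.seed(44)
  X <- matrix(rnorm(400 * 100), 400, 100)
  y <- rep(c(0L, 1L), 200)
  fm <- fit_factor_model(X, y, 1)
  Xa <- factor_adjust(X, fm, y)
  R0 <- cor(X)
  R1 <- cor(Xa)
  expect_lt(mean(abs(R1[upper.tri(R1)] - R0[upper.tri(R0)])), 0.02)
  expect_lt(max(abs(R1[upper.tri(R1)] - R0[upper.tri(R0)])), 0.25)
})

test_that("factor adjustment is an idempotent projection; k = 0 is the identity", {
  tf <- make_two_factor(n = 200, p = 60, seed = 45)
  fm0 <- fit_factor_model(tf$X, tf$y, 0)
  expect_identical(factor_adjust(tf$X, fm0, tf$y), tf$X)
  fm <- fit_factor_model(tf$X, tf$y, 2)
  X1 <- factor_adjust(tf$X, fm, tf$y)
  X2 <- factor_adjust(X1, fm, tf$y)
  expect_lt(max(abs(X2 - X1)), 1e-8)
  expect_error(factor_adjust(tf$X[, 1:10], fm, tf$y),
               class = "mirspec_validation_error")
})

test_that("forward selection finds a perfect separator among noise", {
  set.seed(46)
  n <- 100
  X <- matrix(rnorm(n * 200), n, 200)
  y <- rep(c(0L, 1L), each = n / 2)
  X[, 77] <- y * 10 + rnorm(n, 0, 0.1)   # perfectly separating variable
  sel <- forward_select(X, y, max_subset_size = 5, seed = 1)
  expect_equal(sel[1], 77L)
  expect_equal(forward_select(X, y, max_subset_size = 1, seed = 1), 77L)
})

test_that("forward selection stops well short of the cap on pure noise", {
  sizes <- vapply(1:10, function(s) {
    set.seed(200 + s)
    X <- matrix(rnorm(100 * 200), 100, 200)
    y <- rep(c(0L, 1L), each = 50)
    length(forward_select(X, y, max_subset_size = 15, seed = s))
  }, numeric(1))
  expect_true(all(sizes < 15))
  expect_lte(median(sizes), 8)
})

test_that("repeated selection recovers planted variables and is deterministic", {
  planted <- c(10, 25, 40, 55, 70)
  d <- make_planted(120, 80, planted, delta_m = 2.5, seed = 47)
  cfg <- selection_config(n_runs = 40, max_subset_size = 8, seed = 48,
                          retain_target = 10, final_size_range = c(5, 10))
  sel <- repeated_selection(d$X, d$y, cfg)
  top10 <- sel$histogram$column[order(-sel$histogram$count,
                                      sel$histogram$wavenumber)][1:10]
  expect_gte(sum(planted %in% top10), 4)
  sel2 <- repeated_selection(d$X, d$y, cfg)
  expect_identical(sel$histogram, sel2$histogram)
  # retained ordering: counts descending, ties by ascending wavenumber
  expect_true(all(diff(sel$retained$count) <= 0))
})

test_that("planted-variable rank improves as the effect grows", {
  planted <- c(15, 30, 45, 60, 75)
  med_rank <- vapply(c(0.5, 1, 2), function(mult) {
    d <- make_planted(150, 100, planted, delta_m = mult, seed = 53)
    sel <- repeated_selection(d$X, d$y,
                              selection_config(n_runs = 30, seed = 54,
                                               max_subset_size = 8,
                                               retain_target = 10,
                                               final_size_range = c(5, 10)))
    h <- sel$histogram
    ranks <- rank(-h$count, ties.method = "average")[planted]
    median(ranks)
  }, numeric(1))
  # ranks saturate near the top once the effect is strong, so assert the
  # overall improvement and top-10 membership rather than strict ordering
  expect_gt(med_rank[1], med_rank[3])
  expect_true(all(med_rank[2:3] <= 10))
})

test_that("backward optimization keeps planted variables, honours bounds", {
  # independent planted contributions: removing any one costs AUROC
  planted <- c(5, 20, 35, 50, 65, 80, 95)
  kept <- vapply(1:3, function(s) {
    d <- make_planted(150, 100, planted, delta_m = 2.5, rho = 0,
                      seed = 49 + s)
    cfg <- selection_config(inner_cv_runs = 30, final_size_range = c(7, 12),
                            seed = 50 + s)
    cand <- sort(c(planted, c(2, 11, 28, 41, 57, 63, 71, 88, 92, 99)))
    final <- optimize_subset(cand, d$X, d$y, cfg)
    expect_lte(length(final), 12)
    expect_gte(length(final), 7)
    sum(planted %in% final)
  }, numeric(1))
  expect_true(all(kept >= 6))
  # candidates already equal to the planted set: lower bound reached at once
  d <- make_planted(150, 100, planted, delta_m = 2.5, rho = 0, seed = 49)
  cfg <- selection_config(inner_cv_runs = 30, final_size_range = c(7, 12),
                          seed = 50)
  expect_equal(optimize_subset(planted, d$X, d$y, cfg), sort(planted))
  expect_error(optimize_subset(integer(0), d$X, d$y, cfg),
               class = "mirspec_validation_error")
})

test_that("permutation-null selection frequencies stay low", {
  d <- make_planted(120, 80, c(10, 30), delta_m = 2, seed = 51)
  sel <- repeated_selection(d$X, d$y,
                            selection_config(n_runs = 60, seed = 52,
                                             max_subset_size = 8),
                            null_permute = TRUE)
  expect_lt(max(sel$histogram$frequency), 0.25)
})
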