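test_that("AUROC matches hand example, extremes and the ties convention", {
  r <- roc_auc(c(0.8, 0.7, 0.6, 0.3), c(1L, 0L, 1L, 0L))
  expect_equal(r$auroc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0L, 0L, 1L, 1L))$auroc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0L, 0L, 1L, 1L))$auroc, 0)
  expect_equal(roc_auc(rep(1, 6), c(0L, 1L, 0L, 1L, 0L, 1L))$auroc, 0.5)
  # curve is monotone in both coordinates
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_error(roc_auc(1:3, c(1L, 1L, 1L)), class = "mirspec_label_error")
})

test_that("AUROC equals the brute-force pair-count oracle on random instances", {
  set.seed(81)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    sc <- sample(round(runif(n), 1), n, replace = TRUE)
    lb <- integer(n); lb[sample(n, sample(1:(n - 1), 1))] <- 1L
    if (length(unique(lb)) < 2) next
    expect_identical(roc_auc(sc, lb)$auroc, auc_pair_count(sc, lb))
  }
})

test_that("run-level CI uses the interpolation quantile rule", {
  expect_equal(auc_ci_over_runs(rep(0.9, 100)),
               tibble::tibble(mean = 0.9, ci_lo = 0.9, ci_hi = 0.9,
                              n_runs = 100L))
  runs <- (1:100) / 100
  ci <- auc_ci_over_runs(runs)
  expect_equal(ci$ci_lo, unname(quantile(runs, 0.025)), tolerance = 1e-12)
  expect_lt(abs(ci$ci_lo - 0.033), 0.005)
  expect_lt(abs(ci$ci_hi - 0.977), 0.005)
  expect_equal(auc_ci_over_runs(c(0.8, 1.0))$mean, 0.9)
})

test_that("DeLong comparison has the stated symmetries", {
  set.seed(82)
  y <- rep(c(0L, 1L), each = 20)
  a <- rnorm(40) + y
  b <- rnorm(40) + 0.5 * y
  same <- delong_compare(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_compare(a, b, y)
  ba <- delong_compare(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$auc_a, ba$auc_b)
  expect_error(delong_compare(a[-1], b, y), class = "mirspec_validation_error")
})

test_that("DeLong agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  for (i in 1:20) {
    y <- rep(c(0L, 1L), each = 15)
    a <- rnorm(30) + 0.8 * y
    b <- rnorm(30) + 0.4 * y
    ours <- delong_compare(a, b, y)
    ref <- pROC::roc.test(
      pROC::roc(y, a, quiet = TRUE, direction = "<", levels = c(0, 1)),
      pROC::roc(y, b, quiet = TRUE, direction = "<", levels = c(0, 1)),
      method = "delong")
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("model comparison reports pairwise tests and curves", {
  set.seed(84)
  y <- rep(c(0L, 1L), each = 30)
  mir <- rnorm(60) + 1.5 * y
  meld <- rnorm(60) + 0.5 * y
  cp <- rnorm(60) + 0.5 * y
  comp <- compare_models(list(mir = mir, meld = meld, child_pugh = cp), y)
  expect_equal(nrow(comp$pairs), 3)
  expect_setequal(unique(comp$curves$model), c("mir", "meld", "child_pugh"))
  # a model against itself: p = 1
  self <- compare_models(list(a = meld, b = meld), y)
  expect_equal(self$pairs$p, 1)
  trip <- compare_models(list(a = meld, b = meld, c = meld), y)
  expect_true(all(trip$pairs$p == 1))
})

test_that("a stronger spectral score beats the clinical score in most cohorts", {
  wins <- vapply(1:10, function(s) {
    set.seed(500 + s)
    y <- rep(c(0L, 1L), each = 40)
    mir <- rnorm(80) + 1.6 * y
    meld <- rnorm(80) + 0.7 * y
    comp <- compare_models(list(mir = mir, meld = meld), y)
    comp$aurocs$auroc[comp$aurocs$model == "mir"] >
      comp$aurocs$auroc[comp$aurocs$model == "meld"]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("Spearman network honours rank identities and monotone invariance", {
  set.seed(85)
  x <- rnorm(30)
  spectral <- cbind(`1030` = x, `1468` = x^3)   # monotone transform: r = 1
  clin <- tibble::tibble(bilirubin = -x + rnorm(30, 0, 1e-9),
                         sodium = rnorm(30))
  edges <- spearman_network(spectral, clin)
  e11 <- edges[edges$node_a == "1030" & edges$node_b == "1468", ]
  expect_equal(e11$rho, 1)
  e12 <- edges[edges$node_a == "1030" & edges$node_b == "bilirubin", ]
  expect_equal(e12$rho, -1)
  expect_equal(e12$sign, "negative")
  # the hand example: ranks (1..5) vs (2,1,4,3,5) -> 1 - 6*4/120 = 0.8
  expect_equal(suppressWarnings(
    cor(1:5, c(2, 1, 4, 3, 5), method = "spearman")), 0.8)
  # strictly monotone transforms leave the network unchanged
  edges2 <- spearman_network(cbind(`1030` = exp(x), `1468` = x^3), clin)
  expect_equal(edges2$rho, edges$rho, tolerance = 1e-12)
})

test_that("network drops constant variables with a warning and filters by p", {
  set.seed(86)
  spectral <- cbind(`1030` = rnorm(30), flat = rep(1, 30))
  clin <- tibble::tibble(crp = rnorm(30))
  w <- capture_warnings(edges <- spearman_network(spectral, clin))
  expect_true(any(grepl("constant", w)))
  expect_false("flat" %in% c(edges$node_a, edges$node_b))
  expect_true(all(edges$p < 0.05))
})

test_that("autoplot and tidiers return the expected object types", {
  sim <- simulate_cohort(cohort_config(n = 24, seed = 87))
  proc <- preprocess_spectra(sim$spectra)
  idx <- informative_cols(proc, sim$truth)
  expect_s3_class(autoplot(get_spectrum(sim$spectra, 1)), "ggplot")
  expect_s3_class(autoplot(proc), "ggplot")
  fit <- fit_lda(proc$matrix[, idx], proc$labels)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 7)
  expect_s3_class(glance(fit), "tbl_df")
  cv <- mc_cross_validate(proc$matrix[, idx], proc$labels,
                          cv_config(n_runs = 5, seed = 88))
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(tidy(cv), "tbl_df")
  r <- roc_auc(score_samples(fit, proc$matrix[, idx]), proc$labels)
  expect_s3_class(autoplot(r), "ggplot")
})
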