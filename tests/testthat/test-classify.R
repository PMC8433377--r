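test_that("univariate summary reproduces cohort arithmetic", {
  # zero-variance cohort built from the published group means: ratios and
  # weighted grand averages are exact
  mets <- c("LAA", "glutamate", "choline", "sarcosine")
  gs <- list(group_spec("non-PCa", 10,
                        mean = setNames(c(1984, 40.2, 10.0, 11.5), mets),
                        sd = setNames(rep(0, 4), mets)),
             group_spec("PCa", 16,
                        mean = setNames(c(2694, 62.2, 13.4, 10.0), mets),
                        sd = setNames(rep(0, 4), mets)))
  co <- simulate_cohort(gs, seed = 1)
  su <- univariate_summary(co, group_order = c("non-PCa", "PCa"))
  expect_equal(round(su$ratio_mean[su$metabolite == "glutamate"], 2), 1.55)
  expect_equal(round(su$ratio_mean[su$metabolite == "LAA"], 2), 1.36)
  expect_equal(round(su$grand_mean[su$metabolite == "LAA"]), 2421)
  cc <- attr(su, "cross_correlation")
  expect_true(is.matrix(cc) && isSymmetric(cc))
})

test_that("identical groups give unit ratios and p ~ 1", {
  v <- c(3, 5, 7, 9, 11)
  co <- data.frame(sample_id = 1:10, group = rep(c("a", "b"), each = 5),
                   m1 = c(v, v))
  su <- univariate_summary(co)
  expect_equal(su$ratio_mean, 1)
  expect_equal(su$ratio_median, 1)
  expect_equal(su$p_value, 1)
  expect_error(univariate_summary(co[co$group == "a", ]), "two groups")
})

test_that("AUC is a rank statistic with the expected invariances", {
  set.seed(4)
  y <- rep(c(0, 1), each = 40)
  s <- rnorm(80) + 0.8 * y
  a <- auc(s, y)
  expect_equal(auc(exp(s), y), a)                 # monotone transform
  expect_equal(auc(100 + 3 * s, y), a)
  expect_equal(auc(s, y), 1 - auc(-s, y), tolerance = 1e-12)
  # perfect separation
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  rc <- roc_curve(s, y)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
})

test_that("random forest separates separable data and is seeded", {
  set.seed(9)
  y <- rep(c(0, 1), each = 30)
  x <- matrix(rnorm(120), ncol = 2)
  x[y == 1, ] <- x[y == 1, ] + 10
  set.seed(1)
  model <- rf_fit(x, y, n_trees = 50)
  p <- rf_predict(model, x)
  expect_true(all(p[y == 1] > 0.9))
  expect_true(all(p[y == 0] < 0.1))
})

test_that("cross-validated RF hits the null and separable extremes", {
  # no-signal null: identical feature distributions in both classes.
  # Scaled down to 40 trees and 2 repeats; 6 cohort draws keep the SE of the
  # averaged mean AUC below 0.02 so the 0.5 +/- 0.05 check is a >2.5-sigma
  # bound.
  null_means <- sapply(1:6, function(cs) {
    set.seed(100 + cs)
    co <- data.frame(sample_id = 1:200,
                     group = rep(c("ctl", "case"), each = 100),
                     f1 = rnorm(200), f2 = rnorm(200), f3 = rnorm(200))
    cfg <- classifier_config(n_trees = 40, repeats = 2, seed = cs,
                             features = c("f1", "f2", "f3"), n_boot = 0)
    crossval_rf(co, cfg)$mean_auc
  })
  expect_lt(abs(mean(null_means) - 0.5), 0.05)
  # perfectly separated classes
  co2 <- data.frame(sample_id = 1:40,
                    group = rep(c("ctl", "case"), each = 20),
                    f1 = c(rnorm(20, 0, 0.3), rnorm(20, 10, 0.3)))
  cfg2 <- classifier_config(n_trees = 60, repeats = 2, seed = 1,
                            features = "f1", n_boot = 50)
  rep2 <- crossval_rf(co2, cfg2)
  expect_equal(rep2$mean_auc, 1)
  op <- operating_point(rep2)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
})

test_that("reports are bit-reproducible under a fixed seed", {
  co <- simulate_cohort(seed = 3)
  cfg <- classifier_config(n_trees = 40, repeats = 3, seed = 11, n_boot = 20)
  r1 <- crossval_rf(co, cfg)
  r2 <- crossval_rf(co, cfg)
  expect_identical(r1$per_repeat_auc, r2$per_repeat_auc)
  expect_identical(r1$pooled_auc, r2$pooled_auc)
  cfg3 <- classifier_config(n_trees = 40, repeats = 3, seed = 12, n_boot = 20)
  r3 <- crossval_rf(co, cfg3)
  expect_false(identical(r1$per_repeat_auc, r3$per_repeat_auc))
})

test_that("label permutation destroys the signal", {
  # at n = 26 a single permuted-label AUC has SD ~ 0.12, so the [0.35, 0.65]
  # band is checked on the average over 5 permutations
  co <- simulate_cohort(seed = 5)
  set.seed(21)
  aucs <- vapply(1:5, function(i) {
    cop <- co
    cop$group <- sample(co$group)
    cfg <- classifier_config(n_trees = 50, repeats = 2, seed = i, n_boot = 0)
    crossval_rf(cop, cfg)$mean_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("synthetic clinical cohorts classify in the published regime", {
  # scaled down: 6 cohort seeds (full-scale check: 20), 100 trees, 4 repeats
  aucs <- vapply(1:6, function(s) {
    co <- simulate_cohort(seed = s)
    cfg <- classifier_config(n_trees = 100, repeats = 4, seed = s, n_boot = 0)
    crossval_rf(co, cfg)$mean_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.6)
  expect_lt(mean(aucs), 0.95)
})

test_that("operating point maximizes Youden's J", {
  roc3 <- data.frame(threshold = c(Inf, 0.5, -Inf),
                     fpr = c(0, 0.30, 1), tpr = c(0, 0.94, 1))
  op <- operating_point(roc3)
  expect_equal(op$sensitivity, 0.94)
  expect_equal(op$specificity, 0.70)
  # diagonal (null) ROC: J ~ 0 everywhere, sens + spec ~ 1
  diag_roc <- data.frame(threshold = c(Inf, 0.7, 0.3, -Inf),
                         fpr = c(0, 0.3, 0.7, 1), tpr = c(0, 0.3, 0.7, 1))
  opd <- operating_point(diag_roc)
  expect_equal(opd$sensitivity + opd$specificity, 1)
  expect_error(operating_point(diag_roc[1, ]), "degenerate")
})

test_that("roc_compare overlays the reference test", {
  co <- data.frame(sample_id = 1:40,
                   group = rep(c("ctl", "case"), each = 20),
                   f1 = c(rnorm(20, 0, 0.3), rnorm(20, 10, 0.3)))
  cfg <- classifier_config(n_trees = 40, repeats = 2, seed = 1,
                           features = "f1", n_boot = 0)
  rep1 <- crossval_rf(co, cfg)
  # against itself: zero AUC difference
  self_ref <- list(sensitivity = 1, specificity = 1, auc = rep1$pooled_auc)
  expect_equal(roc_compare(rep1, self_ref)$auc_difference, 0)
  # perfect classifier vs the PSA literature triple: 1.00 - 0.68
  cmp <- roc_compare(rep1)        # default PSA reference
  expect_equal(cmp$auc_difference, 1 - 0.68, tolerance = 1e-12)
  expect_equal(cmp$reference$operating_point$sensitivity, 0.32)
  # classifier-only overlay
  cmp0 <- roc_compare(rep1, reference = NULL)
  expect_true(is.na(cmp0$auc_difference))
})
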