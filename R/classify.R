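# Cohort-level univariate statistics and the repeated cross-validated
# random-forest panel classifier with pooled ROC analysis.

#' Univariate cohort summary
#'
#' Per-metabolite descriptive statistics of a two-group cohort: grand
#' mean/SD/median/range over all samples, the same per group, the ratio of
#' group means and of group medians (second group over first, i.e. case over
#' control when the control group sorts first), a two-sided Welch two-sample
#' t-test p-value, and the pairwise Pearson cross-correlation matrix of the
#' metabolites (attached as attribute `cross_correlation`).
#'
#' @param cohort A cohort data.frame: `sample_id`, `group`, one numeric
#'   column per metabolite.
#' @param group_order Optional length-2 character vector fixing which group
#'   is the denominator (first element) of the ratios.
#' @return A data.frame, one row per metabolite, with attribute
#'   `cross_correlation`.
#' @export
univariate_summary <- function(cohort, group_order = NULL) {
  mets <- setdiff(names(cohort), c("sample_id", "group"))
  mets <- mets[vapply(cohort[mets], is.numeric, logical(1))]
  groups <- if (is.null(group_order)) sort(unique(cohort$group)) else group_order
  if (length(groups) != 2) stop("cohort must contain exactly two groups")
  g1 <- cohort$group == groups[1]
  g2 <- cohort$group == groups[2]
  if (sum(g1) < 2 || sum(g2) < 2) stop("need >= 2 samples per group")
  one <- function(m) {
    v <- cohort[[m]]
    # degenerate zero-variance groups: the Welch statistic is undefined;
    # report 1 when the means coincide and 0 otherwise
    p <- tryCatch(stats::t.test(v[g2], v[g1], var.equal = FALSE)$p.value,
                  error = function(e)
                    if (isTRUE(all.equal(mean(v[g1]), mean(v[g2])))) 1 else 0)
    data.frame(
      metabolite = m,
      grand_mean = mean(v), grand_sd = stats::sd(v),
      grand_median = stats::median(v),
      grand_min = min(v), grand_max = max(v),
      mean_1 = mean(v[g1]), sd_1 = stats::sd(v[g1]),
      median_1 = stats::median(v[g1]),
      min_1 = min(v[g1]), max_1 = max(v[g1]),
      mean_2 = mean(v[g2]), sd_2 = stats::sd(v[g2]),
      median_2 = stats::median(v[g2]),
      min_2 = min(v[g2]), max_2 = max(v[g2]),
      ratio_mean = mean(v[g2]) / mean(v[g1]),
      ratio_median = stats::median(v[g2]) / stats::median(v[g1]),
      p_value = p)
  }
  out <- do.call(rbind, lapply(mets, one))
  attr(out, "groups") <- groups
  attr(out, "cross_correlation") <- stats::cor(as.matrix(cohort[mets]))
  out
}

#' Empirical ROC curve
#'
#' @param scores Predicted scores (higher = more positive).
#' @param labels Binary labels (0/1, logical, or two-level factor with the
#'   second level positive).
#' @return A data.frame `threshold`, `fpr`, `tpr`, ordered from the strictest
#'   threshold; includes the (0,0) and (1,1) endpoints.
#' @export
roc_curve <- function(scores, labels) {
  y <- normalize_labels(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopifnot(n1 > 0, n0 > 0)
  tpr <- vapply(thr, function(th) sum(scores >= th & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & y == 0) / n0, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Rank (Wilcoxon) formulation with midrank tie handling; invariant under any
#' strictly monotone transform of the scores.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- normalize_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) {
    stopifnot(nlevels(labels) == 2)
    return(as.integer(labels) - 1L)
  }
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  y
}

#' Classifier configuration
#'
#' Defaults follow the published setup: a 500-tree random forest trying up to
#' three metabolites at each split, validated by stratified tenfold
#' cross-validation repeated 100 times, with sarcosine excluded from the
#' default feature set.
#'
#' @param n_trees Trees per forest.
#' @param max_features_per_split Features tried at each split.
#' @param folds Cross-validation folds (>= 2).
#' @param repeats Number of repeated CV rounds (>= 1).
#' @param seed Integer seed governing all randomness of [crossval_rf()].
#' @param features Feature (metabolite) names used by the classifier.
#' @param n_boot Bootstrap resamples for the pooled-prediction AUC CI.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 500, max_features_per_split = 3,
                              folds = 10, repeats = 100, seed = 1L,
                              features = c("LAA", "glutamate", "choline"),
                              n_boot = 1000) {
  stopifnot(folds >= 2, repeats >= 1, n_trees >= 1)
  structure(list(n_trees = n_trees,
                 max_features_per_split = max_features_per_split,
                 folds = folds, repeats = repeats, seed = as.integer(seed),
                 features = features, n_boot = n_boot),
            class = "classifier_config")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated cross-validated random-forest classifier
#'
#' For each repeat, draws a stratified k-fold partition, trains a random
#' forest on each training split, and pools the out-of-fold class
#' probabilities of that repeat into one ROC/AUC. Reports the mean AUC over
#' repeats with a percentile 95% confidence interval over the repeat
#' distribution, the ROC of all pooled predictions across repeats (for the
#' curve and operating point), and a bootstrap percentile CI of the pooled
#' AUC (resampling pooled prediction/label pairs). All randomness derives
#' from `cfg$seed`.
#'
#' @param cohort Cohort data.frame with a two-level `group` column (second
#'   sorted level = positive class) and the feature columns of
#'   `cfg$features`.
#' @param cfg A [classifier_config()].
#' @return An object of class `classifier_report`: `per_repeat_auc`,
#'   `mean_auc`, `auc_ci` (percentile over repeats), `pooled_auc`,
#'   `pooled_auc_boot_ci`, `pooled_roc`, `pooled` (scores/labels), and
#'   per-repeat predictions.
#' @export
crossval_rf <- function(cohort, cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  missing_feats <- setdiff(cfg$features, names(cohort))
  if (length(missing_feats) > 0)
    stop("cohort lacks features: ", paste(missing_feats, collapse = ", "))
  x <- as.matrix(cohort[cfg$features])
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2) stop("need exactly two groups")
  y <- as.integer(cohort$group == groups[2])
  if (min(table(y)) < cfg$folds)
    warning("fewer samples than folds in one class; folds will be uneven")
  with_seed(cfg$seed, {
    n <- nrow(x)
    per_repeat <- vector("list", cfg$repeats)
    per_repeat_auc <- numeric(cfg$repeats)
    for (r in seq_len(cfg$repeats)) {
      fold <- stratified_folds(y, cfg$folds)
      prob <- rep(NA_real_, n)
      for (k in seq_len(cfg$folds)) {
        test <- which(fold == k)
        if (length(test) == 0) next
        train <- which(fold != k)
        model <- rf_fit(x[train, , drop = FALSE], y[train],
                        n_trees = cfg$n_trees,
                        mtry = min(cfg$max_features_per_split, ncol(x)))
        prob[test] <- rf_predict(model, x[test, , drop = FALSE])
      }
      per_repeat[[r]] <- prob
      per_repeat_auc[r] <- auc(prob, y)
    }
    pooled_scores <- unlist(per_repeat)
    pooled_labels <- rep(y, cfg$repeats)
    pooled_auc <- auc(pooled_scores, pooled_labels)
    boot <- numeric(cfg$n_boot)
    if (cfg$n_boot > 0) {
      m <- length(pooled_scores)
      for (b in seq_len(cfg$n_boot)) {
        idx <- sample.int(m, m, replace = TRUE)
        boot[b] <- tryCatch(auc(pooled_scores[idx], pooled_labels[idx]),
                            error = function(e) NA_real_)
      }
    }
    structure(list(
      per_repeat_auc = per_repeat_auc,
      mean_auc = mean(per_repeat_auc),
      auc_ci = stats::quantile(per_repeat_auc, c(0.025, 0.975), names = FALSE),
      pooled_auc = pooled_auc,
      pooled_auc_boot_ci = if (cfg$n_boot > 0)
        stats::quantile(boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
      else c(NA_real_, NA_real_),
      pooled_roc = roc_curve(pooled_scores, pooled_labels),
      pooled = list(scores = pooled_scores, labels = pooled_labels),
      per_repeat = per_repeat, labels = y,
      groups = groups, config = cfg),
      class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "repeated %d-fold CV x %d: mean AUC %.3f (95%% CI %.2f-%.2f), pooled AUC %.3f\n",
    x$config$folds, x$config$repeats, x$mean_auc, x$auc_ci[1], x$auc_ci[2],
    x$pooled_auc))
  invisible(x)
}

youden_point <- function(roc) {
  j <- roc$tpr - roc$fpr
  i <- which.max(j)
  list(sensitivity = roc$tpr[i], specificity = 1 - roc$fpr[i],
       threshold = roc$threshold[i])
}

#' ROC operating point
#'
#' Selects the threshold maximizing Youden's J (sensitivity + specificity -
#' 1) on the pooled ROC, and reports percentile 95% CIs of sensitivity and
#' specificity over the per-repeat operating points.
#'
#' @param report A [crossval_rf()] report, or a plain ROC data.frame
#'   (`threshold`, `fpr`, `tpr`), in which case no CIs are computed.
#' @param method Only `"youden"` is implemented.
#' @return List with `sensitivity`, `specificity`, `threshold`, and (for a
#'   report) `sensitivity_ci`, `specificity_ci`.
#' @export
operating_point <- function(report, method = "youden") {
  method <- match.arg(method, "youden")
  if (is.data.frame(report)) {
    if (nrow(report) < 2) stop("degenerate single-threshold ROC")
    return(youden_point(report))
  }
  stopifnot(inherits(report, "classifier_report"))
  op <- youden_point(report$pooled_roc)
  per <- lapply(report$per_repeat, function(s)
    youden_point(roc_curve(s, report$labels)))
  sens <- vapply(per, `[[`, numeric(1), "sensitivity")
  spec <- vapply(per, `[[`, numeric(1), "specificity")
  op$sensitivity_ci <- stats::quantile(sens, c(0.025, 0.975), names = FALSE)
  op$specificity_ci <- stats::quantile(spec, c(0.025, 0.975), names = FALSE)
  op
}

#' Compare a classifier ROC with a reference test
#'
#' Overlays the cross-validated panel ROC with a reference ROC given either
#' as a tabulated curve (`fpr`, `tpr` data.frame with known AUC attribute),
#' as a `(sensitivity, specificity, auc)` triple such as [psa_reference()],
#' or omitted (`NULL`) for a classifier-only summary.
#'
#' @param report A [crossval_rf()] report.
#' @param reference Reference ROC (see above); default the PSA literature
#'   values.
#' @return List with both curves/operating points and the AUC difference
#'   (classifier minus reference).
#' @export
roc_compare <- function(report, reference = psa_reference()) {
  stopifnot(inherits(report, "classifier_report"))
  op <- operating_point(report)
  out <- list(classifier = list(auc = report$pooled_auc,
                                mean_auc = report$mean_auc,
                                roc = report$pooled_roc,
                                operating_point = op))
  if (is.null(reference)) {
    out$auc_difference <- NA_real_
    return(out)
  }
  if (is.data.frame(reference)) {
    ref_auc <- attr(reference, "auc")
    ref_op <- NULL
    ref_curve <- reference
  } else {
    ref_auc <- reference$auc
    ref_op <- list(sensitivity = reference$sensitivity,
                   specificity = reference$specificity)
    ref_curve <- data.frame(
      threshold = c(Inf, NA, -Inf),
      fpr = c(0, 1 - reference$specificity, 1),
      tpr = c(0, reference$sensitivity, 1))
  }
  out$reference <- list(auc = ref_auc, roc = ref_curve,
                        operating_point = ref_op)
  out$auc_difference <- report$pooled_auc - ref_auc
  out
}
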