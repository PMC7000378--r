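# Metrics from confusion counts, as percentages; zero denominators give NA
# ("undefined"), never 0.
confusion_metrics <- function(tp, fn, fp, tn) {
  rat <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(accuracy = rat(tp + tn, tp + fn + fp + tn),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn))
}

#' Evaluation report from confusion counts
#'
#' Builds the standard report (accuracy, sensitivity, specificity, PPV, NPV,
#' as percentages) from the four confusion counts, with cases as the
#' positive class. Metrics are stored at full precision; `printed` holds the
#' one-decimal truncated values used for display. Undefined ratios (zero
#' denominator) are reported as `NA`.
#'
#' @param tp,fn,fp,tn nonnegative integer confusion counts.
#' @return object of class `evaluation_report`: list with `counts`,
#'   `metrics` (full precision), `printed` (truncated to one decimal).
#' @export
evaluation_report <- function(tp, fn, fp, tn) {
  cnt <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (!all(vapply(cnt, is_count, TRUE)))
    stopf("confusion counts must be nonnegative integers")
  if (sum(cnt) == 0) stopf("empty test set: all confusion counts are zero")
  m <- confusion_metrics(tp, fn, fp, tn)
  structure(list(counts = cnt, metrics = m, printed = truncate1(m)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Test-set evaluation (n = %d): tp %d, fn %d, fp %d, tn %d\n",
              sum(x$counts), x$counts["tp"], x$counts["fn"], x$counts["fp"],
              x$counts["tn"]))
  for (m in names(x$metrics))
    cat(sprintf("  %-12s %s%%\n", m,
                ifelse(is.na(x$printed[m]), "undefined",
                       format(x$printed[m]))))
  invisible(x)
}

#' Evaluate a fitted classifier on a held-out test set
#'
#' Predicts each test row at the fixed p >= 0.5 rule (ties positive) and
#' tabulates the confusion matrix with case = positive. Test rows must be
#' disjoint from the rows the model was trained on.
#'
#' @param model a [roi_logit()] fit.
#' @param test_features `feature_table` or matrix of test rows.
#' @param test_labels binary vector (1 = case).
#' @param covariates covariate rows if `test_features` is a bare matrix.
#' @return an [evaluation_report()].
#' @export
evaluate <- function(model, test_features, test_labels, covariates = NULL) {
  if (inherits(test_features, "feature_table") &&
      length(test_labels) != nrow(test_features$counts))
    stopf("labels length %d != %d test rows", length(test_labels),
          nrow(test_features$counts))
  if (length(test_labels) == 0) stopf("empty test set")
  pred <- predict(model, test_features, type = "class",
                  covariates = covariates)
  y <- as.integer(test_labels)
  evaluation_report(tp = sum(pred == 1 & y == 1),
                    fn = sum(pred == 0 & y == 1),
                    fp = sum(pred == 1 & y == 0),
                    tn = sum(pred == 0 & y == 0))
}

# Does exact metric value x (percent) match printed value p at one decimal?
# Published tables mix one-decimal truncation and half-up rounding, so a
# quadruple matches when either convention reproduces the printed value.
matches_printed <- function(x, p) {
  !is.na(x) & (truncate1(x) == p | floor(x * 10 + 0.5) / 10 == p)
}

#' Reconstruct confusion matrices from printed metrics
#'
#' Exhaustively enumerates all nonnegative integer quadruples
#' (tp, fn, fp, tn) with total at most `max_n` whose metrics reproduce the
#' given printed percentages at one decimal. Printed tables mix truncation
#' and half-up rounding, so a metric matches if either convention yields the
#' printed value. Metrics given as `NA` are not constrained. An empty result
#' is valid: no confusion matrix of that size prints those values.
#'
#' @param metrics named numeric vector with any of `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, as printed percentages.
#' @param max_n maximum total test-set size to search.
#' @return data.frame with columns `tp`, `fn`, `fp`, `tn`, `n` plus the
#'   exact metric values, one row per solution.
#' @examples
#' solve_confusion(c(accuracy = 80.9, sensitivity = 87.5, specificity = 76.9,
#'                   ppv = 70, npv = 90.9), max_n = 30)
#' @export
solve_confusion <- function(metrics, max_n = 30) {
  if (!is_count(max_n) || max_n < 1) stopf("max_n must be a positive integer")
  want <- metrics[!is.na(metrics)]
  bad <- setdiff(names(want),
                 c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
  if (length(bad)) stopf("unknown metric(s): %s", paste(bad, collapse = ", "))
  grid <- expand.grid(tp = 0:max_n, fn = 0:max_n, fp = 0:max_n, tn = 0:max_n)
  grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= max_n, ]
  ex <- with(grid, {
    n <- tp + fn + fp + tn
    data.frame(accuracy = 100 * (tp + tn) / n,
               sensitivity = ifelse(tp + fn == 0, NA, 100 * tp / (tp + fn)),
               specificity = ifelse(tn + fp == 0, NA, 100 * tn / (tn + fp)),
               ppv = ifelse(tp + fp == 0, NA, 100 * tp / (tp + fp)),
               npv = ifelse(tn + fn == 0, NA, 100 * tn / (tn + fn)))
  })
  ok <- rep(TRUE, nrow(grid))
  for (m in names(want)) ok <- ok & matches_printed(ex[[m]], want[[m]])
  out <- cbind(grid[ok, , drop = FALSE],
               n = rowSums(grid[ok, , drop = FALSE]),
               ex[ok, names(want), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Test-set subgroup cross-validation of a fixed model
#'
#' Partitions the test set into `k` non-overlapping subgroups (sizes
#' differing by at most one, seeded shuffle) and evaluates the already
#' fitted model on each; no refitting takes place and no training rows are
#' involved. The subgroup accuracies, weighted by subgroup size, average
#' exactly to the whole-test-set accuracy.
#'
#' @param model a fitted `roi_logit`.
#' @param test_features,test_labels the held-out test rows.
#' @param k number of subgroups (default 10); must not exceed the test size.
#' @param seed integer seed for the partition.
#' @param covariates covariate rows if `test_features` is a bare matrix.
#' @return object of class `subgroup_cv`: list with `mean_accuracy`
#'   (unweighted mean over subgroups, %), `subgroup_accuracy`,
#'   `subgroup_size`, `k`, `seed`.
#' @export
test_subgroup_cv <- function(model, test_features, test_labels, k = 10L,
                             seed = 1L, covariates = NULL) {
  n <- length(test_labels)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (k > n) stopf("k = %d exceeds test size %d", k, n)
  pred <- predict(model, test_features, type = "class",
                  covariates = covariates)
  y <- as.integer(test_labels)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  acc <- vapply(seq_len(k), function(g)
    100 * mean(pred[fold == g] == y[fold == g]), numeric(1))
  structure(list(mean_accuracy = mean(acc),
                 subgroup_accuracy = acc,
                 subgroup_size = as.integer(table(factor(fold,
                                                         levels = seq_len(k)))),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "subgroup_cv")
}

#' @export
print.subgroup_cv <- function(x, ...) {
  cat(sprintf("Test-set %d-subgroup cross-validation: mean accuracy %.1f%%\n",
              x$k, truncate1(x$mean_accuracy)))
  invisible(x)
}

#' Empirical permutation p-value from exceedance counts
#'
#' Raw count ratio: the fraction of permutation runs whose accuracy met or
#' exceeded the observed accuracy (11 exceedances in 10,000 runs gives
#' 0.0011). The add-one estimate `(count + 1) / (runs + 1)` is the
#' recommended companion when the raw ratio is 0.
#'
#' @param n_exceed number of runs with accuracy >= observed.
#' @param n_runs total permutation runs.
#' @param add_one use the add-one correction (default FALSE).
#' @return p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(n_exceed, n_runs, add_one = FALSE) {
  if (!is_count(n_exceed) || !is_count(n_runs) || n_runs < 1 ||
      n_exceed > n_runs)
    stopf("need 0 <= n_exceed <= n_runs with n_runs >= 1")
  if (add_one) (n_exceed + 1) / (n_runs + 1) else n_exceed / n_runs
}

# Mode over the discrete attainable accuracy values; ties -> smallest value.
accuracy_mode <- function(acc) {
  tab <- table(acc)
  as.numeric(names(tab)[which.max(tab)])
}

#' Label-shuffle permutation test of classifier accuracy
#'
#' Forms the null distribution of test accuracy by permuting the group
#' labels: each run shuffles the labels over subjects, draws a fresh
#' stratified split of the shuffled sample, refits the penalized logistic
#' model on the shuffled training rows over the fixed selected-region set,
#' and evaluates on the shuffled test rows. The empirical p is the fraction
#' of runs with accuracy at or above the observed accuracy. If no run
#' reaches it within the first `n_runs`, `escalation_runs` further runs are
#' executed and the p recomputed over all runs executed. Feature selection
#' is not rerun per shuffle by default; `reselect = TRUE` enables the
#' stricter (much costlier) variant that reruns RFE inside every run.
#'
#' @param features a `feature_table` (all subjects).
#' @param labels binary vector; default `features$labels`.
#' @param selected_regions region ids the model is fit on (from the
#'   unshuffled pipeline's selection).
#' @param observed_accuracy the unshuffled pipeline's test accuracy, %.
#' @param n_runs first-stage permutation count (default 1000; < 100 warns).
#' @param escalation_runs extra runs if no exceedance occurs (default 10000).
#' @param ratio training fraction per shuffled split (default 0.7).
#' @param penalty ridge strength (default `1/n_train`).
#' @param seed integer seed governing all shuffles and splits.
#' @param reselect rerun RFE on each shuffled training set (default FALSE).
#' @param rfe_target RFE target when `reselect = TRUE`.
#' @param alpha significance level for the `significant` flag (0.05).
#' @return object of class `shuffle_test`: `observed_accuracy`, `n_runs`
#'   (total executed), `shuffled_accuracies` (%), `empirical_p` (raw ratio),
#'   `empirical_p_add_one`, `mean`, `mode`, `max`, `escalated`,
#'   `significant`.
#' @export
shuffle_test <- function(features, labels = NULL, selected_regions,
                         observed_accuracy, n_runs = 1000L,
                         escalation_runs = 10000L, ratio = 0.7,
                         penalty = NULL, seed = 1L, reselect = FALSE,
                         rfe_target = NULL, alpha = 0.05) {
  stopifnot(inherits(features, "feature_table"))
  if (is.null(labels)) labels <- features$labels
  labels <- as.integer(labels)
  if (n_runs < 100)
    warning("fewer than 100 permutation runs gives an unstable empirical p",
            call. = FALSE)
  run_one <- function() {
    perm <- sample(labels)
    sp <- stratified_split(perm, ratio,
                           seed = sample.int(.Machine$integer.max, 1))
    tr <- subset_features(features, sp$train_idx)
    te <- subset_features(features, sp$test_idx)
    sel <- if (reselect)
      rfe_select(tr, perm[sp$train_idx], n_target = rfe_target,
                 penalty = penalty)$selected_region_ids
    else selected_regions
    fit <- roi_logit(tr, perm[sp$train_idx], selected_regions = sel,
                     penalty = penalty)
    100 * mean(predict(fit, te, type = "class") == perm[sp$test_idx])
  }
  with_seed(seed, {
    acc <- vapply(seq_len(n_runs), function(i) run_one(), numeric(1))
    escalated <- FALSE
    if (sum(acc >= observed_accuracy) == 0 && escalation_runs > 0) {
      escalated <- TRUE
      acc <- c(acc, vapply(seq_len(escalation_runs), function(i) run_one(),
                           numeric(1)))
    }
    total <- length(acc)
    exceed <- sum(acc >= observed_accuracy)
    structure(list(observed_accuracy = observed_accuracy,
                   n_runs = total,
                   shuffled_accuracies = acc,
                   empirical_p = empirical_pvalue(exceed, total),
                   empirical_p_add_one = empirical_pvalue(exceed, total,
                                                          add_one = TRUE),
                   mean = mean(acc), mode = accuracy_mode(acc),
                   max = max(acc), escalated = escalated,
                   significant = empirical_pvalue(exceed, total) < alpha,
                   alpha = alpha, seed = as.integer(seed)),
              class = "shuffle_test")
  })
}

#' @export
print.shuffle_test <- function(x, ...) {
  cat(sprintf(
    "Shuffle test: observed %.1f%%, %d runs%s\n",
    x$observed_accuracy, x$n_runs, if (x$escalated) " (escalated)" else ""))
  cat(sprintf(
    "  empirical p = %.4g (add-one %.4g); null mean %.1f%%, mode %.1f%%, max %.1f%%\n",
    x$empirical_p, x$empirical_p_add_one, x$mean, x$mode, x$max))
  cat(sprintf("  %ssignificant at p < %g\n",
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @export
plot.shuffle_test <- function(x, ...) {
  graphics::hist(x$shuffled_accuracies, breaks = 30,
                 main = "Label-shuffle null distribution",
                 xlab = "shuffled test accuracy (%)", ...)
  graphics::abline(v = x$observed_accuracy, lwd = 2)
  invisible(x)
}
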