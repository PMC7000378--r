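test_that("evaluation metrics recompute exactly from their counts", {
  r <- evaluation_report(tp = 7, fn = 1, fp = 3, tn = 10)
  expect_equal(unname(r$metrics["accuracy"]), 100 * 17 / 21)
  expect_equal(unname(r$metrics["sensitivity"]), 87.5)
  expect_equal(unname(r$metrics["specificity"]), 100 * 10 / 13)
  expect_equal(unname(r$metrics["ppv"]), 70)
  expect_equal(unname(r$metrics["npv"]), 100 * 10 / 11)
  expect_identical(sum(r$counts), 21)

  perfect <- evaluation_report(tp = 5, fn = 0, fp = 0, tn = 5)
  expect_true(all(perfect$metrics == 100))

  # undefined ratios are NA, not 0
  noneg <- evaluation_report(tp = 4, fn = 1, fp = 0, tn = 0)
  expect_true(is.na(noneg$metrics["specificity"]))
  expect_equal(unname(noneg$metrics["npv"]), 0)
  expect_error(evaluation_report(0, 0, 0, 0), "empty")
  expect_error(evaluation_report(-1, 0, 0, 2), "nonnegative")
})

test_that("evaluate tabulates predictions with case positive", {
  ft <- planted_feature_table(n = 40, p = 4, signal_cols = 1, shift = 20,
                              seed = 2)
  sp <- stratified_split(ft$labels, 0.7, seed = 2)
  fit <- roi_logit(ft$counts[sp$train_idx, ], ft$labels[sp$train_idx])
  rep_ <- evaluate(fit, ft$counts[sp$test_idx, ], ft$labels[sp$test_idx])
  expect_identical(sum(rep_$counts), length(sp$test_idx))
  # near-deterministic signal: test accuracy must be perfect here
  expect_equal(unname(rep_$metrics["accuracy"]), 100)
  expect_error(evaluate(fit, ft$counts[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("confusion solver recovers the printed Day-1 and Day-2 tables", {
  day1 <- c(accuracy = 80.9, sensitivity = 87.5, specificity = 76.9,
            ppv = 70, npv = 90.9)
  sol1 <- solve_confusion(day1, max_n = 30)
  expect_true(any(sol1$tp == 7 & sol1$fn == 1 & sol1$fp == 3 &
                    sol1$tn == 10))
  expect_true(all(sol1$n <= 30))

  day2 <- c(accuracy = 76.1, sensitivity = 76.9, specificity = 75,
            ppv = 83.3, npv = 66.7)
  sol2 <- solve_confusion(day2, max_n = 30)
  expect_true(any(sol2$tp == 10 & sol2$fn == 3 & sol2$fp == 2 &
                    sol2$tn == 6))

  # degenerate all-100% metrics admit every pure tp/tn split
  all100 <- solve_confusion(c(accuracy = 100, sensitivity = 100,
                              specificity = 100, ppv = 100, npv = 100),
                            max_n = 4)
  expect_gt(nrow(all100), 1)
  expect_true(all(all100$fn == 0 & all100$fp == 0))
  # an impossible combination yields the empty set
  none <- solve_confusion(c(accuracy = 10, sensitivity = 100,
                            specificity = 100), max_n = 10)
  expect_identical(nrow(none), 0L)
  expect_error(solve_confusion(c(foo = 1), 10), "unknown metric")
})

test_that("subgroup cross-validation partitions and averages correctly", {
  ft <- planted_feature_table(n = 70, p = 4, signal_cols = 1, shift = 6,
                              seed = 6)
  sp <- stratified_split(ft$labels, 0.7, seed = 6)
  fit <- roi_logit(ft$counts[sp$train_idx, ], ft$labels[sp$train_idx])
  te_X <- ft$counts[sp$test_idx, ]
  te_y <- ft$labels[sp$test_idx]

  # k = 1 equals plain test accuracy
  cv1 <- test_subgroup_cv(fit, te_X, te_y, k = 1, seed = 1)
  plain <- evaluate(fit, te_X, te_y)$metrics[["accuracy"]]
  expect_equal(cv1$mean_accuracy, plain)

  # subgroup accuracies weighted by size average exactly to the test accuracy
  cv <- test_subgroup_cv(fit, te_X, te_y, k = 5, seed = 2)
  expect_identical(sum(cv$subgroup_size), length(te_y))
  expect_true(max(cv$subgroup_size) - min(cv$subgroup_size) <= 1)
  expect_equal(sum(cv$subgroup_accuracy * cv$subgroup_size) / length(te_y),
               plain)
  expect_error(test_subgroup_cv(fit, te_X, te_y, k = 100), "exceeds")

  # a perfect predictor scores 100 in every subgroup
  strong <- planted_feature_table(n = 70, p = 4, signal_cols = 1,
                                  shift = 50, seed = 6)
  fit2 <- roi_logit(strong$counts[sp$train_idx, ], strong$labels[sp$train_idx])
  cvp <- test_subgroup_cv(fit2, strong$counts[sp$test_idx, ],
                          strong$labels[sp$test_idx], k = 7, seed = 3)
  expect_true(all(cvp$subgroup_accuracy == 100))
})

test_that("empirical p arithmetic matches the count ratio", {
  expect_equal(empirical_pvalue(11, 10000), 0.0011)
  expect_equal(empirical_pvalue(0, 1000), 0)
  expect_equal(empirical_pvalue(0, 1000, add_one = TRUE), 1 / 1001)
  expect_error(empirical_pvalue(5, 4), "n_exceed")
})

test_that("shuffle test basics: trivial observation, shapes, determinism", {
  ft <- planted_feature_table(n = 24, p = 4, signal_cols = integer(0),
                              seed = 9)
  st <- suppressWarnings(shuffle_test(
    ft, selected_regions = as.character(1:4), observed_accuracy = 0,
    n_runs = 60, escalation_runs = 0, seed = 5))
  # every attainable accuracy is >= 0, so p = 1
  expect_equal(st$empirical_p, 1)
  expect_identical(length(st$shuffled_accuracies), st$n_runs)
  expect_false(st$escalated)
  st2 <- suppressWarnings(shuffle_test(
    ft, selected_regions = as.character(1:4), observed_accuracy = 0,
    n_runs = 60, escalation_runs = 0, seed = 5))
  expect_identical(st$shuffled_accuracies, st2$shuffled_accuracies)
  expect_warning(shuffle_test(ft, selected_regions = as.character(1:4),
                              observed_accuracy = 0, n_runs = 50,
                              escalation_runs = 0, seed = 1),
                 "unstable")
})

test_that("shuffle test escalates when the observation is never reached", {
  ft <- planted_feature_table(n = 24, p = 4, signal_cols = integer(0),
                              seed = 14)
  st <- suppressWarnings(shuffle_test(
    ft, selected_regions = as.character(1:4), observed_accuracy = 101,
    n_runs = 30, escalation_runs = 45, seed = 2))
  expect_true(st$escalated)
  # escalation never decreases the denominator; p uses all runs executed
  expect_identical(st$n_runs, 75L)
  expect_equal(st$empirical_p, 0)
  expect_equal(st$empirical_p_add_one, 1 / 76)
  # a raw ratio of 0 is below any alpha; the add-one estimate is the
  # conservative companion for exactly this situation
  expect_true(st$significant)
  # the mode lives on the attainable accuracy grid of the test-set size
  n_test <- length(stratified_split(ft$labels, 0.7, seed = 1)$test_idx)
  expect_true(st$mode %in% (100 * (0:n_test) / n_test))
})
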