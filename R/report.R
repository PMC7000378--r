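#' Read a per-region coefficient table
#'
#' Parses a TSV with columns `region_id`, `region`, `day1`, `day2`: one row
#' per atlas region selected by a session's classifier, its log-odds
#' coefficient in the Day-1 (pre-exercise) and/or Day-2 (post-exercise)
#' model, blank where the region was not selected that day. A region counts
#' as selected for a day whenever its cell is non-blank — a printed 0.000
#' coefficient still marks selection. The package ships such a table for the
#' CFS-vs-control study at
#' `system.file("extdata", "aal_region_coefficients.tsv",
#'  package = "roiclassify")`.
#'
#' @param path TSV path.
#' @return data.frame with `region_id`, `region`, `day1`, `day2` (NA where
#'   absent), `selected_day1`, `selected_day2`.
#' @export
read_region_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "character",
                                         "character", "character"))
  need <- c("region_id", "region", "day1", "day2")
  if (!all(need %in% names(df)))
    stopf("region table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$region_id))
    stopf("duplicate region ids in %s", path)
  sel1 <- !is.na(df$day1) & nzchar(trimws(df$day1))
  sel2 <- !is.na(df$day2) & nzchar(trimws(df$day2))
  df$day1 <- ifelse(sel1, suppressWarnings(as.numeric(df$day1)), NA_real_)
  df$day2 <- ifelse(sel2, suppressWarnings(as.numeric(df$day2)), NA_real_)
  df$selected_day1 <- sel1
  df$selected_day2 <- sel2
  df
}

#' Region overlap between two sessions' selected sets
#'
#' Splits two selected-region sets into the shared regions and those
#' exclusive to each session.
#'
#' @param day1,day2 vectors of selected region ids, or data.frames from
#'   [read_region_table()] (their `selected_day1` / `selected_day2` flags
#'   are used).
#' @return list with `shared`, `only_day1`, `only_day2` (sorted ids).
#' @export
region_overlap <- function(day1, day2) {
  if (is.data.frame(day1) && is.data.frame(day2)) {
    tab <- day1
    day1 <- tab$region_id[tab$selected_day1]
    day2 <- tab$region_id[tab$selected_day2]
  } else if (is.data.frame(day1)) {
    day1 <- day1$region_id[day1$selected_day1]
  } else if (is.data.frame(day2)) {
    day2 <- day2$region_id[day2$selected_day2]
  }
  if (anyDuplicated(day1) || anyDuplicated(day2))
    stopf("selected-region sets must not contain duplicates")
  list(shared = sort(intersect(day1, day2)),
       only_day1 = sort(setdiff(day1, day2)),
       only_day2 = sort(setdiff(day2, day1)))
}

#' Per-group cohort demographics
#'
#' Group sizes, sex counts with one-decimal percentages, and mean +/- SD of
#' numeric covariates, per group. The SD of a single-subject group is
#' undefined and reported as `NA`.
#'
#' @param labels binary group vector (1 = case, 0 = control).
#' @param covariates data.frame with at least `sex` (1 = male) and any
#'   numeric columns (e.g. `age`).
#' @return object of class `cohort_summary`: data.frame, one row per group.
#' @export
cohort_summary <- function(labels, covariates) {
  if (length(labels) == 0) stopf("empty cohort")
  labels <- as.integer(labels)
  groups <- list(control = which(labels == 0), case = which(labels == 1))
  groups <- groups[lengths(groups) > 0]
  num_cols <- names(covariates)[vapply(covariates, is.numeric, TRUE) &
                                  names(covariates) != "sex"]
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    out <- data.frame(group = g, n = length(i))
    if ("sex" %in% names(covariates)) {
      males <- sum(covariates$sex[i] == 1)
      out$male_n <- males
      out$male_pct <- round(100 * males / length(i), 1)
    }
    for (cc in num_cols) {
      out[[paste0(cc, "_mean")]] <- mean(covariates[[cc]][i])
      out[[paste0(cc, "_sd")]] <- if (length(i) > 1)
        stats::sd(covariates[[cc]][i]) else NA_real_
    }
    out
  })
  structure(do.call(rbind, rows), class = c("cohort_summary", "data.frame"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  y <- as.data.frame(x)
  nc <- vapply(y, is.numeric, TRUE)
  y[nc] <- lapply(y[nc], function(v) round(v, 1))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable of [run_pipeline()]; the defaults are the package's
#' reference settings (threshold t = 3.17, 70:30 stratified split, 10
#' cross-validation subgroups, 1,000 shuffle runs escalating by 10,000).
#'
#' @param threshold t cutoff for voxel counting.
#' @param ratio training fraction.
#' @param k test-set cross-validation subgroups.
#' @param rfe_target features kept by RFE (`NULL` = half).
#' @param penalty ridge strength (`NULL` = `1/n_train`).
#' @param n_shuffles,escalation shuffle-test run counts.
#' @param seed master integer seed for the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(threshold = 3.17, ratio = 0.7, k = 10L,
                       rfe_target = NULL, penalty = NULL,
                       n_shuffles = 1000L, escalation = 10000L, seed = 1L) {
  structure(list(threshold = threshold, ratio = ratio, k = as.integer(k),
                 rfe_target = rfe_target, penalty = penalty,
                 n_shuffles = as.integer(n_shuffles),
                 escalation = as.integer(escalation),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full classification pipeline
#'
#' Executes the whole analysis on a cohort of t-statistic volumes: feature
#' extraction at the configured threshold, stratified split, the triple
#' collinearity screen (train / test / combined), recursive feature
#' elimination on the training rows, the penalized logistic fit with age and
#' sex as covariates, test-set evaluation, test-set subgroup
#' cross-validation, and the label-shuffle permutation test. Every stage is
#' seeded from `config$seed`, so identical configs give identical artifacts.
#' With `out_dir` set, all result tables are serialized there (features.csv,
#' corr.csv, selection.json, model.json, evaluation.json, shuffle.json,
#' shuffle.csv, plus config.json and a stage log).
#'
#' @param cohort list of `subject_volume`s (or a precomputed
#'   `feature_table`, in which case extraction is skipped).
#' @param atlas the matching `atlas_volume` (ignored when `cohort` is
#'   already a `feature_table`).
#' @param config a [run_config()].
#' @param out_dir optional directory for the serialized artifacts.
#' @return object of class `pipeline_run`: list with `features`, `split`,
#'   `screen`, `selection`, `model`, `evaluation`, `cv`, `shuffle`,
#'   `config`, `log`.
#' @export
run_pipeline <- function(cohort, atlas = NULL, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stamp <- function(stage, seed = NA_integer_) {
    log[[length(log) + 1]] <<- list(stage = stage, seed = seed,
                                    time = format(Sys.time(), "%H:%M:%OS3"))
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  features <- if (inherits(cohort, "feature_table")) cohort else {
    stamp("extract", config$seed)
    wrap("extract", extract_features(cohort, atlas,
                                     threshold = config$threshold))
  }
  labels <- features$labels

  stamp("split", config$seed)
  split <- wrap("split", stratified_split(labels, config$ratio,
                                          seed = config$seed))
  stamp("screen", config$seed)
  screen <- wrap("screen", screen_collinearity(features, split))

  tr <- subset_features(features, split$train_idx)
  te <- subset_features(features, split$test_idx)

  stamp("rfe", config$seed)
  selection <- wrap("rfe", rfe_select(tr, labels[split$train_idx],
                                      n_target = config$rfe_target,
                                      penalty = config$penalty,
                                      seed = config$seed))
  stamp("fit", config$seed)
  model <- wrap("fit", roi_logit(tr, labels[split$train_idx],
                                 selected_regions =
                                   selection$selected_region_ids,
                                 penalty = config$penalty,
                                 seed = config$seed))
  stamp("evaluate", config$seed)
  evaluation <- wrap("evaluate", evaluate(model, te, labels[split$test_idx]))
  stamp("subgroup_cv", config$seed)
  cv <- wrap("subgroup_cv", test_subgroup_cv(model, te,
                                             labels[split$test_idx],
                                             k = min(config$k,
                                                     length(split$test_idx)),
                                             seed = config$seed))
  stamp("shuffle_test", config$seed)
  shuffle <- wrap("shuffle_test", shuffle_test(
    features, labels, selection$selected_region_ids,
    observed_accuracy = evaluation$metrics[["accuracy"]],
    n_runs = config$n_shuffles, escalation_runs = config$escalation,
    ratio = config$ratio, penalty = config$penalty, seed = config$seed))

  run <- structure(list(features = features, split = split, screen = screen,
                        selection = selection, model = model,
                        evaluation = evaluation, cv = cv, shuffle = shuffle,
                        config = config, log = log),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run\n")
  cat(sprintf("  %d subjects, %d regions, threshold t >= %g\n",
              nrow(x$features$counts), ncol(x$features$counts),
              x$config$threshold))
  cat(sprintf("  selected %d regions; test accuracy %.1f%% (CV mean %.1f%%)\n",
              length(x$selection$selected_region_ids),
              truncate1(x$evaluation$metrics[["accuracy"]]),
              truncate1(x$cv$mean_accuracy)))
  cat(sprintf("  shuffle test: p = %.4g over %d runs%s\n",
              x$shuffle$empirical_p, x$shuffle$n_runs,
              if (x$shuffle$escalated) " (escalated)" else ""))
  invisible(x)
}

# Serialize every artifact of a pipeline run under out_dir.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_features(run$features, p("features.csv"))
  write_correlation(run$screen$combined$correlation, p("corr.csv"))
  jsonlite::write_json(list(
    selected_region_ids = run$selection$selected_region_ids,
    elimination_order = run$selection$elimination_order,
    n_target = run$selection$n_target),
    p("selection.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_model(run$model, p("model.json"))
  jsonlite::write_json(list(
    counts = as.list(run$evaluation$counts),
    metrics = as.list(run$evaluation$metrics),
    printed = as.list(run$evaluation$printed),
    cv_mean_accuracy = run$cv$mean_accuracy,
    cv_subgroup_accuracy = run$cv$subgroup_accuracy),
    p("evaluation.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sh <- run$shuffle
  jsonlite::write_json(list(
    observed_accuracy = sh$observed_accuracy, n_runs = sh$n_runs,
    empirical_p = sh$empirical_p,
    empirical_p_add_one = sh$empirical_p_add_one,
    mean = sh$mean, mode = sh$mode, max = sh$max,
    escalated = sh$escalated, significant = sh$significant),
    p("shuffle.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(data.frame(run = seq_along(sh$shuffled_accuracies),
                              accuracy = sh$shuffled_accuracies),
                   p("shuffle.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(run$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  jsonlite::write_json(run$log, p("log.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
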