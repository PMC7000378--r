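#' Stratified train/test split
#'
#' Samples each class without replacement into the training set. The
#' per-class training count is round-half-up of `ratio` times the class
#' size, so a 70:30 split of 38 cases and 31 controls trains on 27 + 22
#' subjects and tests on the remaining 11 + 9. The same seed always yields
#' the same split.
#'
#' @param labels binary vector (1 = case, 0 = control).
#' @param ratio training fraction, in \[0.5, 0.9\]; default 0.7.
#' @param seed integer seed.
#' @return object of class `split_spec`: list with `train_idx`, `test_idx`
#'   (row indices), `ratio`, `seed`, `stratified = TRUE`.
#' @export
stratified_split <- function(labels, ratio = 0.7, seed = 1L) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio < 0.5 || ratio > 0.9)
    stopf("ratio must lie in [0.5, 0.9], got %s", format(ratio))
  labels <- as.integer(labels)
  for (cl in c(0L, 1L)) {
    if (sum(labels == cl) < 2)
      stopf("class %d has %d member(s); need at least 2", cl,
            sum(labels == cl))
  }
  train <- with_seed(seed, {
    unlist(lapply(c(1L, 0L), function(cl) {
      idx <- which(labels == cl)
      n_tr <- as.integer(floor(ratio * length(idx) + 0.5))  # round half up
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)          # both sides non-empty
      sort(sample(idx, n_tr))
    }))
  })
  train <- sort(train)
  structure(list(train_idx = train,
                 test_idx = setdiff(seq_along(labels), train),
                 ratio = ratio, seed = as.integer(seed), stratified = TRUE),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Stratified split: %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$ratio, x$seed))
  invisible(x)
}

#' Fit the ridge-penalized logistic classifier on selected regions
#'
#' Fits the logit model p(x) = 1 / (1 + exp(-(b0 + b1 x1 + ... + bi xi)))
#' by penalized maximum likelihood: region features are standardized with
#' training-set means and standard deviations; covariates (age, sex) are
#' appended unstandardized, share the ridge penalty, and are never subject
#' to elimination; a small L2 penalty (default `1/n`) keeps the
#' small-sample fit finite under separation. The default optimizer is a
#' deterministic Newton/IRLS maximizer; a seeded stochastic-gradient option
#' is available via `method = "sgd"`.
#'
#' @param train_features numeric matrix (training subjects x regions, with
#'   region-id colnames) or a `feature_table` whose rows are all training
#'   rows.
#' @param train_labels binary vector (1 = case).
#' @param covariates optional data.frame (e.g. age, sex) aligned with rows.
#' @param selected_regions optional character/integer vector restricting the
#'   fit to these region columns (e.g. from [rfe_select()]).
#' @param penalty ridge strength lambda (>= 0); default `1/n`. With
#'   `penalty = 0` a separable fit triggers a warning and refits with a
#'   small fallback ridge so coefficients stay finite.
#' @param seed integer, used only by the SGD optimizer.
#' @param method `"irls"` (default) or `"sgd"`.
#' @return object of class `roi_logit` with components `intercept`,
#'   `coefficients` (per selected region, log-odds per standardized
#'   voxel-count unit), `covariate_coefficients`, `feature_scaling`,
#'   `selected_region_ids`, `penalty`, `deviance`, `null_deviance`,
#'   `converged`, `fitted` (training probabilities), plus the usual methods
#'   (`print`, `summary`, `coef`, `predict`, `residuals`, `simulate`).
#' @examples
#' set.seed(1)
#' X <- matrix(rpois(60, 5), 20, 3, dimnames = list(NULL, c("1", "2", "3")))
#' y <- rbinom(20, 1, stats::plogis(scale(X[, 1])))
#' fit <- roi_logit(X, y)
#' coef(fit)
#' predict(fit, X[1:2, , drop = FALSE])
#' @export
roi_logit <- function(train_features, train_labels, covariates = NULL,
                      selected_regions = NULL, penalty = NULL, seed = 1L,
                      method = c("irls", "sgd")) {
  method <- match.arg(method)
  if (inherits(train_features, "feature_table")) {
    if (is.null(covariates)) covariates <- train_features$covariates
    train_features <- train_features$counts
  }
  M <- as.matrix(train_features)
  if (is.null(colnames(M))) colnames(M) <- as.character(seq_len(ncol(M)))
  if (!is.null(selected_regions)) {
    sel <- as.character(selected_regions)
    missing_sel <- setdiff(sel, colnames(M))
    if (length(missing_sel))
      stopf("selected regions absent from features: %s",
            paste(missing_sel, collapse = ", "))
    M <- M[, sel, drop = FALSE]
  }
  y <- as.integer(train_labels)
  n <- nrow(M)
  if (length(y) != n) stopf("labels length %d != %d rows", length(y), n)
  if (is.null(penalty)) penalty <- 1 / n
  if (penalty < 0) stopf("penalty must be >= 0")

  sc <- feature_scaling(M)
  Xf <- apply_scaling(M, sc)
  C <- if (is.null(covariates)) NULL else {
    Cm <- as.matrix(covariates)
    storage.mode(Cm) <- "double"
    Cm
  }
  X <- cbind(intercept = 1, Xf, C)

  fitter <- function(lam) {
    if (method == "sgd") ridge_logit_sgd(X, y, lam, seed = seed)
    else ridge_logit_irls(X, y, lam)
  }
  fit <- fitter(penalty)
  separated <- function(f) {
    mu <- stats::plogis(drop(X %*% f$beta))
    all(mu[y == 1] > 1 - 1e-4) && all(mu[y == 0] < 1e-4)
  }
  if (penalty == 0 && (!fit$converged || max(abs(fit$beta)) > 30 ||
                       separated(fit))) {
    warning("apparent separation with zero penalty; refitting with a small ",
            "fallback ridge (lambda = 1e-4) to keep coefficients finite",
            call. = FALSE)
    penalty <- 1e-4
    fit <- fitter(penalty)
  }
  if (!fit$converged)
    stopf("optimizer failed to converge; final gradient norm %.3g",
          fit$grad_norm)

  p <- ncol(M)
  beta <- fit$beta
  eta <- drop(X %*% beta)
  null_dev <- -2 * logit_loglik(rep(stats::qlogis(pmin(pmax(mean(y), 1e-12),
                                                       1 - 1e-12)), n), y)
  structure(list(
    intercept = unname(beta[1]),
    coefficients = stats::setNames(beta[1 + seq_len(p)], colnames(M)),
    covariate_coefficients = if (is.null(C)) numeric(0) else
      stats::setNames(beta[(p + 2):length(beta)], colnames(C)),
    feature_scaling = sc,
    selected_region_ids = colnames(M),
    penalty = penalty,
    method = method,
    seed = as.integer(seed),
    deviance = -2 * logit_loglik(eta, y),
    penalized_deviance = fit$deviance,
    null_deviance = null_dev,
    converged = fit$converged,
    iterations = fit$iterations,
    n_train = n,
    labels = y,
    fitted = stats::plogis(eta)
  ), class = "roi_logit")
}

#' @export
print.roi_logit <- function(x, ...) {
  cat(sprintf(
    "Penalized logistic classifier: %d regions + %d covariates, n = %d\n",
    length(x$coefficients), length(x$covariate_coefficients), x$n_train))
  cat(sprintf("  deviance %.2f (null %.2f), lambda = %.4g, %s\n",
              x$deviance, x$null_deviance, x$penalty, x$method))
  invisible(x)
}

#' @export
summary.roi_logit <- function(object, ...) {
  cf <- data.frame(
    term = c("(intercept)", names(object$coefficients),
             names(object$covariate_coefficients)),
    estimate = c(object$intercept, unname(object$coefficients),
                 unname(object$covariate_coefficients)))
  acc <- mean((object$fitted >= 0.5) == (object$labels == 1)) * 100
  out <- list(coefficients = cf, deviance = object$deviance,
              null_deviance = object$null_deviance,
              train_accuracy = acc, n_train = object$n_train,
              penalty = object$penalty)
  class(out) <- "summary.roi_logit"
  out
}

#' @export
print.summary.roi_logit <- function(x, ...) {
  cat(sprintf("n = %d, deviance %.2f (null %.2f), training accuracy %.1f%%\n",
              x$n_train, x$deviance, x$null_deviance,
              truncate1(x$train_accuracy)))
  cf <- x$coefficients
  cf$estimate <- round(cf$estimate, 3)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
coef.roi_logit <- function(object, ...) {
  c("(intercept)" = object$intercept, object$coefficients,
    object$covariate_coefficients)
}

# Standardized design row(s) for new data; errors name any missing feature.
model_design <- function(object, newdata, covariates = NULL) {
  if (inherits(newdata, "feature_table")) {
    if (is.null(covariates)) covariates <- newdata$covariates
    newdata <- newdata$counts
  }
  M <- as.matrix(newdata)
  if (is.null(colnames(M))) colnames(M) <- as.character(seq_len(ncol(M)))
  missing_feat <- setdiff(object$selected_region_ids, colnames(M))
  if (length(missing_feat))
    stopf("missing feature(s): %s", paste(missing_feat, collapse = ", "))
  M <- M[, object$selected_region_ids, drop = FALSE]
  Xf <- apply_scaling(M, object$feature_scaling)
  if (length(object$covariate_coefficients)) {
    cn <- names(object$covariate_coefficients)
    if (is.null(covariates))
      stopf("missing covariate(s): %s", paste(cn, collapse = ", "))
    Cm <- as.matrix(covariates)
    missing_cov <- setdiff(cn, colnames(Cm))
    if (length(missing_cov))
      stopf("missing covariate(s): %s", paste(missing_cov, collapse = ", "))
    Xf <- cbind(Xf, Cm[, cn, drop = FALSE])
  }
  Xf
}

#' Predict group-membership probabilities
#'
#' Evaluates the fitted logit equation on new rows (standardizing region
#' counts with the training-set scaling stored in the model).
#' Classification uses the fixed p >= 0.5 rule, ties classified as positive.
#'
#' @param object a [roi_logit()] fit.
#' @param newdata a `feature_table` or matrix with the selected region
#'   columns.
#' @param type `"response"` (probabilities, default), `"link"` (log-odds) or
#'   `"class"` (0/1 at p >= 0.5).
#' @param covariates covariate rows if `newdata` is a bare matrix.
#' @param ... unused.
#' @return numeric (or integer, for `"class"`) vector, one value per row.
#' @export
predict.roi_logit <- function(object, newdata, type = c("response", "link",
                                                        "class"),
                              covariates = NULL, ...) {
  type <- match.arg(type)
  X <- model_design(object, newdata, covariates)
  eta <- object$intercept + drop(X %*% c(object$coefficients,
                                         object$covariate_coefficients))
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = as.integer(stats::plogis(eta) >= 0.5))
}

#' Probability for a single feature row
#'
#' Convenience scalar form of [predict.roi_logit()]: exact evaluation of
#' p(x) = 1 / (1 + exp(-(b0 + sum(bi xi)))) for one subject.
#'
#' @param model a `roi_logit` fit.
#' @param feature_row named numeric vector or one-row matrix covering every
#'   selected region (and covariates, if the model has them).
#' @return probability in (0, 1).
#' @export
predict_probability <- function(model, feature_row) {
  if (is.null(dim(feature_row))) {
    nm <- names(feature_row)
    if (is.null(nm)) stopf("feature_row must be named")
    feature_row <- matrix(feature_row, nrow = 1, dimnames = list(NULL, nm))
  }
  cn <- names(model$covariate_coefficients)
  cov <- NULL
  if (length(cn)) {
    missing_cov <- setdiff(cn, colnames(feature_row))
    if (length(missing_cov))
      stopf("missing covariate(s): %s", paste(missing_cov, collapse = ", "))
    cov <- feature_row[, cn, drop = FALSE]
  }
  unname(predict(model, feature_row, type = "response", covariates = cov))
}

#' @export
residuals.roi_logit <- function(object, type = c("deviance", "response"),
                                ...) {
  type <- match.arg(type)
  y <- object$labels; mu <- object$fitted
  if (type == "response") return(y - mu)
  d2 <- -2 * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  sign(y - mu) * sqrt(pmax(d2, 0))
}

#' @export
simulate.roi_logit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    as.data.frame(replicate(nsim,
      stats::rbinom(length(object$fitted), 1L, object$fitted)))
  })
}

#' Sweep training:test ratios to check generalizability
#'
#' For each ratio and seed, runs the full training pipeline — stratified
#' split, recursive feature elimination on the training rows, penalized
#' logistic fit, evaluation on the held-out rows — and reports train and
#' test accuracy. Ratios whose mean train-test accuracy gap exceeds
#' `overfit_margin` (percentage points) are flagged as overfitting.
#'
#' @param features a `feature_table`.
#' @param labels optional override of `features$labels`.
#' @param ratios numeric vector of training fractions (>= 2 values).
#' @param seeds integer vector of split seeds (>= 2 values).
#' @param rfe_target features kept by RFE (default: half).
#' @param penalty ridge strength (default `1/n_train`).
#' @param overfit_margin gap in accuracy percentage points (default 25).
#' @return object of class `ratio_sweep`: list with `runs` (one row per
#'   ratio x seed) and `by_ratio` (mean/sd test accuracy, overfit flag).
#' @export
ratio_sweep <- function(features, labels = NULL,
                        ratios = c(0.5, 0.6, 0.7, 0.8, 0.9),
                        seeds = 1:5, rfe_target = NULL, penalty = NULL,
                        overfit_margin = 25) {
  stopifnot(inherits(features, "feature_table"))
  if (is.null(labels)) labels <- features$labels
  if (length(ratios) < 2 || length(seeds) < 2)
    stopf("need at least 2 ratios and 2 seeds")
  runs <- do.call(rbind, lapply(ratios, function(r) {
    do.call(rbind, lapply(seeds, function(s) {
      sp <- stratified_split(labels, r, seed = s)
      tr <- subset_features(features, sp$train_idx)
      te <- subset_features(features, sp$test_idx)
      sel <- rfe_select(tr, labels[sp$train_idx], n_target = rfe_target,
                        penalty = penalty, seed = s)
      fit <- roi_logit(tr, labels[sp$train_idx],
                       selected_regions = sel$selected_region_ids,
                       penalty = penalty, seed = s)
      acc_tr <- mean(predict(fit, tr, type = "class") ==
                       labels[sp$train_idx]) * 100
      acc_te <- mean(predict(fit, te, type = "class") ==
                       labels[sp$test_idx]) * 100
      data.frame(ratio = r, seed = s, n_train = length(sp$train_idx),
                 n_test = length(sp$test_idx), train_accuracy = acc_tr,
                 test_accuracy = acc_te)
    }))
  }))
  by_ratio <- do.call(rbind, lapply(split(runs, runs$ratio), function(d) {
    data.frame(ratio = d$ratio[1],
               mean_test_accuracy = mean(d$test_accuracy),
               sd_test_accuracy = stats::sd(d$test_accuracy),
               mean_gap = mean(d$train_accuracy - d$test_accuracy),
               overfit = mean(d$train_accuracy - d$test_accuracy) >
                 overfit_margin)
  }))
  rownames(by_ratio) <- NULL
  structure(list(runs = runs, by_ratio = by_ratio,
                 overfit_margin = overfit_margin),
            class = "ratio_sweep")
}

#' @export
print.ratio_sweep <- function(x, ...) {
  cat("Training:test ratio sweep\n")
  print(transform(x$by_ratio,
                  mean_test_accuracy = round(mean_test_accuracy, 1),
                  sd_test_accuracy = round(sd_test_accuracy, 1),
                  mean_gap = round(mean_gap, 1)), row.names = FALSE)
  invisible(x)
}

#' Serialize a fitted model to JSON
#' @param model a `roi_logit`.
#' @param path JSON path.
#' @export
write_model <- function(model, path) {
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              covariate_coefficients = as.list(model$covariate_coefficients),
              feature_scaling = list(
                center = as.list(model$feature_scaling$center),
                scale = as.list(model$feature_scaling$scale)),
              selected_region_ids = model$selected_region_ids,
              penalty = model$penalty, method = model$method,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
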