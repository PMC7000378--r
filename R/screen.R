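#' Pearson correlation matrix across regions
#'
#' Pairwise Pearson coefficients over subjects for every pair of region
#' features. Regions with zero variance across subjects are flagged and
#' assigned R = 0 off-diagonal (the coefficient is undefined there); the
#' diagonal is 1.
#'
#' @param features a `feature_table` or a numeric subjects x regions matrix.
#' @return object of class `correlation_matrix`: list with `values`
#'   (regions x regions), `region_ids`, `zero_variance` (ids).
#' @export
pearson_matrix <- function(features) {
  M <- if (inherits(features, "feature_table")) features$counts else
    as.matrix(features)
  if (nrow(M) < 3) stopf("need at least 3 subjects, got %d", nrow(M))
  ids <- if (inherits(features, "feature_table")) features$region_ids else
    (if (is.null(colnames(M))) seq_len(ncol(M)) else colnames(M))
  sds <- apply(M, 2, stats::sd)
  zv <- which(sds == 0)
  R <- suppressWarnings(stats::cor(M))
  R[zv, ] <- 0; R[, zv] <- 0
  diag(R) <- 1
  dimnames(R) <- list(ids, ids)
  structure(list(values = R, region_ids = ids,
                 zero_variance = ids[zv]),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "Correlation matrix: %d regions; max off-diagonal |R| = %.3f; %d zero-variance\n",
    ncol(x$values), if (length(off)) max(abs(off)) else NA_real_,
    length(x$zero_variance)))
  invisible(x)
}

#' @export
plot.correlation_matrix <- function(x, ...) {
  n <- ncol(x$values)
  graphics::image(seq_len(n), seq_len(n), x$values[, n:1], zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "region", ylab = "region", ...)
  invisible(x)
}

#' Flag multicollinear region pairs
#'
#' Returns every unordered off-diagonal pair whose |R| meets the cutoff
#' (inclusive, default 0.9 — the conventional level at which features are
#' removed or combined). An empty result means all features are retained.
#'
#' @param corr a [pearson_matrix()] result.
#' @param cutoff in (0, 1]; compared with `|R| >= cutoff`.
#' @return data.frame with columns `region_a`, `region_b`, `r`, ordered by
#'   decreasing |R|.
#' @export
flag_collinear <- function(corr, cutoff = 0.9) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 1)
    stopf("cutoff must lie in (0, 1], got %s", format(cutoff))
  R <- corr$values
  ut <- which(upper.tri(R) & abs(R) >= cutoff, arr.ind = TRUE)
  out <- data.frame(region_a = corr$region_ids[ut[, 1]],
                    region_b = corr$region_ids[ut[, 2]],
                    r = R[ut])
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Count high-correlation pairs at several levels
#'
#' Number of unordered off-diagonal pairs with R strictly above each level
#' (the convention used for "R > 0.7 / 0.8 / 0.9" pair summaries). Counts
#' are non-increasing across ascending levels. Note the strict inequality
#' here versus the inclusive one in [flag_collinear()].
#'
#' @param corr a [pearson_matrix()] result.
#' @param levels ascending numeric thresholds.
#' @param absolute count `|R|` rather than signed R (default FALSE: signed).
#' @return named integer vector of pair counts.
#' @export
high_correlation_counts <- function(corr, levels = c(0.7, 0.8, 0.9),
                                    absolute = FALSE) {
  stopifnot(inherits(corr, "correlation_matrix"))
  off <- corr$values[upper.tri(corr$values)]
  if (absolute) off <- abs(off)
  stats::setNames(vapply(levels, function(l) sum(off > l), integer(1)),
                  paste0("R>", levels))
}

#' Run the collinearity screen on train, test and combined tables
#'
#' The screen is run three times — training rows, test rows, and all rows
#' combined — and all three reports are returned, so a small sample cannot
#' hide a collinear pair in either portion of the split.
#'
#' @param features a `feature_table`.
#' @param split a [stratified_split()] result.
#' @param cutoff collinearity cutoff, see [flag_collinear()].
#' @return list with elements `train`, `test`, `combined`, each containing
#'   the `correlation_matrix` and its flagged pairs.
#' @export
screen_collinearity <- function(features, split, cutoff = 0.9) {
  pieces <- list(train = subset_features(features, split$train_idx),
                 test = subset_features(features, split$test_idx),
                 combined = features)
  lapply(pieces, function(ft) {
    cm <- pearson_matrix(ft)
    list(correlation = cm, flagged = flag_collinear(cm, cutoff))
  })
}

#' Recursive feature elimination under the ridge-logistic learner
#'
#' Repeatedly fits the penalized logistic learner on the (training-set
#' standardized) features, removes the feature with the smallest absolute
#' standardized coefficient, one per round, until `n_target` remain.
#' Covariates, if supplied, are included in every fit but are exempt from
#' elimination. Must be run on training rows only; passing test rows leaks
#' label information into the selection.
#'
#' @param train_features numeric matrix (training subjects x regions) or a
#'   `feature_table` (its rows are used as-is).
#' @param train_labels binary vector (1 = case).
#' @param n_target number of features to retain, in `[1, ncol]`; default
#'   half the input features.
#' @param covariates optional data.frame / matrix of per-subject covariates.
#' @param penalty ridge strength lambda; default `1/n`.
#' @param seed integer; recorded for provenance (the default learner is
#'   deterministic, so the seed only matters for `method = "sgd"`).
#' @param method `"irls"` (deterministic Newton, default) or `"sgd"`.
#' @return object of class `selection_result`: list with
#'   `selected_region_ids` (ordered as in the input), `elimination_order`
#'   (first-removed first), `n_target`, `seed`.
#' @export
rfe_select <- function(train_features, train_labels, n_target = NULL,
                       covariates = NULL, penalty = NULL, seed = 1L,
                       method = c("irls", "sgd")) {
  method <- match.arg(method)
  if (inherits(train_features, "feature_table")) {
    if (is.null(covariates)) covariates <- train_features$covariates
    train_features <- train_features$counts
  }
  M <- as.matrix(train_features)
  ids <- colnames(M)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(M)))
  p <- ncol(M)
  if (is.null(n_target)) n_target <- max(1L, floor(p / 2))
  if (!is_count(n_target) || n_target < 1 || n_target > p)
    stopf("n_target must be in [1, %d], got %s", p, format(n_target))
  n <- nrow(M)
  if (is.null(penalty)) penalty <- 1 / n
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)

  keep <- seq_len(p)
  elim <- integer(0)
  while (length(keep) > n_target) {
    Mk <- M[, keep, drop = FALSE]
    sc <- feature_scaling(Mk)
    Xf <- apply_scaling(Mk, sc)
    X <- cbind(1, Xf, C)
    fit <- if (method == "sgd")
      ridge_logit_sgd(X, train_labels, penalty, seed = seed)
    else ridge_logit_irls(X, train_labels, penalty)
    imp <- abs(fit$beta[1 + seq_along(keep)])
    drop_i <- which.min(imp)            # ties: first (lowest column index)
    elim <- c(elim, keep[drop_i])
    keep <- keep[-drop_i]
  }
  structure(list(selected_region_ids = ids[keep],
                 elimination_order = ids[elim],
                 n_target = as.integer(n_target),
                 seed = as.integer(seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("RFE selection: %d regions kept (%d eliminated)\n",
              length(x$selected_region_ids), length(x$elimination_order)))
  cat("  kept:", paste(x$selected_region_ids, collapse = " "), "\n")
  invisible(x)
}

#' Serialize a correlation matrix to CSV
#' @param corr a `correlation_matrix`.
#' @param path CSV path.
#' @export
write_correlation <- function(corr, path) {
  utils::write.csv(as.data.frame(corr$values), path, row.names = TRUE)
  invisible(path)
}
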