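#' Count supra-threshold voxels per atlas region
#'
#' For each region id in the atlas, counts the voxels whose t-statistic meets
#' the cutoff. The default comparison is inclusive (`t >= threshold`), the
#' convention used with the package's default cutoff t = 3.17 (one-sided
#' p < 0.001 in the normal limit); only positive-tail activation is counted
#' unless `mode` says otherwise. Background (label 0) voxels are ignored;
#' regions with no supra-threshold voxels report 0, never missing.
#'
#' @param volume a `subject_volume` or bare 3-D numeric array.
#' @param atlas an `atlas_volume` with the same grid dimensions.
#' @param threshold finite t cutoff (default 3.17).
#' @param inclusive compare with `>=` (default) or strict `>`.
#' @param mode `"positive"` (default) counts `t >= threshold`; `"absolute"`
#'   counts `|t| >= threshold`.
#' @return named integer vector, one count per region id.
#' @examples
#' atl <- build_atlas(c(8, 8, 8), 3, seed = 1)
#' tm <- array(0, c(8, 8, 8)); tm[atl$labels == 2][1] <- 5
#' count_significant_voxels(tm, atl)
#' @export
count_significant_voxels <- function(volume, atlas, threshold = 3.17,
                                     inclusive = TRUE,
                                     mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  tmap <- if (inherits(volume, "subject_volume")) volume$tmap else volume
  if (!is.finite(threshold)) stopf("threshold must be finite")
  if (!identical(dim(tmap), dim(atlas$labels)))
    stopf("volume grid %s does not match atlas grid %s",
          paste(dim(tmap), collapse = "x"),
          paste(dim(atlas$labels), collapse = "x"))
  v <- if (mode == "absolute") abs(tmap) else tmap
  hit <- if (inclusive) v >= threshold else v > threshold
  n <- max(atlas$labels)
  lab <- atlas$labels[hit]
  cnt <- tabulate(lab[lab > 0], nbins = n)
  stats::setNames(as.integer(cnt), as.character(seq_len(n)))
}

#' Extract the subjects x regions feature table
#'
#' Applies [count_significant_voxels()] to every subject, producing the
#' feature table fed to screening and the logistic learner: one row per
#' subject in input order, one column per atlas region, plus group labels
#' and covariates. The threshold used is recorded on the table.
#'
#' @param cohort list of `subject_volume`s (a `cohort`).
#' @param atlas the matching `atlas_volume`.
#' @inheritParams count_significant_voxels
#' @return object of class `feature_table`: list with `counts` (integer
#'   matrix, rownames = subject ids, colnames = region ids), `region_ids`,
#'   `labels` (1 = case), `covariates` (data.frame age, sex), `threshold`.
#' @export
extract_features <- function(cohort, atlas, threshold = 3.17,
                             inclusive = TRUE,
                             mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  if (length(cohort) == 0) stopf("cohort is empty")
  dims <- lapply(cohort, function(s) dim(s$tmap))
  bad <- vapply(dims, function(d) !identical(d, dim(atlas$labels)), TRUE)
  if (any(bad))
    stopf("subjects with grids mismatching the atlas: %s",
          paste(vapply(cohort[bad], `[[`, "", "subject_id"), collapse = ", "))
  counts <- t(vapply(cohort, count_significant_voxels,
                     integer(max(atlas$labels)),
                     atlas = atlas, threshold = threshold,
                     inclusive = inclusive, mode = mode))
  rownames(counts) <- vapply(cohort, `[[`, "", "subject_id")
  structure(list(
    counts = counts,
    region_ids = as.integer(colnames(counts)),
    labels = vapply(cohort, `[[`, integer(1), "group"),
    covariates = data.frame(
      age = vapply(cohort, `[[`, numeric(1), "age"),
      sex = vapply(cohort, `[[`, integer(1), "sex")),
    threshold = threshold
  ), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "Feature table: %d subjects x %d regions (t >= %g), %d cases / %d controls\n",
    nrow(x$counts), ncol(x$counts), x$threshold,
    sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

# Row subset of a feature table, preserving class and metadata.
subset_features <- function(ft, idx) {
  structure(list(counts = ft$counts[idx, , drop = FALSE],
                 region_ids = ft$region_ids,
                 labels = ft$labels[idx],
                 covariates = ft$covariates[idx, , drop = FALSE],
                 threshold = ft$threshold),
            class = "feature_table")
}

#' Serialize a feature table to CSV and back
#'
#' Columns: `subject_id`, `group`, `age`, `sex`, then one `region_<id>`
#' column per region. The threshold is kept in a `# threshold:` header line.
#' @param ft a `feature_table`.
#' @param path CSV path.
#' @export
write_features <- function(ft, path) {
  df <- data.frame(subject_id = rownames(ft$counts), group = ft$labels,
                   age = ft$covariates$age, sex = ft$covariates$sex,
                   stringsAsFactors = FALSE)
  cn <- paste0("region_", ft$region_ids)
  df[cn] <- as.data.frame(ft$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# threshold: %.17g", ft$threshold), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  hdr <- readLines(path, n = 1)
  thr <- if (startsWith(hdr, "# threshold:"))
    as.numeric(sub("# threshold:", "", hdr)) else NA_real_
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  rc <- grep("^region_", names(df))
  counts <- as.matrix(df[rc])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$subject_id
  colnames(counts) <- sub("^region_", "", names(df)[rc])
  structure(list(counts = counts,
                 region_ids = as.integer(colnames(counts)),
                 labels = as.integer(df$group),
                 covariates = data.frame(age = df$age, sex = df$sex),
                 threshold = thr),
            class = "feature_table")
}

#' Total supra-threshold voxels per subject across a threshold grid
#'
#' Reproduces the threshold-selection curve: for each cutoff in an ascending
#' grid, the whole-brain count of supra-threshold voxels per subject. Counts
#' are non-increasing in the threshold for every subject.
#'
#' @param cohort list of `subject_volume`s.
#' @param thresholds strictly ascending numeric vector of t cutoffs.
#' @param inclusive inclusive (`>=`, default) or strict comparison.
#' @return object of class `threshold_curve`: list with `thresholds` and
#'   `counts` (subjects x thresholds integer matrix).
#' @export
threshold_curve <- function(cohort, thresholds, inclusive = TRUE) {
  if (length(cohort) == 0) stopf("cohort is empty")
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly ascending")
  counts <- t(vapply(cohort, function(s) {
    vapply(thresholds, function(th) {
      if (inclusive) sum(s$tmap >= th) else sum(s$tmap > th)
    }, numeric(1))
  }, numeric(length(thresholds))))
  if (length(thresholds) == 1L) counts <- matrix(counts, ncol = 1L)
  storage.mode(counts) <- "integer"
  rownames(counts) <- vapply(cohort, `[[`, "", "subject_id")
  colnames(counts) <- as.character(thresholds)
  structure(list(thresholds = thresholds, counts = counts),
            class = "threshold_curve")
}

#' @export
print.threshold_curve <- function(x, ...) {
  cat(sprintf("Threshold curve: %d subjects over t in [%g, %g] (%d points)\n",
              nrow(x$counts), min(x$thresholds), max(x$thresholds),
              length(x$thresholds)))
  invisible(x)
}

#' @export
plot.threshold_curve <- function(x, ...) {
  graphics::matplot(x$thresholds, t(x$counts), type = "l", lty = 1,
                    col = grDevices::grey(0.4, 0.5),
                    xlab = "t threshold",
                    ylab = "supra-threshold voxels per subject", ...)
  invisible(x)
}

#' One-sided upper-tail probability of the t distribution
#'
#' Maps a t cutoff to its one-sided p-value. The degrees of freedom must be
#' given explicitly; `df = Inf` gives the normal limit (t = 3.17 then
#' corresponds to p of about 7.6e-4, i.e. p < 0.001).
#'
#' @param t statistic value(s).
#' @param df degrees of freedom, > 0, or `Inf` for the normal limit.
#' @return upper-tail probability, same length as `t`.
#' @export
t_tail_probability <- function(t, df) {
  if (!is.numeric(df) || length(df) != 1 || is.na(df) || df <= 0)
    stopf("df must be a single positive number (Inf for the normal limit)")
  if (is.infinite(df)) stats::pnorm(t, lower.tail = FALSE)
  else stats::pt(t, df = df, lower.tail = FALSE)
}
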