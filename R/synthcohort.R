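#' Build a synthetic integer-labelled atlas volume
#'
#' Partitions an ellipsoidal foreground mask inside a 3-D grid into
#' `n_regions` contiguous parcels by seeded nearest-centroid assignment:
#' centroids are drawn uniformly from the foreground and every foreground
#' voxel joins its nearest centroid, which inside a convex mask yields
#' connected, roughly convex parcels resembling an anatomical parcellation.
#' Background voxels carry label 0; region ids run contiguously from 1.
#'
#' @param grid_dims integer vector of length 3, the volume dimensions.
#' @param n_regions number of parcels (default 117, the region count of the
#'   anatomical labelling atlas this stands in for).
#' @param seed integer seed; the same seed reproduces the atlas exactly.
#' @param spacing isotropic voxel size in mm for the RAS+ affine (default 2).
#' @return An object of class `atlas_volume`: a list with `labels` (3-D
#'   integer array), `affine` (4x4 voxel-to-world matrix, mm) and `lookup`
#'   (data.frame with `region_id`, `abbreviation`, `name`).
#' @examples
#' atl <- build_atlas(c(16, 16, 16), n_regions = 8, seed = 1)
#' table(atl$labels[atl$labels > 0])
#' @export
build_atlas <- function(grid_dims, n_regions = 117L, seed = 1L, spacing = 2) {
  if (length(grid_dims) != 3 || !all(vapply(grid_dims, is_count, TRUE)) ||
      any(grid_dims < 1))
    stopf("grid_dims must be three positive integers")
  if (!is_count(n_regions) || n_regions < 1)
    stopf("n_regions must be a positive integer")
  grid_dims <- as.integer(grid_dims)
  n_regions <- as.integer(n_regions)

  # Ellipsoidal foreground: semi-axes just inside the grid faces.
  centre <- (grid_dims + 1) / 2
  semi <- pmax(grid_dims / 2 - 1, 0.5)
  idx <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                               y = seq_len(grid_dims[2]),
                               z = seq_len(grid_dims[3])))
  r2 <- ((idx[, 1] - centre[1]) / semi[1])^2 +
        ((idx[, 2] - centre[2]) / semi[2])^2 +
        ((idx[, 3] - centre[3]) / semi[3])^2
  fg <- which(r2 <= 1)
  if (length(fg) < n_regions)
    stopf("grid %s has only %d foreground voxels, fewer than n_regions = %d",
          paste(grid_dims, collapse = "x"), length(fg), n_regions)

  labels <- integer(prod(grid_dims))
  cent <- with_seed(seed, sample(fg, n_regions))
  cx <- idx[cent, , drop = FALSE]
  fx <- idx[fg, , drop = FALSE]
  # Nearest centroid per foreground voxel, chunked to bound memory.
  assign_lab <- integer(length(fg))
  chunk <- 20000L
  for (s in seq(1L, length(fg), by = chunk)) {
    e <- min(s + chunk - 1L, length(fg))
    block <- fx[s:e, , drop = FALSE]
    d2 <- outer(block[, 1], cx[, 1], "-")^2 +
          outer(block[, 2], cx[, 2], "-")^2 +
          outer(block[, 3], cx[, 3], "-")^2
    assign_lab[s:e] <- max.col(-d2, ties.method = "first")
  }
  labels[fg] <- assign_lab
  labels[cent] <- seq_len(n_regions)  # centroid keeps its own id
  labels <- array(labels, dim = grid_dims)

  affine <- diag(c(rep(spacing, 3), 1))
  lookup <- data.frame(
    region_id = seq_len(n_regions),
    abbreviation = sprintf("R%03d", seq_len(n_regions)),
    name = sprintf("Synthetic region %d", seq_len(n_regions)),
    stringsAsFactors = FALSE
  )
  structure(list(labels = labels, affine = affine, lookup = lookup),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  n <- max(x$labels)
  cat(sprintf("Atlas volume: %s grid, %d regions, %d foreground voxels\n",
              paste(dim(x$labels), collapse = "x"), n, sum(x$labels > 0)))
  invisible(x)
}

#' Per-region voxel totals of an atlas
#'
#' @param atlas an `atlas_volume`.
#' @return named integer vector of voxel counts, one entry per region id.
#' @export
atlas_region_sizes <- function(atlas) {
  n <- max(atlas$labels)
  cnt <- tabulate(atlas$labels[atlas$labels > 0], nbins = n)
  names(cnt) <- as.character(seq_len(n))
  cnt
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the generator emulates: 38 cases
#' and 31 controls, 117 atlas regions on a 48^3 grid at 2 mm isotropic
#' spacing (about 440 voxels per parcel, the order of magnitude of real
#' anatomical parcels at this resolution), unit-scale t-value noise smoothed with a Gaussian kernel of
#' sigma 1.27 voxels (6 mm FWHM at 2 mm voxels), a baseline supra-threshold
#' voxel fraction of 0.05 per region at the default cutoff t = 3.17, and a
#' planted case-vs-control shift of +0.15 in five regions spread across the
#' atlas. Age is uniform on 18-70 years (mean 44, sd 15); the probability of
#' male sex is 0.613 for controls and 0.263 for cases, mirroring the cohort
#' demographics the generator stands in for.
#'
#' @param n_cases,n_controls subject counts per group (each >= 2).
#' @param n_regions atlas region count.
#' @param grid_dims 3-D volume dimensions.
#' @param effect_map named numeric vector: region id -> shift in the expected
#'   supra-threshold voxel fraction for cases relative to controls (signed,
#'   dimensionless). `NULL` plants the default +0.15 in five regions; use
#'   `numeric(0)` for a null cohort.
#' @param baseline_activation expected supra-threshold voxel fraction under
#'   no effect, in \[0, 1\].
#' @param noise_sd marginal standard deviation of voxel t-values.
#' @param smoothness Gaussian smoothing sigma in voxels (0 = none).
#' @param threshold the t cutoff at which the fractions are calibrated.
#' @param age_range,male_rate_case,male_rate_control covariate distributions.
#' @param seed integer; fully determines the generated cohort.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 38L, n_controls = 31L, n_regions = 117L,
                         grid_dims = c(48L, 48L, 48L), effect_map = NULL,
                         baseline_activation = 0.05, noise_sd = 1,
                         smoothness = 1.27, threshold = 3.17,
                         age_range = c(18, 70),
                         male_rate_case = 0.263, male_rate_control = 0.613,
                         seed = 1L) {
  if (n_cases < 2 || n_controls < 2)
    stopf("n_cases and n_controls must both be >= 2")
  if (is.null(effect_map)) {
    ids <- unique(pmax(1L, round(seq(0.1, 0.9, length.out = 5) * n_regions)))
    effect_map <- stats::setNames(rep(0.15, length(ids)), ids)
  }
  if (length(effect_map) && is.null(names(effect_map)))
    stopf("effect_map must be named by region id")
  fr <- baseline_activation + c(0, unname(effect_map))
  if (baseline_activation < 0 || baseline_activation > 1 ||
      any(fr < 0 | fr > 1))
    stopf("baseline and effect-adjusted fractions must lie in [0, 1]")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions), grid_dims = as.integer(grid_dims),
    effect_map = effect_map, baseline_activation = baseline_activation,
    noise_sd = noise_sd, smoothness = smoothness, threshold = threshold,
    age_range = age_range, male_rate_case = male_rate_case,
    male_rate_control = male_rate_control, seed = as.integer(seed)
  ), class = "synth_config")
}

# Gaussian kernel FFT and its L2 norm for a (circular) grid, so smoothed
# white noise can be renormalized to exactly unit marginal variance.
smoothing_kernel_fft <- function(grid_dims, sigma) {
  axes <- lapply(grid_dims, function(n) {
    d <- seq_len(n) - 1
    d <- pmin(d, n - d)               # circular distance
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  })
  k3 <- outer(outer(axes[[1]], axes[[2]]), axes[[3]])
  dim(k3) <- grid_dims
  list(fft = stats::fft(k3), l2 = sqrt(sum(k3^2)))
}

# Mean shift giving P(shift + sd*Z >= threshold) = p for Z ~ N(0,1).
# p <= 0 maps to shift 0: a null map is identically zero (plus noise),
# which has zero exceedance whenever threshold > 0.
activation_shift <- function(p, threshold, sd) {
  p <- pmin(p, 1 - 1e-12)
  ifelse(p <= 0, 0, threshold + sd * stats::qnorm(p))
}

#' Generate a synthetic cohort of t-statistic volumes
#'
#' Each subject's map is spatially smoothed Gaussian noise (renormalized so
#' every voxel is marginally N(shift, noise_sd^2)) plus a region-dependent
#' mean shift chosen analytically so that the expected fraction of voxels
#' with t >= `threshold` equals `baseline_activation` everywhere, except in
#' the `effect_map` regions of case subjects where it equals baseline +
#' effect. Covariates and group labels are drawn per `config`; the seed
#' fully determines the output.
#'
#' @param config a [synth_config()].
#' @param atlas an [build_atlas()] result matching `config$grid_dims`.
#' @param day session index recorded on every subject (default 1).
#' @return list of class `cohort`: one `subject_volume` per subject, each a
#'   list with `subject_id`, `group` (1 = case, 0 = control), `tmap`, `age`,
#'   `sex` (1 = male), `day`, `affine`.
#' @examples
#' cfg <- synth_config(n_cases = 3, n_controls = 3, n_regions = 4,
#'                     grid_dims = c(10, 10, 10), effect_map = numeric(0),
#'                     seed = 2)
#' atl <- build_atlas(cfg$grid_dims, cfg$n_regions, seed = 2)
#' coh <- generate_cohort(cfg, atl)
#' length(coh)
#' @export
generate_cohort <- function(config, atlas, day = 1L) {
  stopifnot(inherits(config, "synth_config"), inherits(atlas, "atlas_volume"))
  if (!identical(dim(atlas$labels), config$grid_dims))
    stopf("atlas grid %s does not match config grid_dims %s",
          paste(dim(atlas$labels), collapse = "x"),
          paste(config$grid_dims, collapse = "x"))
  n_reg <- max(atlas$labels)
  eff_ids <- as.integer(names(config$effect_map))
  if (length(eff_ids) && any(eff_ids < 1 | eff_ids > n_reg))
    stopf("effect_map names regions absent from the atlas: %s",
          paste(eff_ids[eff_ids < 1 | eff_ids > n_reg], collapse = ", "))

  b <- config$baseline_activation
  sd <- config$noise_sd
  thr <- config$threshold
  base_shift <- activation_shift(b, thr, sd)
  # Per-voxel shift fields for controls and for cases.
  shift0 <- array(0, dim = config$grid_dims)
  shift0[atlas$labels > 0] <- base_shift
  shift1 <- shift0
  for (i in seq_along(eff_ids)) {
    p1 <- b + unname(config$effect_map[i])
    shift1[atlas$labels == eff_ids[i]] <- activation_shift(p1, thr, sd)
  }

  kern <- if (config$smoothness > 0)
    smoothing_kernel_fft(config$grid_dims, config$smoothness) else NULL
  nvox <- prod(config$grid_dims)
  n <- config$n_cases + config$n_controls
  groups <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))

  with_seed(config$seed, {
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- stats::rbinom(n, 1L,
                         ifelse(groups == 1L, config$male_rate_case,
                                config$male_rate_control))
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      z <- array(stats::rnorm(nvox), dim = config$grid_dims)
      if (!is.null(kern)) {
        z <- Re(stats::fft(stats::fft(z) * kern$fft, inverse = TRUE)) / nvox
        z <- z / kern$l2
      }
      tmap <- (if (groups[i] == 1L) shift1 else shift0) + sd * z
      subjects[[i]] <- structure(list(
        subject_id = sprintf("%s%02d", if (groups[i] == 1L) "case" else "ctrl",
                             i),
        group = groups[i], tmap = tmap, age = age[i], sex = sex[i],
        day = as.integer(day), affine = atlas$affine
      ), class = "subject_volume")
    }
    structure(subjects, class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  g <- vapply(x, `[[`, integer(1), "group")
  cat(sprintf("Synthetic cohort: %d subjects (%d cases, %d controls), grid %s\n",
              length(x), sum(g == 1), sum(g == 0),
              paste(dim(x[[1]]$tmap), collapse = "x")))
  invisible(x)
}

#' Read a generator configuration from JSON or YAML
#'
#' Keys mirror the arguments of [synth_config()]; `effect_map` is given as
#' an object mapping region id to effect (e.g. `{"5": 0.2}`). Unknown keys
#' are rejected; missing keys take the defaults.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a `synth_config`.
#' @export
read_synth_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synth_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  if (!is.null(vals$effect_map))
    vals$effect_map <- unlist(vals$effect_map)
  do.call(synth_config, vals)
}

#' Read and write volumes as NIfTI-1
#'
#' `write_volume()` stores the grid of a `subject_volume` or `atlas_volume`
#' (t-maps as float64, atlas labels as int32) with its affine in the sform;
#' `read_volume()` returns a list with `data` (array) and `affine`, with
#' `kind = "atlas"` when the file holds integer labels. Round-trips preserve
#' grid values, dimensions and affine exactly.
#'
#' @param obj a `subject_volume`, `atlas_volume`, or bare numeric array.
#' @param path file path, conventionally ending in `.nii` or `.nii.gz`.
#' @param affine optional 4x4 affine when `obj` is a bare array.
#' @return `read_volume()`: list with `data`, `affine`, `kind`.
#' @export
write_volume <- function(obj, path, affine = NULL) {
  if (inherits(obj, "atlas_volume")) {
    arr <- obj$labels; affine <- obj$affine; dtype <- "int32"
  } else if (inherits(obj, "subject_volume")) {
    arr <- obj$tmap; affine <- obj$affine; dtype <- "double"
  } else if (is.array(obj)) {
    arr <- obj
    if (is.null(affine)) affine <- diag(4)
    dtype <- if (is.integer(arr)) "int32" else "double"
  } else stopf("cannot write object of class %s as a volume",
               paste(class(obj), collapse = "/"))
  if (any(!is.finite(arr))) stopf("volume contains non-finite values")
  img <- RNifti::asNifti(arr, datatype = dtype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("not a readable NIfTI file (%s): %s",
                                            conditionMessage(e), path))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img))
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  list(data = arr, affine = aff,
       kind = if (is.integer(arr)) "atlas" else "tmap")
}

#' Write / read an atlas region lookup table as TSV
#'
#' Columns `region_id`, `abbreviation`, `name`.
#' @param lookup data.frame as in `atlas_volume$lookup`.
#' @param path TSV path.
#' @export
write_lookup <- function(lookup, path) {
  utils::write.table(lookup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  lk <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "abbreviation", "name")
  if (!all(need %in% names(lk)))
    stopf("lookup TSV must have columns %s", paste(need, collapse = ", "))
  lk
}
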