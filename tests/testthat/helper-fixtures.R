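# Small in-code fixtures shared across tests.

tiny_atlas <- function(dims = c(10, 10, 10), n_regions = 5, seed = 11) {
  build_atlas(dims, n_regions, seed = seed)
}

# A cohort small enough for brute-force oracles.
tiny_cohort <- function(n_cases = 5, n_controls = 5, n_regions = 5,
                        dims = c(10, 10, 10), effect = numeric(0),
                        baseline = 0.1, smoothness = 0, seed = 11) {
  cfg <- synth_config(n_cases = n_cases, n_controls = n_controls,
                      n_regions = n_regions, grid_dims = dims,
                      effect_map = effect, baseline_activation = baseline,
                      smoothness = smoothness, seed = seed)
  list(config = cfg,
       atlas = build_atlas(dims, n_regions, seed = seed),
       cohort = generate_cohort(cfg, build_atlas(dims, n_regions,
                                                 seed = seed)))
}

# Independent triple-loop voxel counter (deliberately naive).
brute_force_counts <- function(tmap, labels, threshold, inclusive = TRUE) {
  n <- max(labels)
  out <- integer(n)
  d <- dim(tmap)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    lab <- labels[i, j, k]
    if (lab > 0) {
      hit <- if (inclusive) tmap[i, j, k] >= threshold
             else tmap[i, j, k] > threshold
      if (hit) out[lab] <- out[lab] + 1L
    }
  }
  out
}

# Feature table built directly from a counts matrix (bypasses volumes).
make_feature_table <- function(counts, labels, age = NULL, sex = NULL,
                               threshold = 3.17) {
  if (is.null(colnames(counts)))
    colnames(counts) <- as.character(seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  storage.mode(counts) <- "integer"
  if (is.null(age)) age <- seq(30, 60, length.out = nrow(counts))
  if (is.null(sex)) sex <- rep_len(c(0L, 1L), nrow(counts))
  structure(list(counts = counts,
                 region_ids = as.integer(colnames(counts)),
                 labels = as.integer(labels),
                 covariates = data.frame(age = age, sex = sex),
                 threshold = threshold),
            class = "feature_table")
}

# Seeded synthetic feature table with a planted logistic signal in
# `signal_cols`; the rest are pure Poisson noise. Covariates are drawn
# independently of the labels so they carry no signal.
planted_feature_table <- function(n = 60, p = 21, signal_cols = 1,
                                  shift = 6, seed = 1) {
  set.seed(seed)
  labels <- rep(c(1L, 0L), length.out = n)
  counts <- matrix(rpois(n * p, 10), n, p)
  for (sc in signal_cols)
    counts[, sc] <- counts[, sc] + labels * shift
  make_feature_table(counts, labels,
                     age = runif(n, 20, 60), sex = rbinom(n, 1L, 0.5))
}

table2_fixture <- function() {
  system.file("extdata", "aal_region_coefficients.tsv",
              package = "roiclassify")
}
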