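test_that("pearson matrix matches the textbook formula computed by loop", {
  set.seed(5)
  M <- matrix(rpois(15, 8), nrow = 5, ncol = 3,
              dimnames = list(NULL, c("1", "2", "3")))
  cm <- pearson_matrix(make_feature_table(M, rep(c(0, 1), length.out = 5)))
  # direct covariance-ratio formula, element by element
  for (a in 1:3) for (b in 1:3) {
    x <- M[, a]; y <- M[, b]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(cm$values[a, b]), r, tolerance = 1e-12)
  }
  expect_true(all(diag(cm$values) == 1))
  expect_equal(cm$values, t(cm$values))
})

test_that("self-correlation, exact negation and zero variance behave", {
  x <- c(3, 7, 1, 9, 5)
  M <- cbind(a = x, b = -x, c = rep(4, 5))
  colnames(M) <- c("1", "2", "3")
  cm <- pearson_matrix(M)
  expect_equal(unname(cm$values["1", "1"]), 1)
  expect_equal(unname(cm$values["1", "2"]), -1)
  # zero-variance region: flagged, off-diagonal 0
  expect_identical(as.character(cm$zero_variance), "3")
  expect_equal(unname(cm$values["1", "3"]), 0)
  expect_error(pearson_matrix(M[1:2, ]), "3 subjects")
})

test_that("collinearity flagging respects the cutoff and nests", {
  set.seed(8)
  base <- rnorm(12)
  M <- cbind(base, base + rnorm(12, sd = 0.1), rnorm(12), base)
  colnames(M) <- as.character(1:4)
  cm <- pearson_matrix(M)
  fl <- flag_collinear(cm, 0.9)
  # duplicated column pair flagged at R = 1
  dup <- fl[fl$region_a == "1" & fl$region_b == "4", ]
  expect_equal(dup$r, 1)
  # monotone in cutoff: pairs at 0.9 are a subset of pairs at 0.7
  fl7 <- flag_collinear(cm, 0.7)
  key <- function(d) paste(d$region_a, d$region_b)
  expect_true(all(key(fl) %in% key(fl7)))
  expect_error(flag_collinear(cm, 0), "cutoff")
  expect_error(flag_collinear(cm, 1.2), "cutoff")
})

test_that("a matrix with max off-diagonal below 0.8 flags nothing at 0.9", {
  set.seed(13)
  M <- matrix(rpois(40 * 10, 20), 40, 10,
              dimnames = list(NULL, as.character(1:10)))
  cm <- pearson_matrix(M)
  expect_lt(max(abs(cm$values[upper.tri(cm$values)])), 0.8)
  expect_identical(nrow(flag_collinear(cm, 0.9)), 0L)
})

test_that("high-correlation pair counts match manual enumeration and nest", {
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.75
  R[1, 3] <- R[3, 1] <- 0.85
  R[2, 3] <- R[3, 2] <- 0.95
  R[1, 4] <- R[4, 1] <- -0.99   # signed counting ignores negatives
  cm <- structure(list(values = R, region_ids = as.character(1:4),
                       zero_variance = character(0)),
                  class = "correlation_matrix")
  cnt <- high_correlation_counts(cm)
  expect_identical(unname(cnt), c(3L, 2L, 1L))
  expect_true(all(diff(cnt) <= 0))
  expect_identical(unname(high_correlation_counts(cm, absolute = TRUE)),
                   c(4L, 3L, 2L))
  # identity matrix: nothing anywhere
  id <- pearson_matrix(matrix(c(1, 2, 3, 3, 1, 2, 2, 3, 1), 3, 3,
                              dimnames = list(NULL, as.character(1:3))))
  expect_true(all(high_correlation_counts(id)[c("R>0.9")] == 0))
})

test_that("the collinearity screen runs on train, test and combined tables", {
  ft <- planted_feature_table(n = 30, p = 6, seed = 3)
  sp <- stratified_split(ft$labels, 0.7, seed = 3)
  scr <- screen_collinearity(ft, sp)
  expect_named(scr, c("train", "test", "combined"))
  for (piece in scr) {
    expect_s3_class(piece$correlation, "correlation_matrix")
    expect_true(is.data.frame(piece$flagged))
  }
  expect_identical(ncol(scr$combined$correlation$values), 6L)
})

test_that("RFE keeps the planted feature and drops constants first", {
  # one informative feature among 20 pure-noise features
  ft <- planted_feature_table(n = 60, p = 21, signal_cols = 1, shift = 6,
                              seed = 17)
  sel <- rfe_select(ft$counts, ft$labels, n_target = 1, seed = 17)
  expect_identical(sel$selected_region_ids, "1")
  expect_identical(length(sel$elimination_order), 20L)

  # constant column is eliminated before informative ones
  M <- ft$counts[, 1:4]
  M[, 4] <- 7L
  colnames(M) <- as.character(1:4)
  sel2 <- rfe_select(M, ft$labels, n_target = 2)
  expect_identical(sel2$elimination_order[1], "4")

  # no-op when n_target equals the feature count
  sel3 <- rfe_select(ft$counts, ft$labels, n_target = 21)
  expect_identical(sel3$selected_region_ids, as.character(1:21))
  expect_identical(sel3$elimination_order, character(0))
  expect_error(rfe_select(ft$counts, ft$labels, n_target = 22), "n_target")
})

test_that("RFE is reproducible and partitions the feature set", {
  ft <- planted_feature_table(n = 40, p = 10, signal_cols = c(2, 5),
                              seed = 23)
  a <- rfe_select(ft, ft$labels, n_target = 4, seed = 9)
  b <- rfe_select(ft, ft$labels, n_target = 4, seed = 9)
  expect_identical(a, b)
  expect_identical(length(a$selected_region_ids), 4L)
  expect_setequal(c(a$selected_region_ids, a$elimination_order),
                  as.character(1:10))
  # default target is half the input features
  d <- rfe_select(ft, ft$labels)
  expect_identical(length(d$selected_region_ids), 5L)
})
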