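test_that("stratified split arithmetic follows round-half-up per class", {
  labs <- rep(c(1, 0), c(10, 10))
  sp <- stratified_split(labs, 0.5, seed = 1)
  expect_identical(sum(labs[sp$train_idx] == 1), 5L)
  expect_identical(sum(labs[sp$train_idx] == 0), 5L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:20)

  # the study's class sizes: 70% of 38 cases and 31 controls -> 27 + 22
  labs2 <- rep(c(1, 0), c(38, 31))
  sp2 <- stratified_split(labs2, 0.7, seed = 2)
  expect_identical(sum(labs2[sp2$train_idx] == 1), 27L)
  expect_identical(sum(labs2[sp2$train_idx] == 0), 22L)
  expect_identical(length(sp2$test_idx), 20L)

  expect_identical(stratified_split(labs2, 0.7, seed = 4),
                   stratified_split(labs2, 0.7, seed = 4))
  expect_false(identical(stratified_split(labs2, 0.7, seed = 4)$train_idx,
                         stratified_split(labs2, 0.7, seed = 5)$train_idx))
  expect_error(stratified_split(labs2, 0.3), "ratio")
  expect_error(stratified_split(c(1, 1, 1, 0), 0.7), "class 0")
})

test_that("null-signal fits shrink to the prevalence", {
  set.seed(2)
  X <- matrix(rpois(200 * 4, 10), 200, 4,
              dimnames = list(NULL, as.character(1:4)))
  y <- rbinom(200, 1, 0.3)               # independent of X
  fit <- roi_logit(X, y)
  expect_true(all(abs(fit$coefficients) < 0.3))
  expect_equal(mean(fit$fitted), mean(y), tolerance = 0.05)
})

test_that("a separable toy problem reaches 100% training accuracy", {
  X <- cbind(c(rep(0, 10), rep(10, 10)), rep(5, 20))
  colnames(X) <- c("1", "2")
  y <- rep(c(0L, 1L), each = 10)
  fit <- roi_logit(X, y, penalty = 1e-4)
  expect_identical(unname(predict(fit, X, type = "class")), y)
  # likelihood ascent: fitted deviance no worse than the null deviance
  expect_lte(fit$deviance, fit$null_deviance)
})

test_that("coefficients match an independent convex-optimizer fit", {
  ft <- planted_feature_table(n = 50, p = 5, signal_cols = 2, shift = 4,
                              seed = 7)
  lam <- 0.5
  fit <- roi_logit(ft$counts, ft$labels, covariates = ft$covariates,
                   penalty = lam)
  # same penalized likelihood handed to a generic quasi-Newton optimizer
  sc <- list(center = fit$feature_scaling$center,
             scale = fit$feature_scaling$scale)
  Xs <- sweep(sweep(ft$counts, 2, sc$center, "-"), 2, sc$scale, "/")
  X <- cbind(1, Xs, as.matrix(ft$covariates))
  y <- ft$labels
  obj <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta))) + lam / 2 * sum(b[-1]^2)
  }
  grad <- function(b) {
    mu <- plogis(drop(X %*% b))
    drop(crossprod(X, mu - y)) + lam * c(0, b[-1])
  }
  ref <- optim(rep(0, ncol(X)), obj, grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))$par
  mine <- c(fit$intercept, unname(fit$coefficients),
            unname(fit$covariate_coefficients))
  expect_lt(max(abs(mine - ref)) / max(abs(ref)), 1e-4)

  # and the unpenalized limit agrees with glm
  fit0 <- roi_logit(ft$counts[, 2, drop = FALSE], y, penalty = 0)
  g <- glm(y ~ scale(ft$counts[, 2]), family = binomial)
  expect_equal(unname(coef(fit0)), unname(coef(g)), tolerance = 1e-5)
})

test_that("zero-penalty separation warns and falls back to a finite fit", {
  X <- matrix(c(rep(0, 6), rep(10, 6)), ncol = 1,
              dimnames = list(NULL, "1"))
  y <- rep(c(0L, 1L), each = 6)
  expect_warning(fit <- roi_logit(X, y, penalty = 0), "separation")
  expect_true(all(is.finite(coef(fit))))
})

test_that("prediction evaluates the logit equation exactly", {
  # hand-built model: beta0 = 1, beta1 = 2, identity scaling
  fit <- structure(list(
    intercept = 1, coefficients = c("1" = 2),
    covariate_coefficients = numeric(0),
    feature_scaling = list(center = c("1" = 0), scale = c("1" = 1)),
    selected_region_ids = "1"), class = "roi_logit")
  expect_equal(predict_probability(fit, c("1" = 1)), 1 / (1 + exp(-3)))
  expect_equal(predict_probability(fit, c("1" = -0.5)), plogis(0))
  expect_equal(predict_probability(fit, c("1" = 1e4)), 1, tolerance = 1e-12)

  fit$intercept <- 0
  expect_equal(predict_probability(fit, c("1" = 0)), 0.5)
  fit$coefficients[] <- 0
  expect_equal(predict_probability(fit, c("1" = 99)), 0.5)

  expect_error(predict_probability(fit, c("2" = 1)), "missing feature")
})

test_that("prediction is monotone in each feature with its coefficient sign", {
  ft <- planted_feature_table(n = 40, p = 3, signal_cols = 1, seed = 4)
  fit <- roi_logit(ft$counts, ft$labels)
  base <- ft$counts[1, ]
  for (j in seq_along(base)) {
    lo <- base; hi <- base
    hi[j] <- hi[j] + 10L
    d <- predict_probability(fit, hi) - predict_probability(fit, lo)
    expect_identical(sign(d), sign(unname(fit$coefficients[j])))
  }
})

test_that("test rows never influence scaling or coefficients", {
  ft <- planted_feature_table(n = 40, p = 4, seed = 10)
  sp <- stratified_split(ft$labels, 0.7, seed = 10)
  fit1 <- roi_logit(ft$counts[sp$train_idx, ], ft$labels[sp$train_idx])
  # corrupt every test row; the fit must be unchanged
  counts2 <- ft$counts
  counts2[sp$test_idx, ] <- counts2[sp$test_idx, ] + 1000L
  fit2 <- roi_logit(counts2[sp$train_idx, ], ft$labels[sp$train_idx])
  expect_identical(fit1$feature_scaling, fit2$feature_scaling)
  expect_identical(coef(fit1), coef(fit2))
})

test_that("residuals, simulate and summary methods are coherent", {
  ft <- planted_feature_table(n = 30, p = 3, seed = 12)
  fit <- roi_logit(ft, ft$labels)
  r <- residuals(fit, type = "response")
  expect_equal(r, fit$labels - fit$fitted)
  expect_equal(sum(residuals(fit)^2), fit$deviance, tolerance = 1e-8)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(30L, 3L))
  expect_true(all(unlist(sims) %in% 0:1))
  s <- summary(fit)
  expect_identical(nrow(s$coefficients), 3L + 2L + 1L)
})

test_that("SGD option approximates the deterministic optimum", {
  ft <- planted_feature_table(n = 60, p = 2, signal_cols = 1, shift = 5,
                              seed = 19)
  det <- roi_logit(ft$counts, ft$labels, penalty = 0.1)
  sgd <- roi_logit(ft$counts, ft$labels, penalty = 0.1, method = "sgd",
                   seed = 3)
  expect_identical(
    sgd, roi_logit(ft$counts, ft$labels, penalty = 0.1, method = "sgd",
                   seed = 3))
  expect_lt(max(abs(coef(det) - coef(sgd))), 0.15)
})

test_that("ratio sweep reports one entry per ratio x seed and calibrates", {
  ft <- planted_feature_table(n = 40, p = 6, signal_cols = integer(0),
                              seed = 31)   # pure noise
  rs <- ratio_sweep(ft, ratios = c(0.5, 0.7), seeds = 1:3, rfe_target = 3)
  expect_identical(nrow(rs$runs), 6L)
  expect_identical(nrow(rs$by_ratio), 2L)
  # null data: test accuracy near prevalence (50%) at every ratio
  expect_true(all(abs(rs$by_ratio$mean_test_accuracy - 50) < 25))

  strong <- planted_feature_table(n = 40, p = 6, signal_cols = 1:2,
                                  shift = 12, seed = 31)
  rs2 <- ratio_sweep(strong, ratios = c(0.5, 0.7), seeds = 1:3,
                     rfe_target = 3)
  expect_true(all(rs2$by_ratio$mean_test_accuracy > 75))
  expect_error(ratio_sweep(ft, ratios = 0.7, seeds = 1:3), "2 ratios")
})

test_that("model JSON serialization is lossless for prediction", {
  ft <- planted_feature_table(n = 30, p = 3, seed = 40)
  fit <- roi_logit(ft$counts, ft$labels)
  f <- tempfile(fileext = ".json")
  write_model(fit, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(js$intercept, fit$intercept)
  expect_equal(unlist(js$coefficients), fit$coefficients)
})
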