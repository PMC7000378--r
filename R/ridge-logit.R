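# Penalized logistic core: Newton/IRLS minimizer of
#   -loglik(beta) + lambda/2 * ||beta[-intercept]||^2
# with the intercept unpenalized. Used by the fitting front-end and by
# recursive feature elimination; deterministic, safe for p > n when
# lambda > 0. A seeded stochastic-gradient option is offered for parity
# with descriptions of SGD-trained logistic models.

logit_loglik <- function(eta, y) -sum(log1p(exp(-(2 * y - 1) * eta)))

penalized_deviance <- function(beta, X, y, lambda) {
  -2 * logit_loglik(drop(X %*% beta), y) + lambda * sum(beta[-1]^2)
}

# X: n x (p+1) design including leading intercept column. Returns beta.
ridge_logit_irls <- function(X, y, lambda, max_iter = 100L, tol = 1e-10) {
  p1 <- ncol(X)
  pen <- c(0, rep(lambda, p1 - 1L))
  beta <- numeric(p1)
  dev <- penalized_deviance(beta, X, y, lambda)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, mu - y)) + pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p1), grad))
    # Backtracking so the penalized deviance never increases.
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      dnew <- penalized_deviance(cand, X, y, lambda)
      if (is.finite(dnew) && dnew <= dev + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { cand <- beta; dnew <- dev; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand; dev <- dnew
    if (moved < tol || sqrt(sum(grad^2)) < 1e-8) {
      return(list(beta = beta, deviance = dev, converged = TRUE,
                  grad_norm = sqrt(sum(grad^2)), iterations = it))
    }
  }
  eta <- drop(X %*% beta)
  g <- drop(crossprod(X, stats::plogis(eta) - y)) + pen * beta
  list(beta = beta, deviance = dev, converged = sqrt(sum(g^2)) < 1e-5,
       grad_norm = sqrt(sum(g^2)), iterations = max_iter)
}

# Seeded mini-batch stochastic gradient descent on the same objective.
ridge_logit_sgd <- function(X, y, lambda, seed = 1L, epochs = 1000L,
                            rate = 0.3, batch = 8L) {
  n <- nrow(X); p1 <- ncol(X)
  pen <- c(0, rep(lambda, p1 - 1L))
  with_seed(seed, {
    beta <- numeric(p1)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      lr <- rate / (1 + 0.01 * ep)
      for (s in seq(1L, n, by = batch)) {
        i <- ord[s:min(s + batch - 1L, n)]
        mu <- stats::plogis(drop(X[i, , drop = FALSE] %*% beta))
        g <- drop(crossprod(X[i, , drop = FALSE], mu - y[i])) * (n / length(i)) +
          pen * beta
        beta <- beta - lr * g / n
      }
    }
    eta <- drop(X %*% beta)
    g <- drop(crossprod(X, stats::plogis(eta) - y)) + pen * beta
    list(beta = beta, deviance = penalized_deviance(beta, X, y, lambda),
         converged = TRUE, grad_norm = sqrt(sum(g^2)), iterations = epochs)
  })
}

# Standardization parameters from training rows; zero-variance columns get
# scale 1 (they standardize to constant 0 and draw a zero coefficient).
feature_scaling <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaling <- function(M, scaling) {
  sweep(sweep(M, 2, scaling$center, "-"), 2, scaling$scale, "/")
}
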