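# Minimal sequential model-based (Bayesian) optimizer used for boosted-tree
# hyperparameter search: Gaussian-process surrogate with a squared-
# exponential kernel on inputs scaled to the unit cube, expected-improvement
# acquisition maximized over a random candidate set. Deliberately small: the
# search spaces here are 4-dimensional with budgets of tens of evaluations.

gp_fit <- function(X, y, lengthscale = 0.4, noise = 1e-6) {
  mu <- mean(y); sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  K <- gp_kernel(X, X, lengthscale) + diag(noise, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, mu = mu, sd = sdv,
       lengthscale = lengthscale)
}

gp_kernel <- function(A, B, lengthscale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * lengthscale^2))
}

gp_predict <- function(fit, Xnew) {
  Ks <- gp_kernel(Xnew, fit$X, fit$lengthscale)
  mean_s <- as.vector(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = fit$mu + fit$sd * mean_s, sd = fit$sd * sqrt(var_s))
}

expected_improvement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * stats::pnorm(z) + sd * stats::dnorm(z)
}

# objective: function(x01) -> scalar to MINIMIZE, x01 in [0,1]^d.
# Returns list(x, value, history). The caller supplies fixed initial points
# (e.g. the engine-default hyperparameters) via init_x01.
bayes_opt <- function(objective, d, budget, seed = 1L,
                      init_x01 = NULL, n_candidates = 500L) {
  stopifnot(budget >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n_init <- min(budget, max(4L, d + 1L))
  X <- init_x01
  if (is.null(X)) X <- matrix(numeric(0), 0, d)
  if (nrow(X) < n_init) {
    extra <- lhs::randomLHS(n_init - nrow(X), d)
    X <- rbind(X, extra)
  }
  X <- X[seq_len(min(nrow(X), budget)), , drop = FALSE]
  y <- apply(X, 1, objective)
  while (length(y) < budget) {
    fit <- gp_fit(X, y)
    cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
    pr <- gp_predict(fit, cand)
    ei <- expected_improvement(pr$mean, pr$sd, min(y))
    xn <- cand[which.max(ei), , drop = FALSE]
    X <- rbind(X, xn)
    y <- c(y, objective(xn[1, ]))
  }
  best <- which.min(y)
  list(x = X[best, ], value = y[best],
       history = data.frame(eval = seq_along(y), value = y))
}
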