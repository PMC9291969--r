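# Shared fixtures, all generated in code under fixed seeds.

# a small simulated trial; calibrate = FALSE keeps it fast (logit(0.25)
# intercept) where the exact prevalence is irrelevant
fixture_trial <- function(n = 400, seed = 42, main_effect = TRUE,
                          hte = FALSE, calibrate = FALSE) {
  sc <- make_scenario(main_effect, hte, dev_n = n, seed = seed,
                      calibrate = calibrate)
  simulate_trial(sc, "development", seed = seed)
}

# a tiny hand-dispatched dataset with both arms and both outcomes
fixture_tiny <- function() {
  set.seed(7)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  a <- rep(c(0L, 1L), length.out = n)
  lp <- -0.5 + 0.8 * X[, 1] - 0.4 * X[, 2] - 0.7 * a
  y <- as.integer(runif(n) < plogis(lp))
  list(X = X, a = a, y = y)
}

# direct Bernoulli log-likelihood, independent of package internals
loglik_oracle <- function(y, p) sum(ifelse(y == 1, log(p), log(1 - p)))

# penalized objective on glmnet's scale: average negative log-likelihood
# plus penalty on coefficients times the population sd of their columns
penalized_objective_oracle <- function(beta0, beta, x, y, lambda, penalty) {
  n <- length(y)
  p_hat <- plogis(beta0 + drop(x %*% beta))
  nll <- -loglik_oracle(y, pmin(pmax(p_hat, 1e-12), 1 - 1e-12)) / n
  sds <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  pen <- if (penalty == "lasso") sum(abs(beta * sds)) else sum((beta * sds)^2) / 2
  nll + lambda * pen
}
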