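# ML and penalized estimation, lambda grids, cross-validation,
# per-arm fits, significance-based selection, risk modeling.

intercept_only_design <- function(n) {
  structure(list(values = matrix(1, n, 1,
                                 dimnames = list(NULL, "(Intercept)")),
                 roles = "intercept", index = NA_integer_, offset = NULL),
            class = "ite_design")
}

test_that("ML fit recovers closed forms and reports a true log-likelihood", {
  y <- rep(c(1, 0, 0, 0), 25)  # mean 0.25
  fit <- fit_ml(intercept_only_design(100), y)
  expect_equal(unname(fit$coefficients), log(1 / 3), tolerance = 1e-8)

  tiny <- fixture_tiny()
  sp <- model_spec("homogeneous", "ml", p = 3)
  fit <- fit_ml(build_design(sp, tiny$X, tiny$a), tiny$y, sp)
  # independent log-likelihood recomputation at the returned coefficients
  d <- build_design(sp, tiny$X, tiny$a)
  p_hat <- plogis(drop(d$values %*% fit$coefficients))
  expect_equal(fit$loglik, loglik_oracle(tiny$y, p_hat), tolerance = 1e-10)
  expect_true(fit$convergence$converged)
})

test_that("penalized fit at lambda = 0 equals maximum likelihood", {
  tiny <- fixture_tiny()
  sp <- model_spec("homogeneous", "ridge", p = 3)
  d <- build_design(sp, tiny$X, tiny$a)
  ml <- fit_ml(d, tiny$y, sp)
  for (pen in c("ridge", "lasso")) {
    pml <- fit_penalized(d, tiny$y, pen, lambda = 0, spec = sp)
    expect_lt(max(abs(pml$coefficients - ml$coefficients)), 1e-4)
  }
})

test_that("a huge lasso penalty gives the null model exactly", {
  tiny <- fixture_tiny()
  sp <- model_spec("homogeneous", "lasso", p = 3)
  d <- build_design(sp, tiny$X, tiny$a)
  fit <- fit_penalized(d, tiny$y, "lasso", lambda = 10, spec = sp)
  cf <- fit$coefficients
  expect_identical(unname(cf[-1]), rep(0, length(cf) - 1))
  expect_equal(unname(cf[1]), qlogis(mean(tiny$y)), tolerance = 1e-6)
})

test_that("penalized solutions beat random coefficient perturbations", {
  set.seed(10)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(0.3 + 0.7 * x[, 1] - 0.5 * x[, 2]))
  d <- structure(list(values = cbind(`(Intercept)` = 1, x1 = x[, 1],
                                     x2 = x[, 2], x3 = x[, 3]),
                      roles = c("intercept", rep("main", 3)),
                      index = c(NA, 1:3), offset = NULL),
                 class = "ite_design")
  for (pen in c("ridge", "lasso")) {
    for (lam in c(0.01, 0.1)) {
      fit <- fit_penalized(d, y, pen, lam)
      b0 <- fit$coefficients[1]
      b <- fit$coefficients[-1]
      obj_fit <- penalized_objective_oracle(b0, b, x, y, lam, pen)
      set.seed(lam * 1000)
      worse <- replicate(2000, {
        eps <- rnorm(4, sd = 0.02)
        penalized_objective_oracle(b0 + eps[1], b + eps[-1], x, y, lam, pen)
      })
      expect_true(all(worse >= obj_fit - 1e-7))
    }
  }
})

test_that("lambda grids start at the null-model gradient bound", {
  set.seed(11)
  n <- 500
  x <- matrix(rnorm(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(-0.5 + x[, 1]))
  d <- structure(list(values = cbind(`(Intercept)` = 1, x),
                      roles = c("intercept", rep("main", 4)),
                      index = c(NA, 1:4), offset = NULL),
                 class = "ite_design")
  # gradient-at-null oracle on standardized columns
  xs <- scale(x, center = TRUE,
              scale = apply(x, 2, function(v) sqrt(mean((v - mean(v))^2))))
  lmax_oracle <- max(abs(crossprod(xs, y - mean(y)))) / n
  g <- make_lambda_grid(d, y, "lasso")
  expect_equal(g[1], lmax_oracle, tolerance = 1e-10)
  expect_true(all(diff(g) < 0))
  expect_equal(length(g), 100L)

  g2 <- make_lambda_grid(d, y, "lasso", n_lambda = 2, ratio = 0.1)
  expect_equal(g2, c(lmax_oracle, 0.1 * lmax_oracle), tolerance = 1e-12)

  # lasso at lambda_max leaves every penalized coefficient at zero
  fit <- fit_penalized(d, y, "lasso", lambda = g[1] * (1 + 1e-10))
  expect_identical(unname(fit$coefficients[-1]), rep(0, 4))

  gr <- make_lambda_grid(d, y, "ridge")
  expect_equal(range(gr), c(1e-4, 1e4), tolerance = 1e-10)
})

test_that("cross-validated deviance matches an explicit per-fold loop", {
  # deviance closed forms
  expect_equal(itepredict:::held_out_deviance(c(1, 0, 1), c(1, 0, 1)), 0)
  n <- 64
  expect_equal(itepredict:::held_out_deviance(rep(c(0, 1), n / 2),
                                              rep(0.5, n)),
               2 * n * log(2))

  set.seed(12)
  nn <- 30
  x <- matrix(rnorm(nn * 2), nn, 2)
  y <- rbinom(nn, 1, plogis(x[, 1]))
  d <- structure(list(values = cbind(`(Intercept)` = 1, a = x[, 1], b = x[, 2]),
                      roles = c("intercept", "main", "main"),
                      index = c(NA, 1:2), offset = NULL),
                 class = "ite_design")
  grid <- make_lambda_grid(d, y, "lasso", n_lambda = 10, ratio = 0.05)
  cv <- cv_select_lambda(d, y, "lasso", K = nn, seed = 99, lambda_grid = grid)

  # hand-rolled leave-out loop using the recorded fold assignment
  folds <- cv$fold_assignments
  dev_oracle <- numeric(length(grid))
  for (k in sort(unique(folds))) {
    tr <- folds != k
    if (all(tr)) next
    f <- glmnet::glmnet(d$values[tr, -1], y[tr], family = "binomial",
                        alpha = 1, lambda = grid, standardize = TRUE,
                        thresh = 1e-10)
    p <- predict(f, newx = d$values[!tr, -1, drop = FALSE], s = grid,
                 type = "response")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    yk <- y[!tr]
    dev_oracle <- dev_oracle +
      colSums(-2 * (yk * log(p) + (1 - yk) * log(1 - p)))
  }
  expect_equal(unname(cv$deviance), unname(dev_oracle), tolerance = 1e-8)
  expect_equal(cv$selected_lambda, grid[which.min(dev_oracle)])
  expect_error(cv_select_lambda(d, y, "lasso", lambda_grid = numeric(0)),
               "empty")
})

test_that("CV selection is invariant to fold relabeling", {
  tiny <- fixture_tiny()
  sp <- model_spec("homogeneous", "ridge", p = 3)
  d <- build_design(sp, tiny$X, tiny$a)
  grid <- exp(seq(log(10), log(0.01), length.out = 20))
  cv <- cv_select_lambda(d, tiny$y, "ridge", K = 5, seed = 3,
                         lambda_grid = grid)
  # relabel folds (k -> K + 1 - k) by rerunning with a permuted-fold oracle
  folds <- cv$fold_assignments
  relab <- max(folds) + 1L - folds
  dev <- numeric(length(grid))
  for (k in sort(unique(relab))) {
    tr <- relab != k
    f <- glmnet::glmnet(d$values[tr, -1], tiny$y[tr], family = "binomial",
                        alpha = 0, lambda = grid, standardize = TRUE,
                        thresh = 1e-10)
    p <- predict(f, newx = d$values[!tr, -1, drop = FALSE], s = grid,
                 type = "response")
    yk <- tiny$y[!tr]
    dev <- dev + colSums(-2 * (yk * log(p) + (1 - yk) * log(1 - p)))
  }
  expect_equal(unname(cv$deviance), unname(dev), tolerance = 1e-8)
})

test_that("per-arm ML equals full-interaction ML; penalization breaks it", {
  tr <- fixture_trial(n = 400, seed = 5)
  sep_ml <- fit_separate_arms(tr$X, tr$a, tr$y, "ml")
  hte_ml <- fit_method("hte_ml", tr)
  p_sep <- predict_risks(sep_ml, tr$X)
  p_hte <- predict_risks(hte_ml, tr$X)
  expect_lt(max(abs(p_sep$p0_hat - p_hte$p0_hat)), 1e-6)
  expect_lt(max(abs(p_sep$p1_hat - p_hte$p1_hat)), 1e-6)
  expect_lt(max(abs(p_sep$delta_hat - p_hte$delta_hat)), 1e-6)

  # same fixed ridge penalty for both routes: no longer equivalent
  sep_r <- fit_separate_arms(tr$X, tr$a, tr$y, "ridge", lambda = 0.05)
  sp <- model_spec("hte_full", "ridge", p = 12)
  hte_r <- fit_penalized(build_design(sp, tr$X, tr$a), tr$y, "ridge",
                         lambda = 0.05, spec = sp)
  expect_gt(max(abs(predict_risks(sep_r, tr$X)$delta_hat -
                    predict_risks(hte_r, tr$X)$delta_hat)), 0)

  # the control-arm model never looks at treated rows
  perm <- seq_along(tr$y)
  treated <- which(tr$a == 1)
  perm[treated] <- rev(treated)
  sep_perm <- fit_separate_arms(tr$X[perm, ], tr$a[perm], tr$y[perm], "ml")
  expect_equal(sep_ml$control$coefficients, sep_perm$control$coefficients,
               tolerance = 1e-10)

  expect_error(fit_separate_arms(tr$X, rep(0L, 400), tr$y, "ml"),
               "non-empty")
})

test_that("significance-based selection applies the two likelihood-ratio tests", {
  # a huge simulated main effect: treatment is always retained
  sc <- make_scenario(TRUE, FALSE, dev_n = 5000, calibrate = FALSE)
  sc$coefficients$beta_t <- -3
  X <- draw_covariates(5000, 0.1, seed = 61)
  a <- assign_treatment(5000, 0.5, seed = 62)
  tr <- true_risks(sc$coefficients, X)
  set.seed(63)
  y <- rbinom(5000, 1, ifelse(a == 1, tr$mu1, tr$mu0))
  fit <- significance_based(X, a, y)
  expect_true(fit$sb$kept_treatment)
  expect_lt(fit$sb$p_treatment, 1e-10)

  # joint test statistic equals -2 * (ll_hom - ll_hte) recomputed from fits
  sp_hom <- model_spec("homogeneous", "ml", p = 12)
  sp_hte <- model_spec("hte_full", "ml", p = 12)
  ll_hom <- fit_ml(build_design(sp_hom, X, a), y, sp_hom)$loglik
  ll_hte <- fit_ml(build_design(sp_hte, X, a), y, sp_hte)$loglik
  expect_equal(fit$sb$lrt_interactions, -2 * (ll_hom - ll_hte),
               tolerance = 1e-8)

  # dropped treatment means identically zero effect predictions
  set.seed(64)
  y0 <- rbinom(400, 1, 0.3)
  X0 <- matrix(rnorm(400 * 12), 400, 12)
  a0 <- rep(c(0L, 1L), 200)
  f0 <- significance_based(X0, a0, y0)
  if (!f0$sb$kept_treatment) {
    expect_identical(max(abs(predict_risks(f0, X0)$delta_hat)), 0)
  }
})

test_that("risk modeling uses the control-arm score as an offset", {
  tr <- fixture_trial(n = 2000, seed = 71)
  fit <- fit_risk_model(tr$X, tr$a, tr$y, "ml")
  expect_equal(length(fit$stage2), 2L)  # treat + treat:eta only

  # control rows: prediction is exactly expit(eta_hat)
  b1 <- fit$stage1
  eta <- drop(b1[1] + tr$X %*% b1[-1])
  pred <- predict_risks(fit, tr$X)
  expect_equal(pred$p0_hat, plogis(eta), tolerance = 1e-12)

  # large-sample homogeneous truth: treatment-by-risk interaction near 0
  big <- fixture_trial(n = 20000, seed = 72, calibrate = TRUE)
  fitb <- fit_risk_model(big$X, big$a, big$y, "ml")
  expect_lt(abs(fitb$stage2[["treat:eta"]]), 0.1)

  expect_error(fit_risk_model(tr$X, rep(1L, 2000), tr$y), "control arm")
})

test_that("overall model needs both arms", {
  expect_error(fit_overall(rep(0L, 10), rbinom(10, 1, 0.5)), "empty arm")
})
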