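# Counterfactual risk prediction and treatment-effect derivation.

test_that("homogeneous log-odds effects translate to the known risk differences", {
  # eta = 0, treatment log-odds -1: 50% -> 27%, an absolute reduction of 23%
  fit <- itepredict:::new_ite_fit(
    model_spec("homogeneous", "ml", p = 2),
    coefficients = c(`(Intercept)` = 0, treat = -1, x1 = 0, x2 = 0),
    roles = c("intercept", "treatment", "main", "main"),
    index = c(NA, NA, 1L, 2L)
  )
  pr <- predict_risks(fit, matrix(0, 3, 2))
  expect_equal(pr$p0_hat, rep(0.5, 3))
  expect_equal(round(pr$p1_hat, 2), rep(0.27, 3))
  expect_equal(round(pr$delta_hat, 2), rep(-0.23, 3))

  # a zero treatment effect gives delta_hat = 0 for every row
  fit0 <- itepredict:::new_ite_fit(
    model_spec("homogeneous", "ml", p = 2),
    coefficients = c(`(Intercept)` = 0.3, treat = 0, x1 = 0.5, x2 = -1),
    roles = c("intercept", "treatment", "main", "main"),
    index = c(NA, NA, 1L, 2L)
  )
  pr0 <- predict_risks(fit0, matrix(rnorm(20), 10, 2))
  expect_identical(pr0$delta_hat, rep(0, 10))
})

test_that("the overall family predicts the marginal arm difference", {
  a <- c(rep(0L, 4), rep(1L, 5))
  y <- c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L)  # 0.25 control, 0.20 treated
  fit <- fit_overall(a, y)
  pr <- predict_risks(fit, matrix(0, 7, 3))
  expect_identical(pr$p0_hat, rep(0.25, 7))
  expect_identical(pr$p1_hat, rep(0.20, 7))
  expect_equal(pr$delta_hat, rep(-0.05, 7))
})

test_that("counterfactual predictions agree with observed-arm fitted values", {
  tiny <- fixture_tiny()
  sp <- model_spec("hte_full", "ml", p = 3)
  d <- build_design(sp, tiny$X, tiny$a)
  fit <- fit_ml(d, tiny$y, sp)
  pr <- predict_risks(fit, tiny$X)
  fitted <- plogis(drop(d$values %*% fit$coefficients))
  observed_arm <- ifelse(tiny$a == 1, pr$p1_hat, pr$p0_hat)
  expect_equal(observed_arm, fitted, tolerance = 1e-10)
})

test_that("delta is invariant to a constant covariate shift fitted with intercept", {
  tiny <- fixture_tiny()
  sp <- model_spec("homogeneous", "ml", p = 3)
  f1 <- fit_ml(build_design(sp, tiny$X, tiny$a), tiny$y, sp)
  Xs <- tiny$X + 5
  f2 <- fit_ml(build_design(sp, Xs, tiny$a), tiny$y, sp)
  expect_equal(predict_risks(f1, tiny$X)$delta_hat,
               predict_risks(f2, Xs)$delta_hat, tolerance = 1e-6)
})

test_that("per-arm predictions come from their own arm models", {
  tr <- fixture_trial(n = 400, seed = 91)
  sep <- fit_separate_arms(tr$X, tr$a, tr$y, "ml")
  # identical per-arm models give delta = 0 everywhere
  sep_same <- sep
  sep_same$treated <- sep$control
  pr <- predict_delta_separate(sep_same, tr$X)
  expect_identical(pr$delta_hat, rep(0, 400))

  # penalized per-arm differs from penalized full-interaction
  sep_r <- fit_separate_arms(tr$X, tr$a, tr$y, "ridge", lambda = 0.02)
  sp <- model_spec("hte_full", "ridge", p = 12)
  hte_r <- fit_penalized(build_design(sp, tr$X, tr$a), tr$y, "ridge",
                         lambda = 0.02, spec = sp)
  expect_gt(max(abs(predict_delta_separate(sep_r, tr$X)$delta_hat -
                    predict_risks(hte_r, tr$X)$delta_hat)), 0)
})

test_that("predictions respect probability bounds and the delta identity", {
  tr <- fixture_trial(n = 300, seed = 92, hte = TRUE)
  for (key in c("hom_ml", "hte_ml", "rm_ml", "sb", "overall")) {
    pr <- predict_risks(fit_method(key, tr), tr$X)
    expect_true(all(pr$p0_hat > 0 & pr$p0_hat < 1))
    expect_true(all(pr$p1_hat > 0 & pr$p1_hat < 1))
    expect_identical(pr$delta_hat, pr$p1_hat - pr$p0_hat)
  }
})
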