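# Data-generating mechanism: coefficients, covariates, calibration,
# true risks, reproducibility.

test_that("scenario coefficients follow the factorial rules", {
  sc <- make_scenario(TRUE, FALSE, dev_n = 400, calibrate = FALSE)
  expect_equal(sc$coefficients$beta_t, log(0.6))
  expect_identical(sc$coefficients$beta_z, rep(0, 12))
  expect_equal(sc$coefficients$beta_m, 2^(-(0:11) / 2))

  sc0 <- make_scenario(FALSE, FALSE, dev_n = 400, calibrate = FALSE)
  expect_identical(sc0$coefficients$beta_t, 0)

  sch <- make_scenario(FALSE, TRUE, dev_n = 400, calibrate = FALSE)
  expect_equal(sch$coefficients$beta_z[10:12], c(-1 / 2, -1 / 4, -1 / 8))
  expect_true(all(abs(sch$coefficients$beta_z[1:9]) <= 0.05))
  # the perturbation is a fixed constant, identical across scenarios
  sch2 <- make_scenario(TRUE, TRUE, dev_n = 1200, calibrate = FALSE)
  expect_identical(sch$coefficients$beta_z[1:9], sch2$coefficients$beta_z[1:9])
})

test_that("scenario validates its configuration", {
  expect_error(make_scenario(TRUE, FALSE, dev_n = 400, rho = 1.2,
                             calibrate = FALSE), "rho")
  expect_error(make_scenario(TRUE, FALSE, dev_n = 400,
                             target_control_prevalence = 1.5,
                             calibrate = FALSE), "probability")
  expect_error(make_scenario(TRUE, TRUE, dev_n = 400,
                             perturbation = rep(0.2, 9),
                             calibrate = FALSE), "0.05")
})

test_that("covariates are compound-symmetric standard normal", {
  x <- draw_covariates(1, 0.1, seed = 1)
  expect_equal(dim(x), c(1L, 12L))

  x <- draw_covariates(2e5, 0, seed = 2)
  cv <- cov(x)
  expect_lt(max(abs(cv - diag(12))), 0.02)

  x <- draw_covariates(2e5, 0.1, seed = 3)
  cv <- cov(x)
  off <- cv[upper.tri(cv)]
  expect_lt(max(abs(off - 0.1)), 0.02)
  expect_lt(max(abs(diag(cv) - 1)), 0.02)

  expect_error(draw_covariates(10, rho = -0.2), "rho")
})

test_that("treatment assignment is Bernoulli with the given probability", {
  expect_identical(assign_treatment(50, 1, seed = 1), rep(1L, 50))
  expect_identical(assign_treatment(50, 0, seed = 1), rep(0L, 50))
  a <- assign_treatment(1e6, 0.5, seed = 4)
  expect_lt(abs(mean(a) - 0.5), 0.002)
})

test_that("intercept calibration matches closed forms and quadrature", {
  expect_equal(calibrate_intercept(rep(0, 12), 0.1, target = 0.25),
               qlogis(0.25))
  expect_equal(calibrate_intercept(rep(0, 12), 0.1, target = 0.5), 0)

  # independent oracle: the linear predictor is N(0, bm' Sigma bm), so the
  # prevalence is a 1-d normal integral solvable by quadrature
  bm <- default_main_effects()
  Sig <- matrix(0.1, 12, 12); diag(Sig) <- 1
  s <- sqrt(drop(t(bm) %*% Sig %*% bm))
  f <- function(b0) {
    integrate(function(z) plogis(b0 + s * z) * dnorm(z), -Inf, Inf)$value - 0.25
  }
  b0_quad <- uniroot(f, c(-5, 0), tol = 1e-10)$root
  expect_equal(b0_quad, -1.634015, tolerance = 1e-5)
  expect_equal(calibrate_intercept(bm, 0.1, target = 0.25), b0_quad,
               tolerance = 1e-3)
})

test_that("true risks reproduce the logistic worked examples", {
  cf <- list(beta0 = 0, beta_t = -1, beta_m = rep(0, 12), beta_z = rep(0, 12))
  tr <- true_risks(cf, matrix(0, 1, 12))
  expect_equal(tr$mu0, 0.5)
  expect_equal(tr$mu1, plogis(-1), tolerance = 1e-12)
  expect_equal(tr$delta_true, plogis(-1) - 0.5)  # approx -0.23

  cf$beta0 <- -1
  tr <- true_risks(cf, matrix(0, 1, 12))
  expect_equal(round(tr$mu0, 2), 0.27)
  expect_equal(round(tr$mu1, 2), 0.12)
  expect_equal(round(tr$delta_true, 2), -0.15)

  expect_error(true_risks(cf, matrix(0, 1, 5)), "dimension")
})

test_that("null scenario has exactly zero treatment effect everywhere", {
  sc <- make_scenario(FALSE, FALSE, dev_n = 400, calibrate = FALSE)
  X <- draw_covariates(5000, 0.1, seed = 11)
  tr <- true_risks(sc$coefficients, X)
  expect_identical(max(abs(tr$delta_true)), 0)
})

test_that("simulated trials are reproducible and correctly sized", {
  sc <- make_scenario(TRUE, FALSE, dev_n = 400, seed = 9, calibrate = FALSE)
  t1 <- simulate_trial(sc, "development")
  t2 <- simulate_trial(sc, "development")
  expect_identical(t1, t2)
  expect_equal(length(t1$y), 400L)
  expect_equal(length(simulate_trial(sc, "validation")$y), 10000L)
  # development and validation draws are different
  expect_false(identical(t1$X[1, ], simulate_trial(sc, "validation")$X[1, ]))
  expect_equal(t1$delta_true, t1$mu1 - t1$mu0)
})

test_that("one calibrated intercept serves all four factorial settings", {
  # control-arm risks depend only on beta0 and beta_m, which are shared
  grid <- expand.grid(me = c(TRUE, FALSE), ht = c(TRUE, FALSE))
  X <- draw_covariates(2000, 0.1, seed = 21)
  mu0s <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- make_scenario(grid$me[i], grid$ht[i], dev_n = 400)
    true_risks(sc$coefficients, X)$mu0
  })
  for (i in 2:4) expect_identical(mu0s[[1]], mu0s[[i]])
  # and the prevalence is near target on a moderate draw
  sc <- make_scenario(TRUE, TRUE, dev_n = 400)
  val <- simulate_trial(sc, "validation", seed = 31, n = 2e5)
  expect_lt(abs(mean(val$mu0) - 0.25), 0.005)
})

test_that("trial CSV round-trips", {
  tr <- fixture_trial(n = 50)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tr, path, truth = TRUE)
  back <- read_trial_csv(path)
  expect_equal(back$X, tr$X, ignore_attr = TRUE)
  expect_identical(back$a, tr$a)
  expect_identical(back$y, tr$y)
  expect_equal(back$delta_true, tr$delta_true)
  unlink(path)
})
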