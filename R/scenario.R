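# Data-generating mechanism for the factorial simulation study.
#
# Outcomes follow a logistic model
#   logit P(Y = 1 | A = a, X = x) = beta0 + beta_t * a + beta_m' x + beta_z' x * a
# with 12 standard-normal covariates under compound-symmetric correlation.

# Fixed perturbation added to the first nine interaction coefficients in
# heterogeneous scenarios.  Drawn once from Uniform(-0.05, 0.05)
# (set.seed(101)) and frozen so that every run of the study uses the same
# small interaction effects.  Override via `make_scenario(perturbation=)`.
HTE_PERTURBATION <- c(
  -0.0127801624, -0.0456175185, 0.0209684018,
  0.0157690397, -0.0250144277, -0.0199945167,
  0.0084866626, -0.0166532857, 0.0122011964
)

#' Main-effect coefficients of the generating model
#'
#' The 12 log-odds slopes are of exponentially decreasing size,
#' \eqn{\beta_{m,j} = 2^{-(j-1)/2}}, so every covariate carries some
#' prognostic signal but later covariates add less and less.
#'
#' @return Numeric vector of length 12.
#' @export
default_main_effects <- function() 2^(-(0:11) / 2)

#' Define a simulation scenario (true coefficients + design constants)
#'
#' Builds the configuration for one cell of the 2x2 factorial design:
#' presence/absence of a main treatment effect (\eqn{\beta_t = \ln 0.6}
#' vs \eqn{\ln 1 = 0}) crossed with presence/absence of heterogeneity of
#' treatment effect (HTE).  In heterogeneous scenarios the interaction
#' coefficients for covariates 10--12 are \eqn{-1/2, -1/4, -1/8} and
#' covariates 1--9 receive a fixed small perturbation (|value| <= 0.05).
#' The intercept is calibrated so that the true control-arm outcome
#' prevalence equals \code{target_control_prevalence}.
#'
#' @param main_effect_present logical; if \code{TRUE}, \eqn{\beta_t = \ln 0.6}.
#' @param hte_present logical; if \code{TRUE}, treatment-covariate
#'   interactions are present as described above.
#' @param dev_n development-set size (the study uses 400, 1200 or 3600).
#' @param seed integer seed stored in the scenario and used by
#'   \code{\link{simulate_trial}}.
#' @param val_n validation-set size (default 10000).
#' @param rho common pairwise covariate correlation, in [0, 1).
#' @param target_control_prevalence true control-arm event prevalence the
#'   intercept is calibrated to (default 0.25).
#' @param treatment_prob randomization probability (default 0.5).
#' @param perturbation length-9 replacement for the frozen interaction
#'   perturbation (heterogeneous scenarios only).
#' @param calibrate if \code{FALSE}, skip intercept calibration and set
#'   \eqn{\beta_0 = \mathrm{logit}} of the target prevalence (useful for
#'   quick tests that do not depend on the exact prevalence).
#'
#' @return An object of class \code{ite_scenario}: a list with elements
#'   \code{coefficients} (list \code{beta0}, \code{beta_t}, \code{beta_m},
#'   \code{beta_z}), the design constants above, and the factorial flags.
#' @export
#' @examples
#' sc <- make_scenario(TRUE, FALSE, dev_n = 400, seed = 1, calibrate = FALSE)
#' sc$coefficients$beta_t  # log(0.6)
make_scenario <- function(main_effect_present, hte_present, dev_n,
                          seed = 1L, val_n = 10000L, rho = 0.1,
                          target_control_prevalence = 0.25,
                          treatment_prob = 0.5,
                          perturbation = HTE_PERTURBATION,
                          calibrate = TRUE) {
  stopifnot(is.logical(main_effect_present), is.logical(hte_present),
            dev_n >= 2, val_n >= 2, length(perturbation) == 9)
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  check_probability(target_control_prevalence)
  check_probability(treatment_prob)
  if (any(abs(perturbation) > 0.05)) {
    stop("interaction perturbation entries must have |value| <= 0.05",
         call. = FALSE)
  }

  beta_m <- default_main_effects()
  beta_t <- if (main_effect_present) log(0.6) else 0
  beta_z <- if (hte_present) {
    c(perturbation, -1 / 2, -1 / 4, -1 / 8)
  } else {
    rep(0, 12)
  }
  beta0 <- if (calibrate) {
    calibrate_intercept(beta_m, rho, target = target_control_prevalence)
  } else {
    stats::qlogis(target_control_prevalence)
  }

  structure(
    list(
      coefficients = list(beta0 = beta0, beta_t = beta_t,
                          beta_m = beta_m, beta_z = beta_z),
      main_effect_present = main_effect_present,
      hte_present = hte_present,
      dev_n = as.integer(dev_n),
      val_n = as.integer(val_n),
      rho = rho,
      target_control_prevalence = target_control_prevalence,
      treatment_prob = treatment_prob,
      seed = as.integer(seed)
    ),
    class = "ite_scenario"
  )
}

#' @export
print.ite_scenario <- function(x, ...) {
  cat("Simulation scenario (12 covariates, rho =", x$rho, ")\n")
  cat("  main treatment effect:", if (x$main_effect_present) "ln(0.6)" else "0",
      " | HTE:", if (x$hte_present) "present" else "absent", "\n")
  cat("  dev n:", x$dev_n, "| val n:", x$val_n,
      "| control prevalence:", x$target_control_prevalence, "\n")
  cat("  beta0 =", format(x$coefficients$beta0, digits = 5), "\n")
  invisible(x)
}

#' Draw compound-symmetric standard-normal covariates
#'
#' Each row is a draw from a 12-dimensional (or \code{p}-dimensional)
#' multivariate normal with zero means, unit variances and all pairwise
#' correlations equal to \code{rho}.  The draw uses the one-factor
#' representation \eqn{x_j = \sqrt{\rho}\, g + \sqrt{1-\rho}\, e_j} with a
#' shared factor \eqn{g} per row, which is exact for \eqn{\rho \ge 0}.
#'
#' @param n number of rows.
#' @param rho common correlation, in [0, 1).
#' @param seed optional integer seed.
#' @param p number of covariates (default 12).
#' @return An \code{n x p} numeric matrix with columns \code{x1..xp}.
#' @export
draw_covariates <- function(n, rho = 0.1, seed = NULL, p = 12L) {
  stopifnot(n >= 1)
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * p), nrow = n, ncol = p, byrow = TRUE)
  x <- sqrt(rho) * g + sqrt(1 - rho) * e
  colnames(x) <- paste0("x", seq_len(p))
  x
}

#' Randomize treatment assignment
#'
#' @param n number of subjects.
#' @param treatment_prob assignment probability (default 0.5).
#' @param seed optional integer seed.
#' @return Integer vector of 0/1 assignments.
#' @export
assign_treatment <- function(n, treatment_prob = 0.5, seed = NULL) {
  stopifnot(n >= 1, treatment_prob >= 0, treatment_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 1L, treatment_prob)
}

# session cache: calibrated intercepts are expensive (2e6-row draw)
.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate the generating intercept to a target control-arm prevalence
#'
#' Finds \eqn{\beta_0} such that the population control-arm event rate
#' \eqn{E_x[\mathrm{expit}(\beta_0 + \beta_m^\top x)]} equals
#' \code{target}.  The expectation is approximated with a fixed
#' Monte-Carlo draw of 2e6 covariate rows (internal seed, so the result
#' is deterministic) and the root is found by \code{uniroot}.  Because
#' the control arm involves only \eqn{\beta_0} and \eqn{\beta_m}, one
#' calibrated value serves every cell of the factorial design.
#'
#' @param beta_m main-effect coefficient vector.
#' @param rho covariate correlation.
#' @param target target control-arm prevalence, in (0, 1).
#' @param tol tolerance on the achieved prevalence (default 5e-4).
#' @param mc_n Monte-Carlo sample size for the expectation (default 2e6).
#' @return The calibrated intercept (log-odds scalar).
#' @export
#' @examples
#' calibrate_intercept(rep(0, 12), rho = 0, target = 0.25)  # logit(0.25)
calibrate_intercept <- function(beta_m, rho, target = 0.25, tol = 5e-4,
                                mc_n = 2e6) {
  check_probability(target)
  key <- paste(format(c(beta_m, rho, target, tol, mc_n), digits = 15),
               collapse = "|")
  hit <- get0(key, envir = .calibration_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  if (all(beta_m == 0)) {
    # degenerate linear predictor: closed form
    b0 <- stats::qlogis(target)
  } else {
    # fixed internal draw keeps the routine deterministic; only the
    # distribution of the linear predictor matters, so store it once
    x <- draw_covariates(mc_n, rho, seed = 761077L, p = length(beta_m))
    lp <- drop(x %*% beta_m)
    # antithetic pairing (x and -x are equally likely) halves the error
    f <- function(b0) {
      mean(stats::plogis(b0 + lp) + stats::plogis(b0 - lp)) / 2 - target
    }
    sol <- tryCatch(
      stats::uniroot(f, interval = c(-20, 20), tol = 1e-8),
      error = function(e) stop("intercept calibration failed to converge: ",
                               conditionMessage(e), call. = FALSE)
    )
    b0 <- sol$root
    if (abs(f(b0)) > tol) {
      stop("intercept calibration did not reach the requested tolerance",
           call. = FALSE)
    }
  }
  assign(key, b0, envir = .calibration_cache)
  b0
}

#' True potential-outcome risks and individualized treatment effect
#'
#' Evaluates the generating model at each covariate row:
#' \eqn{\mu_0(x) = \mathrm{expit}(\beta_0 + \beta_m^\top x)},
#' \eqn{\mu_1(x) = \mathrm{expit}(\beta_0 + \beta_t + (\beta_m+\beta_z)^\top x)}
#' and \eqn{\delta(x) = \mu_1(x) - \mu_0(x)}.
#'
#' @param coefficients list with \code{beta0}, \code{beta_t}, \code{beta_m},
#'   \code{beta_z} (as in \code{make_scenario()$coefficients}).
#' @param X covariate matrix with \code{length(beta_m)} columns.
#' @return List with vectors \code{mu0}, \code{mu1}, \code{delta_true}.
#' @export
true_risks <- function(coefficients, X) {
  X <- as.matrix(X)
  cf <- coefficients
  if (ncol(X) != length(cf$beta_m) || length(cf$beta_z) != length(cf$beta_m)) {
    stop("covariate matrix does not match the coefficient dimensions",
         call. = FALSE)
  }
  lp0 <- cf$beta0 + drop(X %*% cf$beta_m)
  lp1 <- cf$beta0 + cf$beta_t + drop(X %*% (cf$beta_m + cf$beta_z))
  mu0 <- stats::plogis(lp0)
  mu1 <- stats::plogis(lp1)
  list(mu0 = mu0, mu1 = mu1, delta_true = mu1 - mu0)
}

#' Simulate one randomized trial from a scenario
#'
#' Draws covariates, randomizes treatment, and samples the binary
#' outcome from the true assigned-arm risk
#' \eqn{y_i \sim \mathrm{Bernoulli}(\mu_{a_i}(x_i))}.  Covariates,
#' treatment and outcomes use independent sub-streams derived from the
#' seed, so the same seed always reproduces the same dataset.
#'
#' @param scenario an \code{ite_scenario}.
#' @param role \code{"development"} (size \code{dev_n}) or
#'   \code{"validation"} (size \code{val_n}).
#' @param seed integer seed; defaults to the scenario seed (+1 for the
#'   validation role so the two sets are independent).
#' @param n optional explicit size overriding the role-based size.
#' @return An object of class \code{ite_trial}: list with \code{X},
#'   \code{a}, \code{y} and the true \code{mu0}, \code{mu1},
#'   \code{delta_true}.
#' @export
simulate_trial <- function(scenario, role = c("development", "validation"),
                           seed = NULL, n = NULL) {
  stopifnot(inherits(scenario, "ite_scenario"))
  role <- match.arg(role)
  if (is.null(n)) {
    n <- if (role == "development") scenario$dev_n else scenario$val_n
  }
  if (is.null(seed)) {
    seed <- scenario$seed + if (role == "validation") 1L else 0L
  }
  X <- draw_covariates(n, scenario$rho, seed = derive_seed(seed, 1L),
                       p = length(scenario$coefficients$beta_m))
  a <- assign_treatment(n, scenario$treatment_prob,
                        seed = derive_seed(seed, 2L))
  tr <- true_risks(scenario$coefficients, X)
  set.seed(derive_seed(seed, 3L))
  mu_assigned <- ifelse(a == 1L, tr$mu1, tr$mu0)
  y <- as.integer(stats::runif(n) < mu_assigned)
  new_ite_trial(X, a, y, mu0 = tr$mu0, mu1 = tr$mu1,
                delta_true = tr$delta_true)
}

#' Construct a trial-data object
#'
#' Container for (simulated or user-supplied) randomized-trial data with
#' a binary outcome.  True potential-outcome risks are optional and only
#' available for simulated data.
#'
#' @param X numeric covariate matrix.
#' @param a 0/1 treatment indicator vector.
#' @param y 0/1 outcome vector.
#' @param mu0,mu1 optional true risks under control / treatment.
#' @param delta_true optional true risk difference \code{mu1 - mu0}.
#' @return An object of class \code{ite_trial}.
#' @export
new_ite_trial <- function(X, a, y, mu0 = NULL, mu1 = NULL,
                          delta_true = NULL) {
  X <- as.matrix(X)
  a <- as.integer(a)
  y <- as.integer(y)
  check_binary(a, "a")
  check_binary(y, "y")
  stopifnot(nrow(X) == length(a), length(a) == length(y))
  if (!is.null(mu0) && !is.null(mu1)) {
    stopifnot(all(mu0 > 0 & mu0 < 1), all(mu1 > 0 & mu1 < 1))
    if (is.null(delta_true)) delta_true <- mu1 - mu0
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, a = a, y = y, mu0 = mu0, mu1 = mu1,
                 delta_true = delta_true),
            class = "ite_trial")
}

#' @export
print.ite_trial <- function(x, ...) {
  cat("Randomized trial data: n =", length(x$y), ", p =", ncol(x$X), "\n")
  cat("  treated:", sum(x$a), "| events:", sum(x$y),
      if (!is.null(x$delta_true)) "| true risks attached" else "", "\n")
  invisible(x)
}

#' Write / read trial data as CSV
#'
#' Column layout: \code{y,treat,x1..xp} with optional
#' \code{mu0,mu1,delta_true} truth columns.
#'
#' @param trial an \code{ite_trial}.
#' @param path file path.
#' @param truth include the true-risk columns when available?
#' @return \code{write_trial_csv} returns \code{path} invisibly;
#'   \code{read_trial_csv} returns an \code{ite_trial}.
#' @export
write_trial_csv <- function(trial, path, truth = FALSE) {
  df <- data.frame(y = trial$y, treat = trial$a)
  df <- cbind(df, as.data.frame(trial$X))
  if (truth && !is.null(trial$mu0)) {
    df$mu0 <- trial$mu0
    df$mu1 <- trial$mu1
    df$delta_true <- trial$delta_true
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("y", "treat") %in% names(df)))
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  new_ite_trial(
    X = as.matrix(df[xcols]),
    a = df$treat, y = df$y,
    mu0 = df[["mu0"]], mu1 = df[["mu1"]],
    delta_true = df[["delta_true"]]
  )
}
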