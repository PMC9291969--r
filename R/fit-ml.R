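# Maximum-likelihood fitting of the logistic model families.

new_ite_fit <- function(spec, coefficients, roles, index,
                        loglik = NA_real_, convergence = list(),
                        selected_lambda = NULL, cv = NULL, extra = list()) {
  structure(
    c(list(spec = spec,
           coefficients = coefficients,
           roles = roles,
           index = index,
           loglik = loglik,
           convergence = convergence,
           selected_lambda = selected_lambda,
           cv = cv),
      extra),
    class = "ite_fit"
  )
}

#' @export
print.ite_fit <- function(x, ...) {
  cat("Fitted ITE model:", x$spec$family, "/", x$spec$estimator, "\n")
  cat("  coefficients:", length(x$coefficients),
      if (!is.null(x$selected_lambda))
        paste("| lambda =", format(x$selected_lambda, digits = 4)) else "",
      "\n")
  if (isTRUE(x$convergence$separation)) {
    cat("  WARNING: quasi-separation detected\n")
  }
  invisible(x)
}

#' Fit a logistic model by maximum likelihood
#'
#' Thin wrapper around iteratively reweighted least squares
#' (\code{stats::glm.fit}) with a tight convergence tolerance.
#' Quasi-separation (fitted probabilities numerically 0 or 1) and
#' non-convergence are flagged in the returned object rather than
#' silently ignored.
#'
#' @param design an \code{ite_design} from \code{\link{build_design}} or
#'   \code{\link{build_risk_model_stage2}}.
#' @param y 0/1 outcome vector.
#' @param spec optional \code{ite_spec} stored with the fit.
#' @return An object of class \code{ite_fit} with the coefficient vector
#'   (one entry per design column), the maximized log-likelihood, and a
#'   \code{convergence} list (\code{converged}, \code{iterations},
#'   \code{separation}).
#' @export
fit_ml <- function(design, y, spec = NULL) {
  stopifnot(inherits(design, "ite_design"))
  y <- as.numeric(y)
  check_binary(y, "y")
  stopifnot(nrow(design$values) == length(y))
  if (is.null(spec)) spec <- model_spec("homogeneous", "ml",
                                        p = max(1L, sum(design$roles == "main")))

  fit <- suppressWarnings(stats::glm.fit(
    x = design$values, y = y,
    family = stats::binomial(),
    offset = design$offset,
    control = list(epsilon = 1e-10, maxit = 100)
  ))
  mu <- fit$fitted.values
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10)
  ll <- bernoulli_loglik(y, mu)
  cf <- fit$coefficients
  names(cf) <- colnames(design$values)
  if (anyNA(cf)) {
    stop("maximum-likelihood fit produced undefined coefficients ",
         "(rank-deficient design)", call. = FALSE)
  }
  new_ite_fit(spec, cf, design$roles, design$index,
              loglik = ll,
              convergence = list(converged = fit$converged,
                                 iterations = fit$iter,
                                 separation = separation),
              extra = list(offset_design = !is.null(design$offset)))
}

#' Marginal (overall) treatment-effect model
#'
#' Estimates the two arm-level event rates; every subject receives the
#' same predicted risks and the same treatment-effect prediction
#' \eqn{\hat\delta = \bar y_1 - \bar y_0}.
#'
#' @param a 0/1 treatment vector.
#' @param y 0/1 outcome vector.
#' @return An \code{ite_fit} with family \code{"overall"}.
#' @export
fit_overall <- function(a, y) {
  check_binary(a, "a"); check_binary(y, "y")
  if (sum(a == 0) == 0 || sum(a == 1) == 0) {
    stop("the marginal treatment effect is undefined with an empty arm",
         call. = FALSE)
  }
  p0 <- mean(y[a == 0])
  p1 <- mean(y[a == 1])
  spec <- model_spec("overall", "ml", p = 1L)
  new_ite_fit(spec, c(p0 = p0, p1 = p1),
              roles = c("arm_mean", "arm_mean"),
              index = c(NA_integer_, NA_integer_),
              loglik = bernoulli_loglik(y, ifelse(a == 1, p1, p0)),
              convergence = list(converged = TRUE, iterations = 0L,
                                 separation = FALSE),
              extra = list(arm_means = c(control = p0, treated = p1)))
}

#' Significance-based model selection
#'
#' Starting from the homogeneous treatment-effect model with all
#' covariates, a df-1 likelihood-ratio test (LRT) is applied to the
#' treatment coefficient.  If non-significant, treatment is dropped
#' (main-effects-only model, \eqn{\hat\delta \equiv 0}).  If
#' significant, all treatment-covariate interactions are added and their
#' joint df-\eqn{p} LRT decides whether they stay.
#'
#' @param X covariate matrix.
#' @param a 0/1 treatment vector.
#' @param y 0/1 outcome vector.
#' @param alpha test level (default 0.05).
#' @return The selected \code{ite_fit}; component \code{sb} records both
#'   test statistics and decisions.
#' @export
significance_based <- function(X, a, y, alpha = 0.05) {
  check_probability(alpha)
  X <- as.matrix(X)
  p <- ncol(X)
  spec_hom <- model_spec("homogeneous", "ml", p = p)

  fit_hom <- fit_ml(build_design(spec_hom, X, a), y, spec_hom)
  # null model: main effects only, no treatment column
  d0 <- build_design(spec_hom, X, a)
  keep <- d0$roles != "treatment"
  d_null <- structure(list(values = d0$values[, keep, drop = FALSE],
                           roles = d0$roles[keep], index = d0$index[keep],
                           offset = NULL), class = "ite_design")
  fit_null <- fit_ml(d_null, y, spec_hom)

  lrt1 <- 2 * (fit_hom$loglik - fit_null$loglik)
  p1 <- stats::pchisq(lrt1, df = 1, lower.tail = FALSE)

  sb <- list(lrt_treatment = lrt1, p_treatment = p1,
             kept_treatment = p1 < alpha,
             lrt_interactions = NA_real_, p_interactions = NA_real_,
             kept_interactions = FALSE, alpha = alpha)

  if (p1 >= alpha) {
    final <- fit_null
  } else {
    spec_hte <- model_spec("hte_full", "ml", p = p)
    fit_hte <- fit_ml(build_design(spec_hte, X, a), y, spec_hte)
    lrt2 <- 2 * (fit_hte$loglik - fit_hom$loglik)
    p2 <- stats::pchisq(lrt2, df = p, lower.tail = FALSE)
    sb$lrt_interactions <- lrt2
    sb$p_interactions <- p2
    sb$kept_interactions <- p2 < alpha
    final <- if (p2 < alpha) fit_hte else fit_hom
  }
  final$spec <- model_spec(
    "significance_based", "ml", p = p,
    interaction_indices = if (sb$kept_interactions) seq_len(p) else integer(0)
  )
  final$sb <- sb
  final
}
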