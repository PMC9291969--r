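# Comparator model families: per-arm models, risk modeling, and the
# Table-1 method registry used by the study runner.

#' Fit separate outcome models per treatment arm
#'
#' One intercept + main-effects logistic model per arm.  Under maximum
#' likelihood this is an exact reparameterization of the
#' full-interaction model (identical predictions); under penalization
#' the equivalence breaks because each arm is standardized and penalized
#' on its own.
#'
#' @param X covariate matrix.
#' @param a 0/1 treatment vector (both arms must be non-empty).
#' @param y 0/1 outcome vector.
#' @param method \code{"ml"}, \code{"ridge"} or \code{"lasso"}.
#' @param lambda optional fixed penalty (single value applied to both
#'   arms); if \code{NULL} and the method is penalized, each arm runs
#'   its own cross-validated selection.
#' @param K folds for per-arm CV (default 10).
#' @param seed seed for the fold assignments.
#' @return An object of class \code{ite_fit_pair}: list with
#'   \code{control} and \code{treated} \code{ite_fit}s.
#' @export
fit_separate_arms <- function(X, a, y, method = c("ml", "ridge", "lasso"),
                              lambda = NULL, K = 10L, seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  a <- as.integer(a)
  if (sum(a == 0) == 0 || sum(a == 1) == 0) {
    stop("both treatment arms must be non-empty", call. = FALSE)
  }
  p <- ncol(X)
  spec <- model_spec("separate_arms", method, p = p)

  fit_arm <- function(arm) {
    idx <- a == arm
    Xa <- X[idx, , drop = FALSE]
    ya <- y[idx]
    # arm-specific model: intercept + main effects (treatment constant)
    d_full <- build_design(model_spec("homogeneous", method, p = p),
                           Xa, rep(0, sum(idx)))
    keep <- d_full$roles != "treatment"
    d <- structure(list(values = d_full$values[, keep, drop = FALSE],
                        roles = d_full$roles[keep],
                        index = d_full$index[keep], offset = NULL),
                   class = "ite_design")
    if (method == "ml") {
      fit_ml(d, ya, spec)
    } else if (!is.null(lambda)) {
      fit_penalized(d, ya, method, lambda, spec = spec)
    } else {
      fit_penalized_cv(d, ya, method, K = K,
                       seed = if (is.null(seed)) NULL else seed + arm,
                       spec = spec)
    }
  }

  structure(list(control = fit_arm(0L), treated = fit_arm(1L),
                 spec = spec, method = method),
            class = "ite_fit_pair")
}

#' @export
print.ite_fit_pair <- function(x, ...) {
  cat("Per-arm ITE models (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Two-stage risk-modeling fit
#'
#' Stage 1 fits a main-effects risk model in the control arm only (by
#' ML or ridge with cross-validated penalty) and evaluates its linear
#' predictor \eqn{\hat\eta} for every subject.  Stage 2 fits, by ML,
#' \deqn{\mathrm{logit}\,P(Y=1) = \hat\eta + \beta_t a + \gamma a \hat\eta}
#' with \eqn{\hat\eta} as an offset and no free intercept, so treatment
#' effect modification is restricted to a linear function of baseline
#' risk.
#'
#' @param X covariate matrix.
#' @param a 0/1 treatment vector (control arm must be non-empty).
#' @param y 0/1 outcome vector.
#' @param method stage-1 estimator, \code{"ml"} or \code{"ridge"}.
#' @param K folds for stage-1 ridge CV.
#' @param seed seed for the fold assignment.
#' @return An \code{ite_fit} (family \code{"risk_model"}); components
#'   \code{stage1} (control-arm coefficients) and \code{stage2}
#'   (\code{treat}, \code{treat:eta}).
#' @export
fit_risk_model <- function(X, a, y, method = c("ml", "ridge"),
                           K = 10L, seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  a <- as.integer(a)
  if (sum(a == 0) == 0) stop("empty control arm", call. = FALSE)
  p <- ncol(X)
  spec <- model_spec("risk_model", method, p = p)

  ctrl <- a == 0
  d_full <- build_design(model_spec("homogeneous", method, p = p),
                         X[ctrl, , drop = FALSE], rep(0, sum(ctrl)))
  keep <- d_full$roles != "treatment"
  d1 <- structure(list(values = d_full$values[, keep, drop = FALSE],
                       roles = d_full$roles[keep],
                       index = d_full$index[keep], offset = NULL),
                  class = "ite_design")
  stage1 <- if (method == "ml") {
    fit_ml(d1, y[ctrl], spec)
  } else {
    fit_penalized_cv(d1, y[ctrl], "ridge", K = K, seed = seed, spec = spec)
  }

  b <- stage1$coefficients
  eta <- drop(b[1] + X %*% b[-1])
  d2 <- build_risk_model_stage2(eta, a)
  stage2 <- fit_ml(d2, y, spec)

  new_ite_fit(spec,
              coefficients = stage2$coefficients,
              roles = d2$roles, index = d2$index,
              loglik = stage2$loglik,
              convergence = stage2$convergence,
              selected_lambda = stage1$selected_lambda,
              cv = stage1$cv,
              extra = list(stage1 = stage1$coefficients,
                           stage2 = stage2$coefficients))
}

#' Table of study method keys
#'
#' The method grid of the simulation study: marginal arm difference
#' (\code{overall}), homogeneous models (\code{hom_ml},
#' \code{hom_ridge}), full-interaction HTE models (\code{hte_ml},
#' \code{hte_ridge}, \code{hte_lasso}, \code{hte_hgl}), the
#' content-knowledge ridge HTE model (\code{hte_ck_ridge}), risk
#' modeling (\code{rm_ml}, \code{rm_ridge}), the significance-based
#' procedure (\code{sb}), and per-arm models (\code{sep_ml},
#' \code{sep_ridge}, \code{sep_lasso}).
#'
#' @return Character vector of method keys.
#' @export
study_methods <- function() {
  c("overall", "hom_ml", "hom_ridge",
    "hte_ml", "hte_ridge", "hte_lasso", "hte_hgl", "hte_ck_ridge",
    "rm_ml", "rm_ridge", "sb",
    "sep_ml", "sep_ridge", "sep_lasso")
}

#' Fit a study method by key
#'
#' Dispatches a Table-1 method key to the corresponding model family and
#' estimator; penalized methods run 10-fold cross-validated penalty
#' selection.
#'
#' @param key one of \code{\link{study_methods}}.
#' @param trial an \code{ite_trial} (or list with \code{X}, \code{a},
#'   \code{y}).
#' @param seed seed for fold assignments where CV is involved.
#' @param K folds for CV (default 10).
#' @return A fitted model usable with \code{\link{predict_risks}}.
#' @export
fit_method <- function(key, trial, seed = NULL, K = 10L) {
  key <- match.arg(key, study_methods())
  X <- trial$X; a <- trial$a; y <- trial$y
  p <- ncol(X)
  des <- function(fam, est) build_design(model_spec(fam, est, p = p), X, a)

  switch(
    key,
    overall = fit_overall(a, y),
    hom_ml = {
      sp <- model_spec("homogeneous", "ml", p = p)
      fit_ml(build_design(sp, X, a), y, sp)
    },
    hom_ridge = {
      sp <- model_spec("homogeneous", "ridge", p = p)
      fit_penalized_cv(build_design(sp, X, a), y, "ridge", K = K,
                       seed = seed, spec = sp)
    },
    hte_ml = {
      sp <- model_spec("hte_full", "ml", p = p)
      fit_ml(build_design(sp, X, a), y, sp)
    },
    hte_ridge = {
      sp <- model_spec("hte_full", "ridge", p = p)
      fit_penalized_cv(build_design(sp, X, a), y, "ridge", K = K,
                       seed = seed, spec = sp)
    },
    hte_lasso = {
      sp <- model_spec("hte_full", "lasso", p = p)
      fit_penalized_cv(build_design(sp, X, a), y, "lasso", K = K,
                       seed = seed, spec = sp)
    },
    hte_hgl = fit_hgl_cv(X, a, y, K = K, seed = seed),
    hte_ck_ridge = {
      sp <- model_spec("hte_ck", "ridge", p = p)
      fit_penalized_cv(build_design(sp, X, a), y, "ridge", K = K,
                       seed = seed, spec = sp)
    },
    rm_ml = fit_risk_model(X, a, y, "ml"),
    rm_ridge = fit_risk_model(X, a, y, "ridge", K = K, seed = seed),
    sb = significance_based(X, a, y),
    sep_ml = fit_separate_arms(X, a, y, "ml"),
    sep_ridge = fit_separate_arms(X, a, y, "ridge", K = K, seed = seed),
    sep_lasso = fit_separate_arms(X, a, y, "lasso", K = K, seed = seed)
  )
}
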