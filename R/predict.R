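# Counterfactual risk predictions and the individualized treatment
# effect on the risk-difference scale.

new_ite_prediction <- function(p0_hat, p1_hat) {
  p0_hat <- unname(p0_hat)
  p1_hat <- unname(p1_hat)
  structure(list(p0_hat = p0_hat, p1_hat = p1_hat,
                 delta_hat = p1_hat - p0_hat),
            class = "ite_prediction")
}

#' @export
print.ite_prediction <- function(x, ...) {
  cat("ITE predictions for", length(x$delta_hat), "subjects\n")
  cat("  mean delta_hat:", format(mean(x$delta_hat), digits = 4),
      "| range:", paste(format(range(x$delta_hat), digits = 3),
                        collapse = " .. "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ite_prediction <- function(x, ...) {
  data.frame(p0_hat = x$p0_hat, p1_hat = x$p1_hat, delta_hat = x$delta_hat)
}

#' Predict potential-outcome risks and treatment effect
#'
#' Evaluates the fitted model with treatment forced to 0 and to 1
#' (counterfactual plug-in) and differences the two risks:
#' \eqn{\hat\delta(x) = \hat p_1(x) - \hat p_0(x)}.  For the
#' \code{overall} family both risks are the arm-level event rates; for
#' \code{risk_model} fits the stage-1 risk score is recomputed from the
#' covariates.
#'
#' @param model an \code{ite_fit} or \code{ite_fit_pair}.
#' @param X covariate matrix for the subjects to predict.
#' @return An object of class \code{ite_prediction} with vectors
#'   \code{p0_hat}, \code{p1_hat}, \code{delta_hat}.
#' @export
predict_risks <- function(model, X) UseMethod("predict_risks")

#' @export
predict_risks.ite_fit <- function(model, X) {
  X <- as.matrix(X)
  fam <- model$spec$family
  if (fam == "overall") {
    am <- model$arm_means
    return(new_ite_prediction(rep(am[["control"]], nrow(X)),
                              rep(am[["treated"]], nrow(X))))
  }
  if (fam == "risk_model") {
    b1 <- model$stage1
    eta <- drop(b1[1] + X %*% b1[-1])
    b2 <- model$stage2
    lp0 <- eta
    lp1 <- eta + b2[["treat"]] + b2[["treat:eta"]] * eta
    return(new_ite_prediction(stats::plogis(lp0), stats::plogis(lp1)))
  }

  cf <- model$coefficients
  roles <- model$roles
  index <- model$index
  if (max(index, 0, na.rm = TRUE) > ncol(X)) {
    stop("covariate matrix has fewer columns than the fitted model uses",
         call. = FALSE)
  }
  lp0 <- rep(if (any(roles == "intercept")) cf[roles == "intercept"] else 0,
             nrow(X))
  main_i <- which(roles == "main")
  if (length(main_i)) {
    lp0 <- lp0 + drop(X[, index[main_i], drop = FALSE] %*% cf[main_i])
  }
  lp1 <- lp0
  if (any(roles == "treatment")) lp1 <- lp1 + cf[roles == "treatment"]
  inter_i <- which(roles == "interaction")
  if (length(inter_i)) {
    lp1 <- lp1 + drop(X[, index[inter_i], drop = FALSE] %*% cf[inter_i])
  }
  new_ite_prediction(stats::plogis(lp0), stats::plogis(lp1))
}

#' @export
predict_risks.ite_fit_pair <- function(model, X) {
  predict_delta_separate(model, X)
}

#' Predictions from per-arm models
#'
#' \code{p0_hat} comes from the control-arm model and \code{p1_hat}
#' from the treated-arm model.
#'
#' @param models an \code{ite_fit_pair} from
#'   \code{\link{fit_separate_arms}}.
#' @param X covariate matrix.
#' @return An \code{ite_prediction}.
#' @export
predict_delta_separate <- function(models, X) {
  stopifnot(inherits(models, "ite_fit_pair"))
  X <- as.matrix(X)
  arm_lp <- function(fit) {
    cf <- fit$coefficients
    main_i <- which(fit$roles == "main")
    lp <- rep(cf[fit$roles == "intercept"], nrow(X))
    if (length(main_i)) {
      lp <- lp + drop(X[, fit$index[main_i], drop = FALSE] %*% cf[main_i])
    }
    lp
  }
  new_ite_prediction(stats::plogis(arm_lp(models$control)),
                     stats::plogis(arm_lp(models$treated)))
}
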