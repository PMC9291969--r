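# Declarative model specifications and design-matrix construction.
#
# A spec records which terms enter the linear predictor; estimation is
# handled separately so the same spec can be fitted by ML, ridge, lasso
# or the hierarchical group lasso.

MODEL_FAMILIES <- c("overall", "homogeneous", "hte_full", "hte_ck",
                    "risk_model", "significance_based", "separate_arms")
ESTIMATORS <- c("ml", "ridge", "lasso", "hgl")

#' Create a model specification
#'
#' @param family model family: \code{"overall"} (marginal arm difference),
#'   \code{"homogeneous"} (treatment + main effects, no interactions),
#'   \code{"hte_full"} (all treatment-covariate interactions),
#'   \code{"hte_ck"} (content-knowledge restriction: a named subset of
#'   main effects and interaction candidates), \code{"risk_model"}
#'   (control-arm risk score interacted with treatment),
#'   \code{"significance_based"} or \code{"separate_arms"}.
#' @param estimator \code{"ml"}, \code{"ridge"}, \code{"lasso"} or
#'   \code{"hgl"} (the last only for interaction-bearing families).
#' @param p number of covariates (default 12).
#' @param main_effect_indices covariate indices entering as main effects.
#' @param interaction_indices covariate indices entering as
#'   treatment-covariate interactions.  Must be empty for
#'   \code{family = "homogeneous"} and all of \code{1..p} for
#'   \code{family = "hte_full"}.
#' @param options named list of estimator settings (e.g. a fixed
#'   \code{lambda}, \code{nfolds}, \code{n_lambda}).
#' @return An object of class \code{ite_spec}.
#' @export
#' @examples
#' model_spec("homogeneous", "ml")
#' model_spec("hte_ck", "ridge")  # main effects 1-12, interactions 9-12
model_spec <- function(family, estimator = "ml", p = 12L,
                       main_effect_indices = NULL,
                       interaction_indices = NULL,
                       options = list()) {
  family <- match.arg(family, MODEL_FAMILIES)
  estimator <- match.arg(estimator, ESTIMATORS)
  p <- as.integer(p)

  if (is.null(main_effect_indices)) main_effect_indices <- seq_len(p)
  if (is.null(interaction_indices)) {
    interaction_indices <- switch(
      family,
      homogeneous = integer(0),
      overall = integer(0),
      hte_full = seq_len(p),
      # content knowledge: only covariates 9-12 are plausible effect
      # modifiers; strong hierarchy keeps their main effects in too
      hte_ck = intersect(9:12, seq_len(p)),
      seq_len(p)
    )
  }
  if (!all(main_effect_indices %in% seq_len(p)) ||
      !all(interaction_indices %in% seq_len(p))) {
    stop("covariate indices out of range 1..p", call. = FALSE)
  }
  if (family == "homogeneous" && length(interaction_indices) > 0) {
    stop("homogeneous models admit no interaction terms", call. = FALSE)
  }
  if (family == "hte_full" &&
      !setequal(interaction_indices, seq_len(p))) {
    stop("`hte_full` interacts treatment with every covariate", call. = FALSE)
  }
  if (estimator == "hgl" &&
      !family %in% c("hte_full", "hte_ck")) {
    stop("the hierarchical group lasso requires an interaction-bearing family",
         call. = FALSE)
  }
  structure(
    list(family = family, estimator = estimator, p = p,
         main_effect_indices = as.integer(sort(main_effect_indices)),
         interaction_indices = as.integer(sort(interaction_indices)),
         options = options),
    class = "ite_spec"
  )
}

#' @export
print.ite_spec <- function(x, ...) {
  cat("Model spec:", x$family, "/", x$estimator, "\n")
  cat("  main effects:", length(x$main_effect_indices),
      "| interactions:", length(x$interaction_indices), "\n")
  invisible(x)
}

#' Build the design matrix for a model specification
#'
#' Layout: intercept, treatment, main-effect columns \code{x<j>}, then
#' interaction columns \code{a:x<j>} (elementwise products of the
#' treatment column with the corresponding main-effect column).
#'
#' @param spec an \code{ite_spec}.
#' @param X covariate matrix.
#' @param a 0/1 treatment vector.
#' @return An object of class \code{ite_design}: list with the numeric
#'   matrix \code{values}, per-column \code{roles} (\code{"intercept"},
#'   \code{"treatment"}, \code{"main"}, \code{"interaction"}), the
#'   covariate index per column (\code{index}, NA for intercept and
#'   treatment), and an optional \code{offset}.
#' @export
build_design <- function(spec, X, a) {
  stopifnot(inherits(spec, "ite_spec"))
  X <- as.matrix(X)
  if (ncol(X) < max(c(spec$main_effect_indices, spec$interaction_indices, 1L))) {
    stop("covariate matrix has fewer columns than the spec references",
         call. = FALSE)
  }
  stopifnot(nrow(X) == length(a))
  a <- as.numeric(a)

  mains <- X[, spec$main_effect_indices, drop = FALSE]
  colnames(mains) <- paste0("x", spec$main_effect_indices)
  cols <- cbind(`(Intercept)` = 1, treat = a, mains)
  roles <- c("intercept", "treatment", rep("main", ncol(mains)))
  index <- c(NA_integer_, NA_integer_, spec$main_effect_indices)

  if (length(spec$interaction_indices) > 0) {
    inter <- X[, spec$interaction_indices, drop = FALSE] * a
    colnames(inter) <- paste0("treat:x", spec$interaction_indices)
    cols <- cbind(cols, inter)
    roles <- c(roles, rep("interaction", ncol(inter)))
    index <- c(index, spec$interaction_indices)
  }

  structure(list(values = cols, roles = roles, index = index, offset = NULL),
            class = "ite_design")
}

#' Second-stage design for the risk-modeling approach
#'
#' The control-arm risk score \eqn{\hat\eta} enters as an offset, and the
#' model estimates a treatment main effect plus a linear
#' treatment-by-risk-score interaction:
#' \deqn{\mathrm{logit}\,P(Y=1) = \hat\eta + \beta_t a + \gamma\, a \hat\eta.}
#' There is no free intercept; for control rows the fitted probability is
#' exactly \eqn{\mathrm{expit}(\hat\eta)}.
#'
#' @param eta_hat risk-score linear predictor per subject (finite).
#' @param a 0/1 treatment vector.
#' @return An \code{ite_design} with columns \code{treat} and
#'   \code{treat:eta} and offset \code{eta_hat}.
#' @export
build_risk_model_stage2 <- function(eta_hat, a) {
  stopifnot(length(eta_hat) == length(a), all(is.finite(eta_hat)))
  a <- as.numeric(a)
  vals <- cbind(treat = a, `treat:eta` = a * eta_hat)
  structure(list(values = vals,
                 roles = c("treatment", "interaction"),
                 index = c(NA_integer_, NA_integer_),
                 offset = as.numeric(eta_hat)),
            class = "ite_design")
}

# columns of a design that a penalized estimator may shrink
penalized_columns <- function(design) design$roles != "intercept"
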