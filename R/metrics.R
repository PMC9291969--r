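# Performance measures for individualized treatment effect prediction.

#' Root mean squared prediction error
#'
#' \eqn{\mathrm{rMSPE} = \sqrt{n^{-1}\sum_i(\hat\delta_i - \delta_i)^2}},
#' an error on the risk-difference scale.
#'
#' @param delta_hat predicted treatment effects.
#' @param delta_true true treatment effects (same length).
#' @return Non-negative scalar.
#' @export
rmspe <- function(delta_hat, delta_true) {
  if (length(delta_hat) != length(delta_true) || length(delta_hat) < 1) {
    stop("`delta_hat` and `delta_true` must have equal length >= 1",
         call. = FALSE)
  }
  sqrt(mean((delta_hat - delta_true)^2))
}

#' 0.9-quantile of absolute prediction errors
#'
#' Empirical 0.9-quantile (linear-interpolation / type-7) of
#' \code{|pred - true|}; used for both treatment-effect and risk
#' predictions.
#'
#' @param pred predicted values.
#' @param true true values (same length).
#' @param prob quantile level (default 0.9).
#' @return Non-negative scalar.
#' @export
q90_abs_error <- function(pred, true, prob = 0.9) {
  if (length(pred) != length(true)) {
    stop("length mismatch", call. = FALSE)
  }
  unname(stats::quantile(abs(pred - true), probs = prob, type = 7))
}

# equal-size rank-based grouping with stable tie handling: ties (and
# constant inputs) are split by original input order
quantile_groups <- function(x, groups) {
  n <- length(x)
  stopifnot(groups >= 2, n >= groups)
  ord <- order(x)                       # stable in R
  sizes <- diff(round(seq(0, n, length.out = groups + 1)))
  g <- integer(n)
  g[ord] <- rep(seq_len(groups), times = sizes)
  g
}

#' Calibration table over equal-size prediction bins
#'
#' Predictions are cut into \code{bins} equal-size rank groups and the
#' mean prediction is compared to the mean true value per bin.
#'
#' @param pred predicted values (treatment effects or risks).
#' @param true true values from the generating mechanism (or observed
#'   outcomes).
#' @param bins number of equal-size groups (default 20).
#' @return A data.frame with columns \code{bin}, \code{n},
#'   \code{mean_pred}, \code{mean_true}, \code{se_true}.
#' @export
calibration_table <- function(pred, true, bins = 20L) {
  if (length(pred) != length(true)) stop("length mismatch", call. = FALSE)
  if (length(pred) < bins) stop("fewer observations than bins", call. = FALSE)
  g <- quantile_groups(pred, bins)
  out <- lapply(seq_len(bins), function(b) {
    i <- g == b
    data.frame(bin = b, n = sum(i),
               mean_pred = mean(pred[i]),
               mean_true = mean(true[i]),
               se_true = stats::sd(true[i]) / sqrt(sum(i)))
  })
  do.call(rbind, out)
}

#' Brier score
#'
#' Mean squared difference between binary outcomes and predicted
#' probabilities.
#'
#' @param y 0/1 outcomes.
#' @param p_hat predicted probabilities.
#' @return Scalar in [0, 1].
#' @export
brier <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stop("length mismatch", call. = FALSE)
  check_binary(y, "y")
  mean((y - p_hat)^2)
}

#' Nagelkerke R-squared
#'
#' Likelihood-ratio R-squared rescaled to a maximum of 1:
#' \eqn{R^2_{CS} = 1 - \exp\{2(\ell_0 - \ell_1)/n\}} divided by
#' \eqn{1 - \exp\{2\ell_0/n\}}, where \eqn{\ell_1} is the Bernoulli
#' log-likelihood at \code{p_hat} and \eqn{\ell_0} at the reference
#' prevalence.  Zero at the null model; may be negative out-of-sample.
#'
#' @param y 0/1 outcomes (both classes must be present).
#' @param p_hat predicted (or true) event probabilities.
#' @param reference_prevalence prevalence defining the null model;
#'   defaults to \code{mean(y)} in the evaluated sample.
#' @return Unitless scalar (at most 1).
#' @export
nagelkerke_r2 <- function(y, p_hat, reference_prevalence = NULL) {
  if (length(y) != length(p_hat)) stop("length mismatch", call. = FALSE)
  check_binary(y, "y")
  if (all(y == 0) || all(y == 1)) {
    stop("Nagelkerke R-squared is undefined for a single-class outcome",
         call. = FALSE)
  }
  n <- length(y)
  if (is.null(reference_prevalence)) reference_prevalence <- mean(y)
  ll1 <- bernoulli_loglik(y, p_hat)
  ll0 <- bernoulli_loglik(y, rep(reference_prevalence, n))
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_cs / (1 - exp(2 * ll0 / n))
}

#' Concordance statistic (c-statistic)
#'
#' Probability that a random event subject has a higher predicted risk
#' than a random non-event subject; ties count one half.  Computed via
#' midranks (equivalent to the all-pairs count).
#'
#' @param y 0/1 outcomes (both classes must be present).
#' @param p_hat predicted probabilities (any monotone score works).
#' @return Scalar in [0, 1].
#' @export
c_statistic <- function(y, p_hat) {
  if (length(y) != length(p_hat)) stop("length mismatch", call. = FALSE)
  check_binary(y, "y")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("c-statistic requires both outcome classes", call. = FALSE)
  }
  r <- rank(p_hat, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
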