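#' @useDynLib itepredict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats glm binomial coef predict plogis qlogis rnorm rbinom runif
#'   uniroot pchisq quantile sd var setNames
NULL

# non-standard-evaluation column names used in ggplot2 aes()
utils::globalVariables(c(
  "method", "se", "mean_pred", "mean_true", "se_true",
  "mean_delta_hat", "observed_effect", "setting"
))

# inverse logit; stats::plogis is used directly where convenient
expit <- function(x) stats::plogis(x)

# clip probabilities away from 0/1 before taking logs in metrics
# (never applied to predictions themselves)
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Bernoulli log-likelihood
bernoulli_loglik <- function(y, p, eps = 1e-12) {
  p <- clip_prob(p, eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# deterministic derived seeds kept well below .Machine$integer.max;
# `stream` separates covariate / treatment / outcome draws so the
# streams are independent for a given user-facing seed
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483647)
}

check_binary <- function(x, name = deparse(substitute(x))) {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0/1 values", name), call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(p, name = deparse(substitute(p))) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop(sprintf("`%s` must be a probability strictly in (0, 1)", name),
         call. = FALSE)
  }
  invisible(p)
}
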