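# Penalized maximum likelihood (ridge / lasso) and cross-validated
# penalty selection.  Ridge and lasso fits are delegated to glmnet,
# which minimizes the same objective used throughout this package:
#   (1/n) * negative log-likelihood + lambda * P(beta),
# with P the ridge (0.5 * sum beta^2) or lasso (sum |beta|) penalty over
# all non-intercept columns, columns standardized internally and
# coefficients returned on the original scale.

# population-style standard deviation used for lambda_max computations
# (matches glmnet's internal standardization)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Build a descending penalty grid
#'
#' For lasso and the hierarchical group lasso the grid starts at the
#' smallest \eqn{\lambda_{max}} that sets every penalized term to zero
#' (computed from the gradient of the null model) and decreases
#' log-linearly to \eqn{\lambda_{max} \cdot ratio}.  The ridge penalty
#' has no finite \eqn{\lambda_{max}}, so a fixed log-spaced span is
#' used.
#'
#' @param design an \code{ite_design} (for \code{penalty = "hgl"} pass
#'   the full-interaction design; the grid is computed from the latent
#'   group structure).
#' @param y 0/1 outcome vector.
#' @param penalty \code{"ridge"}, \code{"lasso"} or \code{"hgl"}.
#' @param n_lambda grid length; defaults: ridge/lasso 100, hgl 50.
#' @param ratio smallest/largest grid value; defaults: ridge span
#'   \code{[1e-4, 1e4]}, lasso 1e-3, hgl 1e-2.
#' @return Strictly decreasing numeric vector of penalties.
#' @export
make_lambda_grid <- function(design, y, penalty = c("ridge", "lasso", "hgl"),
                             n_lambda = NULL, ratio = NULL) {
  penalty <- match.arg(penalty)
  if (penalty == "ridge") {
    if (is.null(n_lambda)) n_lambda <- 100L
    stopifnot(n_lambda >= 2)
    return(exp(seq(log(1e4), log(1e-4), length.out = n_lambda)))
  }
  y <- as.numeric(y)
  if (penalty == "lasso") {
    if (is.null(n_lambda)) n_lambda <- 100L
    if (is.null(ratio)) ratio <- 1e-3
    lmax <- lasso_lambda_max(design, y)
  } else {
    if (is.null(n_lambda)) n_lambda <- 50L
    if (is.null(ratio)) ratio <- 1e-2
    lmax <- hgl_lambda_max_design(design, y)
  }
  stopifnot(n_lambda >= 2, ratio > 0, ratio < 1)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# smallest lambda zeroing all lasso coefficients: max over standardized
# penalized columns of |<x_j, y - ybar>| / n at the null model
lasso_lambda_max <- function(design, y) {
  x <- design$values[, penalized_columns(design), drop = FALSE]
  n <- length(y)
  xs <- scale(x, center = TRUE, scale = apply(x, 2, pop_sd))
  xs[is.na(xs)] <- 0  # constant columns carry no gradient
  max(abs(crossprod(xs, y - mean(y)))) / n
}

#' Fit a ridge- or lasso-penalized logistic model at a given penalty
#'
#' @param design an \code{ite_design} with an intercept column; all
#'   other columns are penalized.
#' @param y 0/1 outcome vector.
#' @param penalty \code{"ridge"} or \code{"lasso"}.
#' @param lambda penalty value (\code{lambda = 0} reproduces the ML fit).
#' @param spec optional \code{ite_spec} stored with the fit.
#' @return An \code{ite_fit}; coefficients are on the original covariate
#'   scale and the intercept is never penalized.
#' @export
fit_penalized <- function(design, y, penalty = c("ridge", "lasso"), lambda,
                          spec = NULL) {
  penalty <- match.arg(penalty)
  stopifnot(inherits(design, "ite_design"), lambda >= 0)
  y <- as.numeric(y)
  check_binary(y, "y")
  if (is.null(spec)) {
    spec <- model_spec("homogeneous", penalty,
                       p = max(1L, sum(design$roles == "main")))
  }

  keep <- penalized_columns(design)
  x <- design$values[, keep, drop = FALSE]
  if (is.null(colnames(x)) || any(colnames(x) == "")) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  alpha <- if (penalty == "lasso") 1 else 0

  # glmnet is fitted along a short descending warm-start path ending at
  # the requested lambda, whose solution is then read off exactly
  top <- max(lambda * 100, 1)
  path <- exp(seq(log(top), log(max(lambda, top * 1e-6)), length.out = 15))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  # read the solution off the path at the requested lambda (it is a
  # member of the supplied sequence, so no interpolation is needed)
  j <- which.min(abs(fit$lambda - lambda))
  cf <- as.numeric(rbind(fit$a0, as.matrix(fit$beta))[, j])

  full <- setNames(numeric(ncol(design$values)), colnames(design$values))
  full[design$roles == "intercept"] <- cf[1]
  full[which(keep)] <- cf[-1]

  mu <- stats::plogis(drop(design$values %*% full))
  new_ite_fit(spec, full, design$roles, design$index,
              loglik = bernoulli_loglik(y, mu),
              convergence = list(converged = TRUE,
                                 iterations = fit$npasses,
                                 separation = FALSE),
              selected_lambda = lambda)
}

# outcome-stratified fold assignment (events and non-events are spread
# evenly across the K folds); returns integer labels in 1..K
stratified_folds <- function(y, K, seed = NULL) {
  stopifnot(K >= 2, length(y) >= K)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(K), length(idx)))
  }
  folds
}

# summed deviance of predictions on held-out data
held_out_deviance <- function(y, p_hat) {
  p_hat <- clip_prob(p_hat)
  -2 * sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
}

#' Select a penalty by K-fold cross-validated deviance
#'
#' Folds are stratified by outcome.  For each candidate penalty the
#' total held-out deviance \eqn{-2\sum[y\log\hat p + (1-y)\log(1-\hat p)]}
#' is accumulated across folds and the minimizing penalty is selected
#' (ties resolve to the larger penalty).
#'
#' @param design an \code{ite_design} (full-interaction design for
#'   \code{penalty = "hgl"}).
#' @param y 0/1 outcome vector.
#' @param penalty \code{"ridge"}, \code{"lasso"} or \code{"hgl"}.
#' @param K number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param lambda_grid optional descending grid; defaults to
#'   \code{\link{make_lambda_grid}}.
#' @return An object of class \code{ite_cv}: list with
#'   \code{lambda_grid}, \code{fold_assignments}, \code{deviance} (one
#'   total per grid point) and \code{selected_lambda}.
#' @export
cv_select_lambda <- function(design, y, penalty = c("ridge", "lasso", "hgl"),
                             K = 10L, seed = NULL, lambda_grid = NULL) {
  penalty <- match.arg(penalty)
  y <- as.numeric(y)
  if (is.null(lambda_grid)) lambda_grid <- make_lambda_grid(design, y, penalty)
  if (length(lambda_grid) == 0) stop("empty penalty grid", call. = FALSE)
  stopifnot(all(diff(lambda_grid) < 0) || length(lambda_grid) == 1)

  folds <- stratified_folds(y, K, seed)
  dev <- numeric(length(lambda_grid))

  for (k in seq_len(K)) {
    train <- folds != k
    test <- !train
    if (!any(test)) next
    p_mat <- cv_path_predictions(design, y, penalty, lambda_grid,
                                 train, test)
    for (l in seq_along(lambda_grid)) {
      dev[l] <- dev[l] + held_out_deviance(y[test], p_mat[, l])
    }
  }

  structure(list(lambda_grid = lambda_grid,
                 fold_assignments = folds,
                 deviance = dev,
                 selected_lambda = lambda_grid[which.min(dev)],
                 penalty = penalty),
            class = "ite_cv")
}

#' @export
print.ite_cv <- function(x, ...) {
  cat("Cross-validated penalty selection (", x$penalty, ", ",
      length(x$lambda_grid), " grid points, K = ",
      max(x$fold_assignments), ")\n", sep = "")
  cat("  selected lambda:", format(x$selected_lambda, digits = 5), "\n")
  invisible(x)
}

# held-out predicted probabilities for every grid point, one fold
cv_path_predictions <- function(design, y, penalty, lambda_grid,
                                train, test) {
  if (penalty == "hgl") {
    Xa <- design_to_raw(design)
    path <- hgl_path(Xa$X[train, , drop = FALSE], Xa$a[train], y[train],
                     lambda_grid)
    p_mat <- sapply(seq_along(lambda_grid), function(l) {
      lp <- hgl_linear_predictor(path$coefficients[, l],
                                 Xa$X[test, , drop = FALSE], Xa$a[test])
      stats::plogis(lp)
    })
  } else {
    keep <- penalized_columns(design)
    x <- design$values[, keep, drop = FALSE]
    alpha <- if (penalty == "lasso") 1 else 0
    fit <- glmnet::glmnet(x[train, , drop = FALSE], y[train],
                          family = "binomial", alpha = alpha,
                          lambda = lambda_grid, standardize = TRUE,
                          thresh = 1e-10, maxit = 1e6)
    p_mat <- stats::predict(fit, newx = x[test, , drop = FALSE],
                            s = lambda_grid, type = "response")
  }
  matrix(p_mat, nrow = sum(test), ncol = length(lambda_grid))
}

# recover (X, a) from a full-interaction design
design_to_raw <- function(design) {
  main_cols <- design$roles == "main"
  list(X = design$values[, main_cols, drop = FALSE],
       a = design$values[, design$roles == "treatment"])
}

#' Fit a penalized model with cross-validated penalty selection
#'
#' Convenience wrapper: build the grid, run
#' \code{\link{cv_select_lambda}}, refit on the full data at the
#' selected penalty.
#'
#' @inheritParams cv_select_lambda
#' @param spec optional \code{ite_spec} stored with the fit.
#' @return An \code{ite_fit} carrying the \code{ite_cv} object in
#'   \code{$cv}.
#' @export
fit_penalized_cv <- function(design, y, penalty = c("ridge", "lasso"),
                             K = 10L, seed = NULL, lambda_grid = NULL,
                             spec = NULL) {
  penalty <- match.arg(penalty)
  cv <- cv_select_lambda(design, y, penalty, K = K, seed = seed,
                         lambda_grid = lambda_grid)
  fit <- fit_penalized(design, y, penalty, cv$selected_lambda, spec = spec)
  fit$cv <- cv
  fit
}
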