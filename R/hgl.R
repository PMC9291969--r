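# Hierarchical group lasso for treatment-covariate interactions.
#
# The model is the full-interaction logistic model; selection acts on a
# latent-overlap group structure so that an interaction can only enter
# together with the main effects of its two components (strong
# hierarchy).  See src/hgl.cpp for the solver.

HGL_GROUP_WEIGHT <- sqrt(3)  # standard group-size scaling for size-3 groups

# expanded latent design: [a, x_1..x_p, (a, x_j, a*x_j) for each j]
hgl_latent_design <- function(X, a) {
  X <- as.matrix(X)
  a <- as.numeric(a)
  p <- ncol(X)
  blocks <- lapply(seq_len(p), function(j) cbind(a, X[, j], a * X[, j]))
  m <- cbind(a, X, do.call(cbind, blocks))
  colnames(m) <- c(
    "treat", paste0("x", seq_len(p)),
    unlist(lapply(seq_len(p), function(j)
      paste0(c("g", "g", "g"), j, c(":treat", ":x", ":prod"))))
  )
  m
}

# standardize latent columns; constant columns get scale 1
hgl_standardize <- function(m) {
  ctr <- colMeans(m)
  scl <- apply(m, 2, pop_sd)
  scl[scl == 0] <- 1
  list(Xs = sweep(sweep(m, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# smallest lambda at which every penalized latent term is zero
hgl_lambda_max <- function(X, a, y) {
  std <- hgl_standardize(hgl_latent_design(X, a))
  n <- length(y)
  p <- ncol(as.matrix(X))
  g <- drop(crossprod(std$Xs, mean(y) - y)) / n
  sing <- abs(g[seq_len(1 + p)])
  grp <- vapply(seq_len(p), function(j) {
    s <- 1 + p + 3 * (j - 1) + 1
    sqrt(sum(g[s:(s + 2)]^2)) / HGL_GROUP_WEIGHT
  }, numeric(1))
  max(sing, grp)
}

# lambda_max from a full-interaction design object (for make_lambda_grid)
hgl_lambda_max_design <- function(design, y) {
  raw <- design_to_raw(design)
  hgl_lambda_max(raw$X, raw$a, y)
}

#' Hierarchical group lasso over a penalty path
#'
#' Solves the latent-overlap group-lasso logistic regression by
#' proximal gradient (FISTA) with backtracking line search and warm
#' starts along a descending penalty path.  Parameters: an unpenalized
#' intercept; singleton groups for treatment and each main effect; and,
#' for each covariate \eqn{j}, a size-3 interaction group holding latent
#' copies of treatment and \eqn{x_j} plus the product \eqn{a x_j},
#' weighted by \eqn{\sqrt 3}.  Observed coefficients are sums of latent
#' contributions, which enforces strong hierarchy: a selected
#' interaction brings its main effects with it.
#'
#' @param X covariate matrix.
#' @param a 0/1 treatment vector.
#' @param y 0/1 outcome vector.
#' @param lambda_grid descending penalty path (default:
#'   \code{\link{make_lambda_grid}} with 50 points down to 1e-2 of
#'   \eqn{\lambda_{max}}).
#' @param tol relative-objective convergence tolerance (default 1e-7).
#' @param maxit maximum proximal-gradient iterations per path point.
#' @return List with \code{coefficients} (observed-scale coefficient
#'   matrix, rows \code{(Intercept), treat, x1..xp, treat:x1..treat:xp},
#'   one column per penalty), \code{latent} (standardized latent
#'   parameters), \code{lambda_grid}, \code{iterations},
#'   \code{objective}.
#' @export
hgl_path <- function(X, a, y, lambda_grid = NULL, tol = 1e-7, maxit = 1e4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  m <- hgl_latent_design(X, a)
  std <- hgl_standardize(m)
  if (is.null(lambda_grid)) {
    lmax <- hgl_lambda_max(X, a, y)
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-2), length.out = 50))
  }
  sol <- hgl_fista_path(std$Xs, y, p, lambda_grid, HGL_GROUP_WEIGHT,
                        tol, as.integer(maxit))
  theta <- sol$theta  # (1 + q) x nlam, standardized latent scale
  q <- ncol(m)
  nlam <- length(lambda_grid)

  coefs <- matrix(0, nrow = 2 + 2 * p, ncol = nlam,
                  dimnames = list(c("(Intercept)", "treat",
                                    paste0("x", seq_len(p)),
                                    paste0("treat:x", seq_len(p))), NULL))
  for (l in seq_len(nlam)) {
    th <- theta[-1, l] / std$scale            # latent, original scale
    b0 <- theta[1, l] - sum(theta[-1, l] * std$center / std$scale)
    bt <- th[1]
    bm <- th[1 + seq_len(p)]
    bz <- numeric(p)
    for (j in seq_len(p)) {
      s <- 1 + p + 3 * (j - 1) + 1
      bt <- bt + th[s]
      bm[j] <- bm[j] + th[s + 1]
      bz[j] <- th[s + 2]
    }
    coefs[, l] <- c(b0, bt, bm, bz)
  }
  list(coefficients = coefs, latent = theta, lambda_grid = lambda_grid,
       iterations = sol$iterations, objective = sol$objective,
       scale = std$scale, center = std$center)
}

# linear predictor from one column of hgl_path coefficients
hgl_linear_predictor <- function(coefs, X, a) {
  p <- ncol(as.matrix(X))
  b0 <- coefs[1]; bt <- coefs[2]
  bm <- coefs[2 + seq_len(p)]
  bz <- coefs[2 + p + seq_len(p)]
  drop(b0 + bt * a + as.matrix(X) %*% bm + (as.matrix(X) %*% bz) * a)
}

#' Fit the hierarchical group lasso at one penalty value
#'
#' @inheritParams hgl_path
#' @param lambda penalty value.
#' @return An \code{ite_fit} (family \code{"hte_full"}, estimator
#'   \code{"hgl"}); component \code{hgl} holds the latent solution for
#'   hierarchy inspection.
#' @export
fit_hgl <- function(X, a, y, lambda, tol = 1e-7, maxit = 1e4) {
  stopifnot(lambda >= 0)
  X <- as.matrix(X)
  p <- ncol(X)
  lmax <- hgl_lambda_max(X, a, y)
  # short warm-start path down to the requested value
  if (lambda >= lmax) {
    grid <- lambda
  } else {
    grid <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-8)),
                    length.out = 12))
    grid <- sort(unique(c(grid, lambda)), decreasing = TRUE)
  }
  path <- hgl_path(X, a, y, grid, tol = tol, maxit = maxit)
  l <- which(grid == lambda)[1]

  spec <- model_spec("hte_full", "hgl", p = p)
  design_names <- c("(Intercept)", "treat", paste0("x", seq_len(p)),
                    paste0("treat:x", seq_len(p)))
  cf <- setNames(path$coefficients[, l], design_names)
  new_ite_fit(spec, cf,
              roles = c("intercept", "treatment", rep("main", p),
                        rep("interaction", p)),
              index = c(NA, NA, seq_len(p), seq_len(p)),
              loglik = {
                lp <- hgl_linear_predictor(path$coefficients[, l], X, a)
                bernoulli_loglik(y, stats::plogis(lp))
              },
              convergence = list(converged = path$iterations[l] < maxit,
                                 iterations = path$iterations[l],
                                 separation = FALSE,
                                 objective = path$objective[l]),
              selected_lambda = lambda,
              extra = list(hgl = list(latent = path$latent[, l],
                                      scale = path$scale,
                                      lambda_max = lmax)))
}

#' Fit the hierarchical group lasso with cross-validated penalty
#'
#' @inheritParams hgl_path
#' @param K number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param n_lambda,ratio path controls (defaults 50 and 1e-2).
#' @return An \code{ite_fit} with the \code{ite_cv} object in \code{$cv}.
#' @export
fit_hgl_cv <- function(X, a, y, K = 10L, seed = NULL,
                       n_lambda = 50L, ratio = 1e-2,
                       tol = 1e-7, maxit = 1e4) {
  X <- as.matrix(X)
  spec <- model_spec("hte_full", "hgl", p = ncol(X))
  design <- build_design(spec, X, a)
  lmax <- hgl_lambda_max(X, a, y)
  grid <- exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
  cv <- cv_select_lambda(design, y, "hgl", K = K, seed = seed,
                         lambda_grid = grid)
  fit <- fit_hgl(X, a, y, cv$selected_lambda, tol = tol, maxit = maxit)
  fit$cv <- cv
  fit
}

#' Does a fit satisfy strong hierarchy?
#'
#' For every covariate with a nonzero interaction coefficient, checks
#' that the observed treatment coefficient and the covariate's main
#' effect are nonzero too.
#'
#' @param fit an \code{ite_fit} with interaction terms.
#' @return \code{TRUE}/\code{FALSE}.
#' @export
hgl_hierarchy_holds <- function(fit) {
  cf <- fit$coefficients
  inter <- fit$roles == "interaction"
  if (!any(inter)) return(TRUE)
  active <- which(inter & cf != 0)
  if (length(active) == 0) return(TRUE)
  bt <- cf[fit$roles == "treatment"]
  all(vapply(active, function(i) {
    j <- fit$index[i]
    main_i <- which(fit$roles == "main" & fit$index == j)
    bt != 0 && cf[main_i] != 0
  }, logical(1)))
}
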