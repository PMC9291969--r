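# Bootstrap internal validation and treatment-effect calibration.

#' Treatment-effect calibration by quantile groups
#'
#' Groups subjects into quantiles of \eqn{\hat\delta} and compares, per
#' group, the mean predicted effect against the observed effect: event
#' rate among treated minus event rate among controls in that group.
#' The per-group standard error assumes independent binomial arm rates,
#' \eqn{\sqrt{\bar p_1(1-\bar p_1)/n_1 + \bar p_0(1-\bar p_0)/n_0}}.
#'
#' @param delta_hat predicted treatment effects.
#' @param y 0/1 outcomes.
#' @param a 0/1 treatment assignments.
#' @param groups number of quantile groups (default 5).
#' @return A data.frame with columns \code{group}, \code{n},
#'   \code{n_treated}, \code{n_control}, \code{mean_delta_hat},
#'   \code{observed_effect}, \code{se}; groups missing an arm get
#'   \code{NA} observed effect.
#' @export
te_calibration <- function(delta_hat, y, a, groups = 5L) {
  stopifnot(length(delta_hat) == length(y), length(y) == length(a),
            groups >= 2)
  check_binary(y, "y"); check_binary(a, "a")
  if (sum(a == 0) == 0 || sum(a == 1) == 0) {
    stop("both treatment arms must be represented", call. = FALSE)
  }
  g <- quantile_groups(delta_hat, groups)
  out <- lapply(seq_len(groups), function(k) {
    i <- g == k
    n1 <- sum(a[i] == 1); n0 <- sum(a[i] == 0)
    if (n1 == 0 || n0 == 0) {
      eff <- NA_real_; se <- NA_real_
    } else {
      p1 <- mean(y[i & a == 1]); p0 <- mean(y[i & a == 0])
      eff <- p1 - p0
      se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
    }
    data.frame(group = k, n = sum(i), n_treated = n1, n_control = n0,
               mean_delta_hat = mean(delta_hat[i]),
               observed_effect = eff, se = se)
  })
  do.call(rbind, out)
}

# predicted risk under the assigned arm
assigned_arm_risk <- function(pred, a) {
  ifelse(a == 1, pred$p1_hat, pred$p0_hat)
}

#' Bootstrap internal validation of model fit
#'
#' For each of \code{B} bootstrap resamples (with replacement, size n)
#' every specification is refitted on the resample -- including any
#' cross-validated penalty selection -- and evaluated on the out-of-bag
#' rows through the predicted risk under the assigned arm.  Out-of-bag
#' Brier scores and Nagelkerke R-squared values are averaged across
#' replicates.  Resamples with a single-class outcome or an empty
#' out-of-bag set are skipped and logged.
#'
#' @param trial an \code{ite_trial}.
#' @param specs character vector of method keys
#'   (see \code{\link{study_methods}}).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param reference \code{"oob"} (default) evaluates Nagelkerke
#'   R-squared against the out-of-bag sample's own prevalence,
#'   \code{"training"} against the resample prevalence.
#' @return List with \code{summary} (data.frame: method, mean out-of-bag
#'   \code{brier} and \code{nagelkerke_r2}, replicates used),
#'   \code{replicates} (long data.frame), \code{skipped} (log of skipped
#'   replicates).
#' @export
bootstrap_validate <- function(trial, specs, B = 100L, seed = 1L,
                               reference = c("oob", "training")) {
  stopifnot(inherits(trial, "ite_trial"), B >= 1)
  reference <- match.arg(reference)
  n <- length(trial$y)
  set.seed(seed)
  rep_seeds <- sample.int(1e6, B)

  rows <- list()
  skipped <- character(0)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    yb <- trial$y[idx]
    if (length(oob) == 0) {
      skipped <- c(skipped, sprintf("replicate %d: empty out-of-bag set", b))
      next
    }
    if (all(yb == 0) || all(yb == 1)) {
      skipped <- c(skipped, sprintf("replicate %d: single-class resample", b))
      next
    }
    boot <- new_ite_trial(trial$X[idx, , drop = FALSE], trial$a[idx], yb)
    y_oob <- trial$y[oob]
    a_oob <- trial$a[oob]
    ref_prev <- if (reference == "oob") mean(y_oob) else mean(yb)
    for (key in specs) {
      fit <- tryCatch(fit_method(key, boot, seed = rep_seeds[b]),
                      error = function(e) NULL)
      if (is.null(fit)) {
        skipped <- c(skipped, sprintf("replicate %d: %s failed", b, key))
        next
      }
      pred <- predict_risks(fit, trial$X[oob, , drop = FALSE])
      p_hat <- assigned_arm_risk(pred, a_oob)
      r2 <- if (all(y_oob == 0) || all(y_oob == 1)) NA_real_ else
        nagelkerke_r2(y_oob, p_hat, reference_prevalence = ref_prev)
      rows[[length(rows) + 1]] <- data.frame(
        replicate = b, method = key, n_oob = length(oob),
        brier = brier(y_oob, p_hat), nagelkerke_r2 = r2
      )
    }
  }
  reps <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(reps, reps$method), function(d) {
    data.frame(method = d$method[1],
               brier = mean(d$brier),
               nagelkerke_r2 = mean(d$nagelkerke_r2, na.rm = TRUE),
               replicates = nrow(d))
  }))
  rownames(summary) <- NULL
  list(summary = summary, replicates = reps, skipped = skipped)
}

#' Bootstrap out-of-sample treatment-effect calibration
#'
#' Per replicate: refit the specification on a bootstrap resample,
#' predict \eqn{\hat\delta} on the out-of-bag rows, form quantile
#' groups, and tabulate observed vs predicted effects.  Group identity
#' (quantile rank) is retained across replicates, mirroring the
#' color-coded out-of-sample calibration display.
#'
#' @param trial an \code{ite_trial}.
#' @param spec a method key (see \code{\link{study_methods}}).
#' @param B number of bootstrap replicates.
#' @param groups quantile groups (default 5).
#' @param seed integer seed.
#' @return List with \code{tables} (long data.frame of per-replicate
#'   group rows) and \code{skipped}.
#' @export
te_calibration_bootstrap <- function(trial, spec, B = 100L, groups = 5L,
                                     seed = 1L) {
  stopifnot(inherits(trial, "ite_trial"), B >= 1)
  n <- length(trial$y)
  set.seed(seed)
  rep_seeds <- sample.int(1e6, B)
  rows <- list()
  skipped <- character(0)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(idx))
    yb <- trial$y[idx]
    if (length(oob) < groups || all(yb == 0) || all(yb == 1)) {
      skipped <- c(skipped, sprintf("replicate %d skipped", b))
      next
    }
    boot <- new_ite_trial(trial$X[idx, , drop = FALSE], trial$a[idx], yb)
    fit <- tryCatch(fit_method(spec, boot, seed = rep_seeds[b]),
                    error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, sprintf("replicate %d: fit failed", b))
      next
    }
    pred <- predict_risks(fit, trial$X[oob, , drop = FALSE])
    tab <- te_calibration(pred$delta_hat, trial$y[oob], trial$a[oob],
                          groups = groups)
    tab$replicate <- b
    rows[[length(rows) + 1]] <- tab
  }
  list(tables = do.call(rbind, rows), skipped = skipped)
}
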