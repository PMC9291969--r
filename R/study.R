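# Factorial simulation-study orchestration: settings x sample sizes x
# methods x replicates, scored on an independent validation set against
# the known true treatment effects.

#' Configure a factorial simulation study
#'
#' @param settings data.frame with logical columns \code{main_effect}
#'   and \code{hte} (default: the full 2x2 factorial).
#' @param sample_sizes development-set sizes (default \code{c(400, 1200,
#'   3600)}).
#' @param methods method keys from \code{\link{study_methods}}.
#' @param replicates simulation replicates per cell (the full study uses
#'   250; 50 is a practical scale for routine runs).
#' @param val_n validation-set size (default 10000).
#' @param base_seed master seed; every replicate derives its own
#'   sub-stream from it.
#' @return A \code{ite_study_config} list.
#' @export
study_config <- function(settings = NULL,
                         sample_sizes = c(400L, 1200L, 3600L),
                         methods = study_methods(),
                         replicates = 50L,
                         val_n = 10000L,
                         base_seed = 1L) {
  if (is.null(settings)) {
    settings <- expand.grid(main_effect = c(TRUE, FALSE),
                            hte = c(FALSE, TRUE))
  }
  stopifnot(replicates >= 1, all(methods %in% study_methods()))
  structure(list(settings = settings,
                 sample_sizes = as.integer(sample_sizes),
                 methods = methods,
                 replicates = as.integer(replicates),
                 val_n = as.integer(val_n),
                 base_seed = as.integer(base_seed)),
            class = "ite_study_config")
}

setting_label <- function(main_effect, hte) {
  paste0(if (main_effect) "main" else "null",
         "_", if (hte) "hte" else "hom")
}

#' Run the factorial simulation study
#'
#' For every (setting, sample size, replicate): simulate a development
#' and a validation set from the same generating mechanism, fit each
#' configured method on the development data (cross-validated penalty
#' selection where applicable), predict \eqn{\hat\delta} on the
#' validation set, and score against the known \eqn{\delta}.  All
#' methods within a replicate share the same pair of datasets.
#' Deterministic given \code{base_seed}; individual fit failures are
#' recorded, not fatal.
#'
#' @param config an \code{ite_study_config}.
#' @param verbose print per-cell progress?
#' @return An \code{ite_study_results} list with \code{records} (long
#'   data.frame: setting, n, method, replicate, rmspe, q90_delta,
#'   q90_risk, converged) and \code{failures}.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ite_study_config"))
  records <- list()
  failures <- character(0)
  cell_id <- 0L

  for (s in seq_len(nrow(config$settings))) {
    me <- config$settings$main_effect[s]
    ht <- config$settings$hte[s]
    lab <- setting_label(me, ht)
    for (n in config$sample_sizes) {
      cell_id <- cell_id + 1L
      if (verbose) message("cell ", lab, " n=", n)
      scenario <- make_scenario(me, ht, dev_n = n, val_n = config$val_n,
                                seed = config$base_seed)
      for (r in seq_len(config$replicates)) {
        seed_dev <- derive_seed(config$base_seed, 1000L * cell_id + 2L * r)
        seed_val <- derive_seed(config$base_seed, 1000L * cell_id + 2L * r + 1L)
        dev <- simulate_trial(scenario, "development", seed = seed_dev)
        val <- simulate_trial(scenario, "validation", seed = seed_val)
        mu_val <- ifelse(val$a == 1, val$mu1, val$mu0)
        for (key in config$methods) {
          fit <- tryCatch(fit_method(key, dev, seed = seed_dev),
                          error = function(e) e)
          if (inherits(fit, "error")) {
            failures <- c(failures, sprintf("%s n=%d rep=%d %s: %s",
                                            lab, n, r, key,
                                            conditionMessage(fit)))
            next
          }
          pred <- predict_risks(fit, val$X)
          p_assigned <- assigned_arm_risk(pred, val$a)
          converged <- if (inherits(fit, "ite_fit_pair")) {
            fit$control$convergence$converged && fit$treated$convergence$converged
          } else {
            isTRUE(fit$convergence$converged)
          }
          records[[length(records) + 1]] <- data.frame(
            setting = lab, main_effect = me, hte = ht,
            n = n, method = key, replicate = r,
            rmspe = rmspe(pred$delta_hat, val$delta_true),
            q90_delta = q90_abs_error(pred$delta_hat, val$delta_true),
            q90_risk = q90_abs_error(p_assigned, mu_val),
            converged = converged
          )
        }
      }
    }
  }
  structure(list(records = do.call(rbind, records), failures = failures,
                 config = config),
            class = "ite_study_results")
}

#' @export
print.ite_study_results <- function(x, ...) {
  cat("Simulation study:", nrow(x$records), "records,",
      length(x$failures), "fit failures\n")
  invisible(x)
}

#' Aggregate study results per cell
#'
#' Means and Monte-Carlo standard errors (sample SD across replicates /
#' sqrt(replicates)) per (setting, n, method).  With a single replicate
#' the SE is reported as \code{NA}.
#'
#' @param results an \code{ite_study_results} (or its \code{records}
#'   data.frame).
#' @param metric which metric to aggregate (default \code{"rmspe"}).
#' @return Data.frame with \code{setting}, \code{n}, \code{method},
#'   \code{mean}, \code{se}, \code{replicates}.
#' @export
aggregate_study <- function(results, metric = "rmspe") {
  rec <- if (inherits(results, "ite_study_results")) results$records else results
  stopifnot(metric %in% names(rec))
  cells <- split(rec, interaction(rec$setting, rec$n, rec$method, drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(d) {
    v <- d[[metric]]
    data.frame(setting = d$setting[1], main_effect = d$main_effect[1],
               hte = d$hte[1], n = d$n[1], method = d$method[1],
               mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               replicates = length(v))
  }))
  rownames(out) <- NULL
  out[order(out$setting, out$n, out$method), ]
}

#' Summary panel of mean rMSPE by method and setting
#'
#' One panel per factorial setting; methods on the x axis, mean rMSPE
#' with +/- 2 SE error bars, one line per development sample size.
#'
#' @param aggregates output of \code{\link{aggregate_study}}.
#' @param file optional path; when given the plot is saved there.
#' @return A ggplot object (invisibly when saved to file).
#' @export
plot_rmspe_summary <- function(aggregates, file = NULL) {
  if (nrow(aggregates) == 0 || length(unique(aggregates$method)) == 0) {
    stop("no aggregated results to plot", call. = FALSE)
  }
  agg <- aggregates
  agg$method <- factor(agg$method, levels = study_methods())
  agg$n <- factor(agg$n)
  gg <- ggplot2::ggplot(
    agg,
    ggplot2::aes(x = method, y = mean,
                 color = n, group = n)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean - 2 * se,
                   ymax = mean + 2 * se),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~setting) +
    ggplot2::labs(x = NULL, y = "mean rMSPE (risk difference)",
                  color = "dev n") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 9, height = 6)
    return(invisible(gg))
  }
  gg
}

#' Calibration plot (predicted vs true, equal-size bins)
#'
#' @param tab output of \code{\link{calibration_table}}.
#' @param file optional output path.
#' @return A ggplot object.
#' @export
plot_calibration <- function(tab, file = NULL) {
  gg <- ggplot2::ggplot(tab, ggplot2::aes(x = mean_pred,
                                          y = mean_true)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_true - se_true,
                   ymax = mean_true + se_true), width = 0) +
    ggplot2::labs(x = "mean predicted", y = "mean true/observed") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 5, height = 5)
    return(invisible(gg))
  }
  gg
}

#' Treatment-effect calibration plot by quantile group
#'
#' @param tab output of \code{\link{te_calibration}}.
#' @param file optional output path.
#' @return A ggplot object.
#' @export
plot_te_calibration <- function(tab, file = NULL) {
  gg <- ggplot2::ggplot(tab, ggplot2::aes(x = mean_delta_hat,
                                          y = observed_effect)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = observed_effect - se,
                   ymax = observed_effect + se), width = 0) +
    ggplot2::labs(x = "mean predicted treatment effect",
                  y = "observed treatment effect") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 5, height = 5)
    return(invisible(gg))
  }
  gg
}
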