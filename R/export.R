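#' Export a model fit as JSON summaries plus a draws table
#'
#' Writes a machine-readable account of a fitted model: posterior mean,
#' SD and 95% highest-density interval per reported parameter, the
#' convergence report (per-parameter split R-hat), and the sampler
#' settings. Optionally the full draw array is written alongside as a
#' CSV (one column per parameter, one row per retained draw, chains
#' stacked).
#'
#' @param fit A `glmm_fit` or `mixture_fit`.
#' @param path Output JSON path.
#' @param draws_path Optional CSV path for the full draw array.
#' @return `path`, invisibly.
#' @export
export_fit <- function(fit, path, draws_path = NULL) {
  if (inherits(fit, "glmm_fit")) {
    cm <- cell_mean_draws(fit)
    summ <- purrr::map_dfr(colnames(cm), function(cl) {
      s <- posterior_summary(cm[, cl])
      tibble::tibble(parameter = paste0("cell_mean[", cl, "]"),
                     mean = s$mean, sd = stats::sd(cm[, cl]),
                     lower = s$lower, upper = s$upper)
    })
    flat <- matrix(fit$draws, ncol = dim(fit$draws)[3],
                   dimnames = list(NULL, dimnames(fit$draws)[[3]]))
  } else if (inherits(fit, "mixture_fit")) {
    s0 <- summary(fit)
    summ <- tibble::tibble(parameter = paste0(s0$parameter, "[", s0$cell, "]"),
                           mean = s0$mean, sd = NA_real_,
                           lower = s0$lower, upper = s0$upper)
    flat <- matrix(fit$draws, ncol = dim(fit$draws)[3],
                   dimnames = list(NULL, dimnames(fit$draws)[[3]]))
  } else {
    stop("`fit` must be a glmm_fit or mixture_fit", call. = FALSE)
  }
  jsonlite::write_json(
    list(summary = summ,
         convergence = list(pass = fit$convergence$pass,
                            threshold = fit$convergence$threshold,
                            rhat = fit$convergence$table),
         settings = fit$settings),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(draws_path)) {
    readr::write_csv(tibble::as_tibble(flat), draws_path)
  }
  invisible(path)
}
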