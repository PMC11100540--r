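logit_target_ <- function(p) log(p / ((1 - p) / 3))

#' Default group-level generating parameters per experiment
#'
#' Reference cohorts for recovery studies, chosen to mirror the
#' qualitative result structure of the designs: accuracy falls with
#' total load; in E3-style cohorts proactive facilitation/interference
#' are absent at set size 2 and grow with set size; in E4 cohorts LTM
#' intrusions occur on old-mismatch pairs only at set size 4 while the
#' imaginary-colour baseline stays at its floor. Non-target choice
#' categories share the residual probability equally.
#'
#' @param experiment_id `"E1"`, `"E2"`, `"E3"` or `"E4"`.
#' @return A [group_params()] object.
#' @export
default_group_params <- function(experiment_id) {
  experiment_id <- match.arg(experiment_id, experiment_ids)
  if (experiment_id %in% c("E1", "E2")) {
    cond <- e12_conditions(experiment_id)
    acc <- c(`2_0` = 0.95, `4_0` = 0.75, `6_0` = 0.62,
             `0_2` = 0.92, `2_2` = 0.85, `4_2` = 0.72)
    key <- paste(cond$wm_load, cond$ltm_load, sep = "_")
    lg <- dplyr::bind_cols(cond, tibble::tibble(
      l_target = logit_target_(unname(acc[key])),
      l_intrusion = 0, l_ltm_lure = 0))
    group_params(choice_logits = lg, sigma = c(l_target = 0.5))
  } else if (experiment_id == "E3") {
    grid <- tidyr::expand_grid(set_size = 2:4,
                               pair_type = c("new_new", "old_match",
                                             "old_mismatch"))
    acc <- c(0.90, 0.90, 0.90,   # SS2: no PF, no PI
             0.80, 0.84, 0.72,   # SS3: emerging effects
             0.68, 0.78, 0.52)   # SS4: clear PF and PI
    lg <- dplyr::bind_cols(grid, tibble::tibble(
      l_target = logit_target_(acc), l_intrusion = 0, l_ltm_lure = 0))
    group_params(choice_logits = lg, sigma = c(l_target = 0.5))
  } else {
    grid <- tidyr::expand_grid(set_size = 2:4,
                               pair_type = c("new_new", "old_match",
                                             "old_mismatch"))
    w <- tibble::tribble(
      ~p_m, ~p_swap, ~p_ltm, ~p_g,
      0.92, 0.02, 0.01, 0.05,  # ss2 new_new
      0.92, 0.02, 0.01, 0.05,  # ss2 old_match
      0.92, 0.02, 0.01, 0.05,  # ss2 old_mismatch
      0.82, 0.05, 0.01, 0.12,  # ss3 new_new
      0.85, 0.05, 0.01, 0.09,  # ss3 old_match
      0.80, 0.05, 0.02, 0.13,  # ss3 old_mismatch
      0.66, 0.08, 0.02, 0.24,  # ss4 new_new
      0.76, 0.07, 0.02, 0.15,  # ss4 old_match
      0.58, 0.08, 0.15, 0.19   # ss4 old_mismatch: true LTM intrusions
    )
    lg <- dplyr::bind_cols(grid, tibble::tibble(
      l_m = log(w$p_m / w$p_g), l_swap = log(w$p_swap / w$p_g),
      l_ltm = log(w$p_ltm / w$p_g)))
    group_params(repro_logits = lg,
                 log_kappa = tibble::tibble(set_size = 2:4,
                                            log_kappa = log(c(16, 13, 10))),
                 sigma = c(l_m = 0.4, log_kappa = 0.2))
  }
}

#' Build a recovery-study configuration
#'
#' A config fully determines a recovery run: the experiment simulated,
#' cohort size, generating group parameters, one master seed (from
#' which design, data and sampler seeds are derived), and MCMC
#' settings. Configs can also be read from YAML via
#' [read_run_config()].
#'
#' @param experiment `"E1"`-`"E4"`.
#' @param n_participants Cohort size.
#' @param seed Master seed.
#' @param chains,warmup,samples MCMC settings for the fitting stage.
#' @param group Generating [group_params()]; defaults to
#'   [default_group_params()].
#' @param out_dir Optional directory: simulated data (CSV) and the
#'   report (JSON) are written there, file names carrying a hash of
#'   the config.
#' @return List of class `run_config`.
#' @export
recovery_config <- function(experiment = "E3", n_participants = 30,
                            seed = 1L, chains = 2, warmup = 500,
                            samples = 750, group = NULL, out_dir = NULL) {
  experiment <- match.arg(experiment, experiment_ids)
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed), chains = as.integer(chains),
                 warmup = as.integer(warmup), samples = as.integer(samples),
                 group = group %||% default_group_params(experiment),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a recovery configuration from YAML
#'
#' Scalar fields (`experiment`, `n_participants`, `seed`, `chains`,
#' `warmup`, `samples`, `out_dir`) are read from the file; generating
#' parameters default per experiment.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(recovery_config, y[intersect(names(y),
                                       names(formals(recovery_config)))])
}

#' Run an end-to-end parameter-recovery study
#'
#' Simulates a cohort at known group parameters, fits the matching
#' hierarchical model (binomial logistic for E1-E3, von Mises mixture
#' for E4), and reports per-parameter recovery (true value, posterior
#' mean, bias, 95% HDI coverage) together with the designs' focal
#' Bayes factors: LTM-load effects at each WM load (E1/E2), proactive
#' facilitation/interference at each set size (E3), and the
#' LTM-intrusion contrast at each set size (E4).
#'
#' @param config A `run_config` from [recovery_config()], or a path to
#'   a YAML config.
#' @return List of class `recovery_report`: `config`, `recovery`
#'   (tibble), `bfs` (tibble), `convergence`, `data` (the simulated
#'   cohort).
#' @export
run_recovery_study <- function(config = recovery_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_population(config$experiment, config$group,
                                config$n_participants,
                                seed = child_seed_(config$seed, "data"))
  fit_seed <- child_seed_(config$seed, "sampler")
  if (config$experiment == "E4") {
    fit <- fit_mixture_hierarchical(cohort$data, chains = config$chains,
                                    warmup = config$warmup,
                                    samples = config$samples,
                                    seed = fit_seed)
    rec <- mixture_recovery_(fit, config$group)
    bfs <- purrr::map_dfr(fit$ss_levels, function(ss) {
      ct <- ltm_intrusion_test(fit, ss)
      bf <- directed_bf(ct$draws, "positive", parameter = ct$label)
      tibble::tibble(contrast = ct$label, type = "directed",
                     bf10 = bf$bf10, classification = classify_bf(bf))
    })
    conv <- fit$convergence
  } else {
    cells <- aggregate_cells(cohort$data)
    fit <- fit_binomial_glmm(cells, chains = config$chains,
                             warmup = config$warmup,
                             samples = config$samples, seed = fit_seed)
    rec <- glmm_recovery_(fit, cohort, config$group)
    bfs <- focal_choice_bfs_(fit, config$experiment)
    conv <- fit$convergence
  }
  report <- structure(list(config = config, recovery = rec, bfs = bfs,
                           convergence = conv, data = cohort$data),
                      class = "recovery_report")
  if (!is.null(config$out_dir)) write_recovery_report_(report)
  report
}

glmm_recovery_ <- function(fit, cohort, group) {
  cm <- cell_mean_draws(fit)
  acc_draws <- stats::plogis(cm)
  lg <- group$choice_logits
  keys <- fit$spec$keys
  truth_key <- do.call(paste, c(lg[keys], sep = "\r"))
  cell_key <- do.call(paste, c(fit$spec$cell_table[keys], sep = "\r"))
  p_true <- softmax4_(lg$l_target, lg$l_intrusion,
                      lg$l_ltm_lure)[match(cell_key, truth_key), 1]
  purrr::map_dfr(seq_along(cell_key), function(ci) {
    s <- posterior_summary(acc_draws[, ci])
    tibble::tibble(parameter = "p_target",
                   cell = fit$spec$cell_labels[ci],
                   true = p_true[ci], estimate = s$mean,
                   bias = s$mean - p_true[ci],
                   lower = s$lower, upper = s$upper,
                   covered = p_true[ci] >= s$lower & p_true[ci] <= s$upper)
  })
}

mixture_recovery_ <- function(fit, group) {
  lg <- group$repro_logits
  p_true <- softmax4_(lg$l_m, lg$l_swap, lg$l_ltm)
  truth_key <- paste0("ss", lg$set_size, ",", lg$pair_type)
  labs <- cell_label_(fit$cells)
  comp <- c("p_m", "p_swap", "p_ltm", "p_g")
  rows <- purrr::map_dfr(seq_along(comp), function(j) {
    purrr::map_dfr(seq_along(labs), function(ci) {
      tv <- p_true[match(labs[ci], truth_key), j]
      s <- posterior_summary(fit$prob[[comp[j]]][, ci])
      tibble::tibble(parameter = comp[j], cell = labs[ci], true = tv,
                     estimate = s$mean, bias = s$mean - tv,
                     lower = s$lower, upper = s$upper,
                     covered = tv >= s$lower & tv <= s$upper)
    })
  })
  kt <- group$log_kappa
  krows <- purrr::map_dfr(seq_along(fit$ss_levels), function(si) {
    ss <- fit$ss_levels[si]
    tv <- exp(kt$log_kappa[match(ss, kt$set_size)])
    s <- posterior_summary(fit$prob$kappa[, si])
    tibble::tibble(parameter = "kappa", cell = paste0("ss", ss), true = tv,
                   estimate = s$mean, bias = s$mean - tv,
                   lower = s$lower, upper = s$upper,
                   covered = tv >= s$lower & tv <= s$upper)
  })
  dplyr::bind_rows(rows, krows)
}

focal_choice_bfs_ <- function(fit, experiment) {
  ct <- fit$spec$cell_table
  if (all(c("wm_load", "ltm_load") %in% fit$spec$keys)) {
    wm_levels <- intersect(unique(ct$wm_load[ct$ltm_load == 0]),
                           unique(ct$wm_load[ct$ltm_load == 2]))
    purrr::map_dfr(sort(wm_levels), function(wm) {
      lab0 <- fit$spec$cell_labels[ct$wm_load == wm & ct$ltm_load == 0]
      lab2 <- fit$spec$cell_labels[ct$wm_load == wm & ct$ltm_load == 2]
      cc <- contrast(fit, stats::setNames(c(1, -1), c(lab2, lab0)),
                     label = sprintf("LTM load 0 vs 2 at WM load %d", wm))
      bf <- bf_contrast(cc, "savage_dickey")
      tibble::tibble(contrast = cc$label, type = "savage_dickey",
                     bf10 = bf$bf10, classification = classify_bf(bf))
    })
  } else {
    purrr::map_dfr(sort(unique(ct$set_size)), function(ss) {
      pp <- pf_pi_contrasts(fit, ss)
      purrr::map_dfr(pp, function(cc) {
        bf <- bf_contrast(cc, "savage_dickey")
        tibble::tibble(contrast = cc$label, type = "savage_dickey",
                       bf10 = bf$bf10, classification = classify_bf(bf))
      })
    })
  }
}

write_recovery_report_ <- function(report) {
  dir.create(report$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- substr(rlang::hash(report$config[setdiff(names(report$config),
                                                   "out_dir")]), 1, 8)
  write_trial_data(report$data,
                   file.path(report$config$out_dir,
                             paste0("cohort_", hash, ".csv")))
  jsonlite::write_json(
    list(config = report$config[c("experiment", "n_participants", "seed",
                                  "chains", "warmup", "samples")],
         config_hash = hash,
         recovery = report$recovery, bfs = report$bfs,
         max_rhat = max(report$convergence$table$rhat)),
    file.path(report$config$out_dir, paste0("recovery_", hash, ".json")),
    auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery study: %s, %d participants, seed %d\n",
              x$config$experiment, x$config$n_participants, x$config$seed))
  cat(sprintf("  max R-hat: %.4f | mean |bias|: %.4f | coverage: %.0f%%\n",
              max(x$convergence$table$rhat),
              mean(abs(x$recovery$bias)),
              100 * mean(x$recovery$covered)))
  print(x$bfs)
  invisible(x)
}
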