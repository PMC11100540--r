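#' Construct choice propensities for the 4AFC simulator
#'
#' A table of per-condition response-category probabilities over
#' `{target, within_trial_intrusion, ltm_lure, new}`. Conditions are
#' identified by whichever design columns are supplied (`wm_load` +
#' `ltm_load` for E1/E2, `set_size` + `pair_type` for E3); rows are
#' matched to schedule pairs by those columns. A table with no
#' condition columns applies to every pair.
#'
#' @param ... Design columns (vectors) followed by the four probability
#'   columns `p_target`, `p_intrusion`, `p_ltm_lure`, `p_new`.
#' @return A tibble validated so each probability vector sums to 1.
#' @export
choice_propensities <- function(...) {
  tab <- tibble::tibble(...)
  pcols <- c("p_target", "p_intrusion", "p_ltm_lure", "p_new")
  if (!all(pcols %in% names(tab))) {
    stop("propensity table needs columns ", paste(pcols, collapse = ", "),
         call. = FALSE)
  }
  p <- as.matrix(tab[pcols])
  if (any(p < 0 | p > 1)) stop("propensities must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(p) - 1) > 1e-12)) {
    stop("each propensity vector must sum to 1", call. = FALSE)
  }
  tab
}

response_categories <- c("target", "within_trial_intrusion", "ltm_lure", "new")

join_params_ <- function(schedule, tab) {
  keys <- intersect(c("wm_load", "ltm_load", "set_size", "pair_type"), names(tab))
  if (length(keys) == 0) {
    dplyr::bind_cols(schedule, tab[rep(1L, nrow(schedule)), , drop = FALSE])
  } else {
    out <- dplyr::left_join(schedule, tab, by = keys)
    if (anyNA(out[[setdiff(names(tab), keys)[1]]])) {
      stop("some schedule conditions have no matching parameter row", call. = FALSE)
    }
    out
  }
}

#' Simulate 4AFC choice responses for a schedule
#'
#' Every pair presented in a WM trial is tested once; the response
#' category is drawn from the participant's propensities for that
#' pair's condition. This is the generative mirror of the aggregated
#' logistic model: with equal propensities accuracy converges to the
#' 4AFC chance level of 25%.
#'
#' @param schedule A `trial_schedule` from [build_design()].
#' @param params Either a propensity table from [choice_propensities()]
#'   or a list with element `choice` holding one.
#' @param seed Integer seed.
#' @return A `ChoiceDataset` tibble: the schedule plus a
#'   `response_category` column (one row per retrieval).
#' @export
simulate_choice_responses <- function(schedule, params, seed = 1L) {
  tab <- if (is.data.frame(params)) params else params$choice
  tab <- choice_propensities(!!!tab)
  aug <- join_params_(tibble::as_tibble(schedule), tab)
  p <- as.matrix(aug[c("p_target", "p_intrusion", "p_ltm_lure", "p_new")])
  with_seed_(seed, {
    u <- stats::runif(nrow(aug))
    cum <- t(apply(p, 1, cumsum))
    idx <- 1L + rowSums(u > cum + 1e-15)
    idx <- pmin(idx, 4L)
  })
  aug$response_category <- response_categories[idx]
  aug$response_deg <- NA_real_
  dplyr::select(aug, -dplyr::all_of(c("p_target", "p_intrusion",
                                      "p_ltm_lure", "p_new")))
}

#' Construct mixture parameters for the reproduction simulator
#'
#' Per-condition mixture weights over the four response sources (target
#' retrieval `p_m`, swap `p_swap`, LTM intrusion `p_ltm`, guessing
#' `p_g`) plus a `kappa` table per set size. Mirrors the parameters the
#' hierarchical mixture model estimates.
#'
#' @param weights Tibble with optional design columns (`set_size`,
#'   `pair_type`) and columns `p_m`, `p_swap`, `p_ltm`, `p_g` summing
#'   to 1 per row.
#' @param kappa Tibble with columns `set_size`, `kappa`, or a single
#'   number applied to all set sizes.
#' @return List of class `mixture_params`.
#' @export
mixture_params <- function(weights, kappa) {
  pcols <- c("p_m", "p_swap", "p_ltm", "p_g")
  if (!all(pcols %in% names(weights))) {
    stop("weights need columns ", paste(pcols, collapse = ", "), call. = FALSE)
  }
  p <- as.matrix(weights[pcols])
  if (any(p < 0 | p > 1) || any(abs(rowSums(p) - 1) > 1e-9)) {
    stop("mixture weights must be probabilities summing to 1", call. = FALSE)
  }
  if (is.numeric(kappa) && !is.data.frame(kappa)) {
    kappa <- tibble::tibble(set_size = 2:4, kappa = kappa)
  }
  if (any(kappa$kappa < 0)) stop("kappa must be nonnegative", call. = FALSE)
  structure(list(weights = tibble::as_tibble(weights),
                 kappa = tibble::as_tibble(kappa)),
            class = "mixture_params")
}

#' Simulate continuous colour-reproduction responses
#'
#' For each tested pair a response source is drawn from the mixture
#' weights of its condition, then a colour: von Mises around the target
#' (`p_m`), around one of the trial's other items chosen uniformly
#' (`p_swap`), around the pair's LTM colour (`p_ltm`), or uniform on
#' the wheel (`p_g`). Precision `kappa` is shared across the von Mises
#' components and varies with set size.
#'
#' @param schedule An E4 `trial_schedule` with `ltm_color_deg` complete
#'   (see [assign_imaginary_ltm_colors()]).
#' @param params A `mixture_params` object, or a list with element
#'   `repro` holding one.
#' @param seed Integer seed.
#' @return A `ReproDataset` tibble: the schedule plus `response_deg`
#'   and the latent `component` that generated each response.
#' @export
simulate_repro_responses <- function(schedule, params, seed = 1L) {
  mp <- if (inherits(params, "mixture_params")) params else params$repro
  stopifnot(inherits(mp, "mixture_params"))
  df <- tibble::as_tibble(schedule)
  if (anyNA(df$ltm_color_deg)) {
    stop("every pair needs an `ltm_color_deg`; run assign_imaginary_ltm_colors()",
         call. = FALSE)
  }
  aug <- join_params_(df, mp$weights)
  aug <- dplyr::left_join(aug, mp$kappa, by = "set_size")
  if (anyNA(aug$kappa)) stop("kappa missing for some set size", call. = FALSE)
  n <- nrow(aug)
  with_seed_(seed, {
    w <- as.matrix(aug[c("p_m", "p_swap", "p_ltm", "p_g")])
    u <- stats::runif(n)
    cum <- t(apply(w, 1, cumsum))
    comp <- c("target", "swap", "ltm", "guess")[pmin(1L + rowSums(u > cum + 1e-15), 4L)]
    # swap centres: one of the trial's other items, uniformly
    centre <- aug$target_color_deg
    swap_idx <- which(comp == "swap")
    if (length(swap_idx)) {
      key <- paste(aug$block, aug$trial)
      centre[swap_idx] <- vapply(swap_idx, function(i) {
        others <- setdiff(which(key == key[i]), i)
        # index into `others` to avoid sample()'s scalar expansion
        aug$target_color_deg[others[sample.int(length(others), 1)]]
      }, numeric(1))
    }
    centre[comp == "ltm"] <- aug$ltm_color_deg[comp == "ltm"]
    kap <- aug$kappa
    kap[comp == "guess"] <- 0
    aug$response_deg <- vm_sample(n, mu = centre, kappa = kap)
  })
  aug$component <- comp
  aug$response_category <- NA_character_
  dplyr::select(aug, -dplyr::all_of(c("p_m", "p_swap", "p_ltm", "p_g", "kappa")))
}

#' Group-level parameters for a simulated cohort
#'
#' Group means and between-participant dispersions on the unconstrained
#' scale: category/component logits (reference category fixed at 0) and
#' log-kappa. Participant parameters are drawn as independent normal
#' deviations around the group means, matching the hierarchy assumed by
#' the fitting modules.
#'
#' @param choice_logits For choice cohorts: tibble with condition
#'   columns and logits `l_target`, `l_intrusion`, `l_ltm_lure`
#'   (reference `new` = 0).
#' @param repro_logits For reproduction cohorts: tibble with condition
#'   columns and logits `l_m`, `l_swap`, `l_ltm` (reference guess = 0).
#' @param log_kappa Tibble with `set_size`, `log_kappa` (or scalar).
#' @param sigma Named numeric vector of between-participant SDs on the
#'   unconstrained scale; names among `l_target`, `l_intrusion`,
#'   `l_ltm_lure`, `l_m`, `l_swap`, `l_ltm`, `log_kappa`. Zero SDs mean
#'   all participants share the group values.
#' @return List of class `group_params`.
#' @export
group_params <- function(choice_logits = NULL, repro_logits = NULL,
                         log_kappa = NULL, sigma = numeric()) {
  if (any(sigma < 0)) stop("dispersions must be nonnegative", call. = FALSE)
  if (!is.null(log_kappa) && is.numeric(log_kappa) && !is.data.frame(log_kappa)) {
    log_kappa <- tibble::tibble(set_size = 2:4, log_kappa = log_kappa)
  }
  structure(list(choice_logits = choice_logits, repro_logits = repro_logits,
                 log_kappa = log_kappa, sigma = sigma),
            class = "group_params")
}

softmax4_ <- function(l1, l2, l3) {
  m <- pmax(l1, l2, l3, 0)
  e1 <- exp(l1 - m); e2 <- exp(l2 - m); e3 <- exp(l3 - m); e4 <- exp(-m)
  s <- e1 + e2 + e3 + e4
  cbind(e1 / s, e2 / s, e3 / s, e4 / s)
}

#' Simulate a cohort of participants with known ground truth
#'
#' Draws participant-level parameters from the group distribution, a
#' fresh randomized schedule per participant, and trial-level responses
#' from the generative model. The returned ground truth supports
#' parameter-recovery checks of the fitting modules.
#'
#' @param experiment_id `"E1"`, `"E2"`, `"E3"` (choice cohorts) or
#'   `"E4"` (reproduction cohort).
#' @param group A `group_params` object.
#' @param n_participants Cohort size.
#' @param seed Integer seed; fixes schedules, participant parameters
#'   and responses.
#' @return List with `data` (all participants' trial-level rows, with a
#'   `participant` column), `truth` (per-participant parameter table on
#'   both the unconstrained and probability scales), and `group`.
#' @export
simulate_population <- function(experiment_id, group, n_participants,
                                seed = 1L) {
  experiment_id <- match.arg(experiment_id, experiment_ids)
  stopifnot(inherits(group, "group_params"), n_participants >= 1)
  is_repro <- experiment_id == "E4"
  lg <- if (is_repro) group$repro_logits else group$choice_logits
  if (is.null(lg)) stop("group parameters lack the logits for ", experiment_id,
                        call. = FALSE)
  lcols <- if (is_repro) c("l_m", "l_swap", "l_ltm") else
    c("l_target", "l_intrusion", "l_ltm_lure")
  keys <- intersect(c("wm_load", "ltm_load", "set_size", "pair_type"), names(lg))
  sig <- function(nm) unname(group$sigma[nm] %|na|% 0)

  datasets <- vector("list", n_participants)
  truths <- vector("list", n_participants)
  for (s in seq_len(n_participants)) {
    pseed <- child_seed_(seed, paste0("participant", s))
    sch <- build_design(experiment_id, seed = child_seed_(pseed, "design"))
    dev <- with_seed_(child_seed_(pseed, "population"), {
      stats::setNames(stats::rnorm(length(lcols) + 1, 0,
                                   c(vapply(lcols, sig, 0), sig("log_kappa"))),
                      c(lcols, "log_kappa"))
    })
    plg <- lg
    for (cc in lcols) plg[[cc]] <- plg[[cc]] + dev[[cc]]
    pr <- softmax4_(plg[[lcols[1]]], plg[[lcols[2]]], plg[[lcols[3]]])
    if (is_repro) {
      kt <- group$log_kappa
      if (is.null(kt)) stop("repro cohorts need `log_kappa`", call. = FALSE)
      kt$kappa <- exp(kt$log_kappa + dev[["log_kappa"]])
      w <- dplyr::bind_cols(plg[keys],
                            tibble::tibble(p_m = pr[, 1], p_swap = pr[, 2],
                                           p_ltm = pr[, 3], p_g = pr[, 4]))
      mp <- mixture_params(w, kt[c("set_size", "kappa")])
      sch <- assign_imaginary_ltm_colors(sch, seed = child_seed_(pseed, "imaginary"))
      dat <- simulate_repro_responses(sch, mp, seed = child_seed_(pseed, "data"))
      truth <- dplyr::mutate(dplyr::left_join(w, kt[c("set_size", "kappa")],
                                              by = "set_size"),
                             participant = s, .before = 1)
    } else {
      tab <- dplyr::bind_cols(plg[keys],
                              tibble::tibble(p_target = pr[, 1],
                                             p_intrusion = pr[, 2],
                                             p_ltm_lure = pr[, 3],
                                             p_new = pr[, 4]))
      dat <- simulate_choice_responses(sch, tab, seed = child_seed_(pseed, "data"))
      truth <- dplyr::mutate(tab, participant = s, .before = 1)
    }
    dat$participant <- s
    datasets[[s]] <- dat
    truths[[s]] <- truth
  }
  list(data = dplyr::relocate(dplyr::bind_rows(datasets), participant),
       truth = dplyr::bind_rows(truths),
       group = group)
}

`%|na|%` <- function(x, y) {
  if (length(x) == 0 || is.na(x)) y else x
}
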