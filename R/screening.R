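#' Chance performance level of a task
#'
#' Reference levels used for screening and as sanity anchors: 25%
#' accuracy on a four-alternative forced choice, 1/3 on a
#' three-alternative forced choice, and a 90-degree mean absolute
#' recall error for continuous reproduction on the colour wheel.
#'
#' @param task One of `"four_afc"`, `"three_afc"`,
#'   `"continuous_reproduction"`.
#' @return The chance accuracy (AFC tasks) or chance mean absolute
#'   error in degrees (continuous reproduction).
#' @export
chance_level <- function(task = c("four_afc", "three_afc",
                                  "continuous_reproduction")) {
  task <- match.arg(task)
  switch(task,
         four_afc = 0.25,
         three_afc = 1 / 3,
         continuous_reproduction = 90)
}

#' Screen participants before model fitting
#'
#' Applies the exclusion rules used in the study designs:
#'
#' * `below_chance_delayed_test` - delayed-memory-test accuracy
#'   strictly below the task's chance level.
#' * `two_sd_below_mean` - overall accuracy strictly more than 2
#'   standard deviations below the cohort mean (a participant exactly
#'   at `mean - 2 SD` is kept).
#' * `at_chance_learning_error` - learning-phase mean recall error
#'   within `learning_band` degrees of the 90-degree chance level
#'   (continuous-reproduction cohorts).
#'
#' Rules are deterministic given the summary table. The
#' `two_sd_below_mean` rule is iterated to a fixed point (threshold
#' recomputed on the survivors until no one else is flagged), which
#' makes screening idempotent: re-screening an already-screened cohort
#' excludes no one further.
#'
#' @param summaries Tibble with column `participant` and, per rule,
#'   `delayed_accuracy`, `overall_accuracy`, `learning_error_deg`.
#' @param rules Character vector of rule ids to apply (default: all
#'   whose columns are present).
#' @param task Delayed-test task for the chance level.
#' @param learning_band Half-width (degrees) of the "at chance" band
#'   around 90 degrees.
#' @return List with `kept` (summary rows retained) and `excluded`
#'   (rows with a `reason` column; one row per participant and rule).
#' @export
screen_participants <- function(summaries,
                                rules = c("below_chance_delayed_test",
                                          "two_sd_below_mean",
                                          "at_chance_learning_error"),
                                task = "four_afc",
                                learning_band = 5) {
  rules <- match.arg(rules, several.ok = TRUE)
  needed <- c(below_chance_delayed_test = "delayed_accuracy",
              two_sd_below_mean = "overall_accuracy",
              at_chance_learning_error = "learning_error_deg")
  rules <- rules[needed[rules] %in% names(summaries)]
  if (!"participant" %in% names(summaries)) {
    stop("summaries need a `participant` column", call. = FALSE)
  }
  excluded <- list()
  if ("below_chance_delayed_test" %in% rules) {
    bad <- summaries$delayed_accuracy < chance_level(task)
    excluded$chance <- summaries[bad, ] |>
      dplyr::mutate(reason = "below_chance_delayed_test")
  }
  if ("two_sd_below_mean" %in% rules) {
    # iterated to a fixed point so that screening is idempotent: after
    # removal, the survivors' mean and SD flag no further participant
    keep <- rep(TRUE, nrow(summaries))
    repeat {
      mu <- mean(summaries$overall_accuracy[keep])
      sd_ <- stats::sd(summaries$overall_accuracy[keep])
      bad <- keep & summaries$overall_accuracy < mu - 2 * sd_
      if (!any(bad)) break
      keep <- keep & !bad
    }
    excluded$sd <- summaries[!keep, ] |>
      dplyr::mutate(reason = "two_sd_below_mean")
  }
  if ("at_chance_learning_error" %in% rules) {
    bad <- abs(summaries$learning_error_deg -
                 chance_level("continuous_reproduction")) <= learning_band
    excluded$learning <- summaries[bad, ] |>
      dplyr::mutate(reason = "at_chance_learning_error")
  }
  exc <- dplyr::bind_rows(excluded)
  kept <- summaries[!summaries$participant %in% exc$participant, ]
  list(kept = kept, excluded = exc)
}

#' Within-subject confidence intervals (Cousineau-Morey)
#'
#' Condition-mean confidence intervals after removing between-subject
#' level differences: each participant's condition means are centred on
#' their own mean (plus the grand mean), the centred values are
#' rescaled by the Morey factor `sqrt(C / (C - 1))` for `C` conditions,
#' and per-condition intervals use the t quantile with `n - 1` degrees
#' of freedom. A participant-specific constant added to all of that
#' participant's means leaves the intervals unchanged.
#'
#' @param data Tibble in long format.
#' @param participant,condition,value Column names (strings).
#' @param level Confidence level.
#' @return Tibble with per-condition `mean`, `se`, `lower`, `upper`.
#' @export
within_subject_ci <- function(data, participant = "participant",
                              condition = "condition", value = "value",
                              level = 0.95) {
  df <- tibble::tibble(participant = data[[participant]],
                       condition = data[[condition]],
                       value = data[[value]])
  tab <- tidyr::pivot_wider(df, names_from = "condition",
                            values_from = "value")
  if (anyNA(tab)) stop("condition x participant table is incomplete",
                       call. = FALSE)
  n <- nrow(tab)
  cond_cols <- setdiff(names(tab), "participant")
  cc <- length(cond_cols)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (cc < 2) stop("centring is undefined with fewer than 2 conditions",
                   call. = FALSE)
  m <- as.matrix(tab[cond_cols])
  grand <- mean(m)
  centred <- m - rowMeans(m) + grand
  morey <- sqrt(cc / (cc - 1))
  rescaled <- grand + (centred - grand) * morey
  se <- unname(apply(rescaled, 2, stats::sd)) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  mns <- unname(colMeans(m))
  tibble::tibble(condition = cond_cols,
                 mean = mns,
                 se = se,
                 lower = mns - tq * se,
                 upper = mns + tq * se)
}

#' Descriptive summaries of a simulated dataset
#'
#' Per-condition accuracy (choice datasets) or mean absolute recall
#' error in degrees (reproduction datasets), with Cousineau-Morey
#' within-subject confidence intervals when the cohort has two or more
#' participants.
#'
#' @param dataset A `ChoiceDataset` or `ReproDataset` tibble following
#'   the package's CSV schema (see [write_trial_data()]).
#' @return Tibble keyed by condition with `estimate` (accuracy or mean
#'   absolute error), and CI columns when available.
#' @export
describe_dataset <- function(dataset) {
  is_repro <- "response_deg" %in% names(dataset) &&
    any(!is.na(dataset$response_deg))
  if (!is_repro && !"response_category" %in% names(dataset)) {
    stop("dataset has neither continuous nor categorical responses",
         call. = FALSE)
  }
  keys <- detect_keys_(dataset)
  if (!"participant" %in% names(dataset)) dataset$participant <- 1L
  per_part <- dataset |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant", keys)))) |>
    dplyr::summarise(
      estimate = if (is_repro) mean(abs(circ_diff(response_deg, target_color_deg)))
                 else mean(response_category == "target"),
      .groups = "drop")
  out <- per_part |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(estimate = mean(estimate), n_participants = dplyr::n(),
                     .groups = "drop")
  if (dplyr::n_distinct(per_part$participant) >= 2 && length(keys) >= 1) {
    per_part$condition <- do.call(paste,
                                  c(per_part[keys], sep = "."))
    if (dplyr::n_distinct(per_part$condition) >= 2 &&
        nrow(per_part) == dplyr::n_distinct(per_part$participant) *
          dplyr::n_distinct(per_part$condition)) {
      ci <- within_subject_ci(per_part, "participant", "condition", "estimate")
      out$condition <- do.call(paste, c(out[keys], sep = "."))
      out <- dplyr::left_join(out, ci[c("condition", "se", "lower", "upper")],
                              by = "condition")
      out$condition <- NULL
    }
  }
  out
}
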