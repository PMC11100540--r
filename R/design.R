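#' Experimental designs
#'
#' @description
#' The package simulates four paired-associate experiments probing when
#' working memory (WM) draws on episodic long-term memory (LTM):
#'
#' * **E1** - word pairs, 4AFC recognition. Six conditions crossing WM
#'   load (number of new pairs) with LTM load (number of pre-learned
#'   pairs): 2+0, 4+0, 6+0, 0+2, 2+2, 4+2. 15 trials per condition, one
#'   per block across 15 blocks (90 WM trials). Two learning phases of
#'   90 word pairs each.
#' * **E2** - E1 without the 2+2 condition (75 trials, 15 blocks of 5),
#'   so all set-size-4 trials contain only new pairings.
#' * **E3** - word pairs at set sizes 2-4 whose composition over pair
#'   types (new-new, old-mismatch, old-match) follows the seven design
#'   rows in [trial_compositions()]; 27 trials in 3 blocks of 9, after a
#'   learning phase of 54 pairs.
#' * **E4** - colour-object conjunctions with the same set-size/pair-type
#'   structure, 81 trials in 9 blocks of 9; 120 conjunctions pre-learned
#'   in groups of 10; responses are continuous reproductions on a
#'   360-colour wheel.
#'
#' @name designs
NULL

experiment_ids <- c("E1", "E2", "E3", "E4")

e12_conditions <- function(experiment_id) {
  cond <- tibble::tribble(
    ~wm_load, ~ltm_load,
    2L, 0L,
    4L, 0L,
    6L, 0L,
    0L, 2L,
    2L, 2L,
    4L, 2L
  )
  if (experiment_id == "E2") cond <- dplyr::filter(cond, !(wm_load == 2 & ltm_load == 2))
  cond
}

#' Trial compositions for the set-size by pair-type designs
#'
#' The seven admissible multisets of pair types at set sizes 2, 3 and 4
#' used by experiments E3 and E4. Each block of 9 trials contains one
#' trial per set-size-2 row, three trials of the single set-size-3 row,
#' and one trial per set-size-4 row, giving 3 trials per set size per
#' block.
#'
#' @return A list of character vectors of pair types; names encode the
#'   set size and row.
#' @export
trial_compositions <- function() {
  list(
    ss2_a = c("new_new", "old_mismatch"),
    ss2_b = c("old_mismatch", "old_match"),
    ss2_c = c("new_new", "old_match"),
    ss3_a = c("new_new", "old_mismatch", "old_match"),
    ss4_a = c("new_new", "new_new", "old_mismatch", "old_match"),
    ss4_b = c("new_new", "old_mismatch", "old_mismatch", "old_match"),
    ss4_c = c("new_new", "old_mismatch", "old_match", "old_match")
  )
}

# pair-type multisets making up one block of 9 trials in E3/E4
block_compositions_ <- function() {
  comp <- trial_compositions()
  comp[c("ss2_a", "ss2_b", "ss2_c", "ss3_a", "ss3_a", "ss3_a",
         "ss4_a", "ss4_b", "ss4_c")]
}

#' Colour wheel used in the continuous-reproduction experiment
#'
#' The 360 colours lie on a circle in CIELAB space centred on
#' `L = 70, a = 20, b = 38` with radius 60; consecutive entries are 1
#' degree apart in hue angle, and wheel index `i` maps to response angle
#' `wrap_angle(i)`.
#'
#' @return A tibble with columns `index` (0-359), `angle_deg`
#'   (wrapped), and CIELAB coordinates `L`, `a`, `b`.
#' @export
build_color_wheel <- function() {
  index <- 0:359
  rad <- index * pi / 180
  tibble::tibble(
    index = index,
    angle_deg = wrap_angle(index),
    L = 70,
    a = 20 + 60 * cos(rad),
    b = 38 + 60 * sin(rad)
  )
}

# draw n discrete wheel colours (degrees)
sample_wheel_ <- function(n) wrap_angle(sample.int(360, n, replace = TRUE) - 1)

#' Build the trial schedule of an experiment
#'
#' Constructs the full factorial trial plan of one participant for one
#' of the four designs (see [designs]). The condition multiset within
#' each block is fixed by the design; trial order within blocks, serial
#' positions within trials, and the assignment of (opaque) stimulus
#' identities and colours are randomized by `seed`.
#'
#' @param experiment_id One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param seed Integer seed; fixes the schedule exactly.
#' @return A `trial_schedule`: a tibble with one row per pair
#'   (columns `experiment`, `block`, `trial`, `trial_in_block`,
#'   `set_size`, `wm_load`, `ltm_load`, `serial_position`, `pair_type`,
#'   `cue_id`, `target_id`, `target_color_deg`, `ltm_color_deg`), with
#'   the learning-phase list attached as attribute `learning`.
#' @examples
#' sch <- build_design("E1", seed = 1)
#' nrow(dplyr::distinct(sch, trial))  # 90 WM trials
#' @export
build_design <- function(experiment_id, seed = 1L) {
  experiment_id <- match.arg(experiment_id, experiment_ids)
  with_seed_(seed, {
    if (experiment_id %in% c("E1", "E2")) build_design_e12_(experiment_id)
    else build_design_e34_(experiment_id)
  })
}

new_schedule_ <- function(df, experiment_id, learning) {
  structure(df, class = c("trial_schedule", class(df)),
            experiment = experiment_id, learning = learning)
}

build_design_e12_ <- function(experiment_id) {
  cond <- e12_conditions(experiment_id)
  n_blocks <- 15L
  # two learning phases ("mega-blocks") of 90 word pairs each
  learning <- tibble::tibble(
    phase = rep(1:2, each = 90L),
    pair_id = sprintf("P%d_L%03d", rep(1:2, each = 90L), rep(1:90, 2))
  )
  phase_of_block <- ifelse(seq_len(n_blocks) <= 8L, 1L, 2L)
  ltm_pool <- split(learning$pair_id, learning$phase)
  new_counter <- 0L
  rows <- list()
  trial_id <- 0L
  for (b in seq_len(n_blocks)) {
    ord <- sample.int(nrow(cond))
    for (j in seq_along(ord)) {
      trial_id <- trial_id + 1L
      wm <- cond$wm_load[ord[j]]; ltm <- cond$ltm_load[ord[j]]
      ss <- wm + ltm
      ptype <- sample(c(rep("new", wm), rep("ltm", ltm)))
      ids <- character(ss)
      n_ltm <- sum(ptype == "ltm")
      if (n_ltm > 0) {
        ph <- phase_of_block[b]
        take <- ltm_pool[[ph]][seq_len(n_ltm)]
        ltm_pool[[ph]] <- ltm_pool[[ph]][-seq_len(n_ltm)]
        ids[ptype == "ltm"] <- take
      }
      n_new <- sum(ptype == "new")
      if (n_new > 0) {
        ids[ptype == "new"] <- sprintf("N%04d", new_counter + seq_len(n_new))
        new_counter <- new_counter + n_new
      }
      # the within-trial intrusion probe is drawn from an LTM pair or a
      # new pair at random when the trial contains both types
      lure_source <- if (wm > 0 && ltm > 0) {
        sample(c("new", "ltm"), ss, replace = TRUE)
      } else rep(ptype[1], ss)
      rows[[trial_id]] <- tibble::tibble(
        experiment = experiment_id, block = b, trial = trial_id,
        trial_in_block = j, set_size = ss, wm_load = wm, ltm_load = ltm,
        serial_position = seq_len(ss), pair_type = ptype,
        lure_source = lure_source,
        cue_id = paste0(ids, "_cue"), target_id = paste0(ids, "_tgt"),
        target_color_deg = NA_real_, ltm_color_deg = NA_real_
      )
    }
  }
  # LTM pools are drawn without replacement and never exhausted:
  # at most 48 of the 90 learned pairs per phase appear in WM trials.
  new_schedule_(dplyr::bind_rows(rows), experiment_id, learning)
}

build_design_e34_ <- function(experiment_id) {
  n_blocks <- if (experiment_id == "E3") 3L else 9L
  n_learned <- if (experiment_id == "E3") 54L else 120L
  learning <- tibble::tibble(
    pair_id = sprintf("L%03d", seq_len(n_learned)),
    group = ceiling(seq_len(n_learned) / 10),
    learned_color_deg = if (experiment_id == "E4") sample_wheel_(n_learned) else NA_real_
  )
  # old stimuli are used without replacement until the learned list is
  # exhausted, then recycled in order of first use (E4 blocks 8-9)
  old_order <- sample(learning$pair_id)
  old_ptr <- 0L
  next_old <- function() {
    old_ptr <<- old_ptr + 1L
    old_order[((old_ptr - 1L) %% n_learned) + 1L]
  }
  comps <- block_compositions_()
  new_counter <- 0L
  rows <- list()
  trial_id <- 0L
  for (b in seq_len(n_blocks)) {
    ord <- sample.int(length(comps))
    for (j in seq_along(ord)) {
      trial_id <- trial_id + 1L
      ptype <- sample(comps[[ord[j]]])  # randomize serial positions
      ss <- length(ptype)
      cue <- character(ss); tgt <- character(ss)
      tcol <- rep(NA_real_, ss); lcol <- rep(NA_real_, ss)
      for (i in seq_len(ss)) {
        if (ptype[i] == "new_new") {
          new_counter <- new_counter + 1L
          cue[i] <- sprintf("N%04d_cue", new_counter)
          tgt[i] <- sprintf("N%04d_tgt", new_counter)
          if (experiment_id == "E4") tcol[i] <- sample_wheel_(1)
        } else {
          id <- next_old()
          cue[i] <- paste0(id, "_cue")
          lc <- learning$learned_color_deg[match(id, learning$pair_id)]
          if (ptype[i] == "old_match") {
            tgt[i] <- paste0(id, "_tgt")
            if (experiment_id == "E4") { tcol[i] <- lc; lcol[i] <- lc }
          } else {  # old_mismatch: learned cue re-paired with a new associate
            new_counter <- new_counter + 1L
            tgt[i] <- sprintf("N%04d_tgt", new_counter)
            if (experiment_id == "E4") { tcol[i] <- sample_wheel_(1); lcol[i] <- lc }
          }
        }
      }
      rows[[trial_id]] <- tibble::tibble(
        experiment = experiment_id, block = b, trial = trial_id,
        trial_in_block = j, set_size = ss,
        wm_load = NA_integer_, ltm_load = NA_integer_,
        serial_position = seq_len(ss), pair_type = ptype,
        cue_id = cue, target_id = tgt,
        target_color_deg = tcol, ltm_color_deg = lcol
      )
    }
  }
  new_schedule_(dplyr::bind_rows(rows), experiment_id, learning)
}

#' Fill in imaginary LTM colours for an E4 schedule
#'
#' The LTM-intrusion component of the mixture model needs an LTM colour
#' for every pair. Old-mismatch pairs keep their true pre-learned
#' colour; new-new and old-match pairs receive independent "imaginary"
#' colours drawn uniformly on the wheel. Because participants never saw
#' these imaginary colours, the fitted intrusion probability in those
#' cells serves as a floor/baseline against which true intrusions on
#' mismatch pairs are compared.
#'
#' @param schedule An E4 `trial_schedule` (or simulated E4 dataset).
#' @param seed Integer seed for the uniform draws.
#' @return The schedule with `ltm_color_deg` complete.
#' @export
assign_imaginary_ltm_colors <- function(schedule, seed = 1L) {
  if (!identical(attr(schedule, "experiment"), "E4") &&
      !all(schedule$experiment == "E4")) {
    stop("imaginary LTM colours are defined for E4 schedules only", call. = FALSE)
  }
  idx <- schedule$pair_type %in% c("new_new", "old_match")
  with_seed_(seed, {
    schedule$ltm_color_deg[idx] <- stats::runif(sum(idx), -180, 180)
  })
  schedule
}
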