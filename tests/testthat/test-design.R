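trial_table <- function(sch) dplyr::distinct(tibble::as_tibble(sch), trial,
                                             .keep_all = TRUE)

test_that("E1 schedule reproduces the printed design counts", {
  sch <- build_design("E1", seed = 3)
  tr <- trial_table(sch)
  expect_equal(nrow(tr), 90)
  expect_equal(max(tr$block), 15)
  expect_true(all(table(tr$block) == 6))
  counts <- dplyr::count(tr, wm_load, ltm_load)
  expect_equal(nrow(counts), 6)
  expect_true(all(counts$n == 15))
  expect_setequal(paste(counts$wm_load, counts$ltm_load),
                  c("2 0", "4 0", "6 0", "0 2", "2 2", "4 2"))
  # each block contains each condition exactly once
  per_block <- dplyr::count(tr, block, wm_load, ltm_load)
  expect_true(all(per_block$n == 1))
  # two learning phases of 90 word pairs
  learning <- attr(sch, "learning")
  expect_equal(as.integer(table(learning$phase)), c(90L, 90L))
  # set size equals number of pairs presented
  expect_true(all(dplyr::count(tibble::as_tibble(sch), trial)$n ==
                    tr$set_size[order(tr$trial)]))
})

test_that("E2 drops the 2+2 condition and keeps 15 trials per cell", {
  tr <- trial_table(build_design("E2", seed = 4))
  expect_equal(nrow(tr), 75)
  counts <- dplyr::count(tr, wm_load, ltm_load)
  expect_true(all(counts$n == 15))
  expect_false(any(counts$wm_load == 2 & counts$ltm_load == 2))
  expect_setequal(paste(counts$wm_load, counts$ltm_load),
                  c("2 0", "4 0", "6 0", "0 2", "4 2"))
})

test_that("within-trial lure sources mix LTM and new pairs in mixed trials", {
  hits <- sapply(1:6, function(s) {
    sch <- tibble::as_tibble(build_design("E1", seed = s))
    mixed <- sch[sch$wm_load > 0 & sch$ltm_load > 0, ]
    c(any(mixed$lure_source == "ltm"), any(mixed$lure_source == "new"))
  })
  expect_true(all(hits))
  pure <- tibble::as_tibble(build_design("E1", seed = 1))
  pure <- pure[pure$ltm_load == 0, ]
  expect_true(all(pure$lure_source == "new"))
})

test_that("E3/E4 schedules follow the set-size composition table", {
  comp <- trial_compositions()
  sorted_multiset <- function(x) paste(sort(x), collapse = "+")
  admissible <- vapply(comp, sorted_multiset, "")

  for (ex in c("E3", "E4")) {
    sch <- tibble::as_tibble(build_design(ex, seed = 7))
    tr <- trial_table(sch)
    expect_equal(nrow(tr), if (ex == "E3") 27 else 81)
    expect_equal(max(tr$block), if (ex == "E3") 3 else 9)
    expect_true(all(table(tr$block) == 9))
    # 3 trials per set size per block
    per <- dplyr::count(tr, block, set_size)
    expect_true(all(per$n == 3))
    # every trial's pair-type multiset is an admissible composition row
    multisets <- sch |>
      dplyr::group_by(trial) |>
      dplyr::summarise(ms = sorted_multiset(pair_type), .groups = "drop")
    expect_true(all(multisets$ms %in% admissible))
    # each block holds one of each SS2 and SS4 row and three SS3 trials
    blk <- sch |>
      dplyr::group_by(block, trial) |>
      dplyr::summarise(ms = sorted_multiset(pair_type), .groups = "drop") |>
      dplyr::count(block, ms)
    expect_true(all(blk$n[blk$ms %in% admissible[c(1:3, 5:7)]] == 1))
    expect_true(all(blk$n[blk$ms == admissible[4]] == 3))
  }
})

test_that("E4 learning list has 120 conjunctions in groups of 10", {
  sch <- build_design("E4", seed = 9)
  learning <- attr(sch, "learning")
  expect_equal(nrow(learning), 120)
  expect_equal(as.integer(table(learning$group)), rep(10L, 12))
  expect_true(all(learning$learned_color_deg >= -180 &
                    learning$learned_color_deg < 180))
  # new stimuli never repeat; old stimuli recycle only after exhaustion
  df <- tibble::as_tibble(sch)
  new_ids <- df$target_id[df$pair_type == "new_new"]
  expect_equal(anyDuplicated(new_ids), 0L)
  old_cues <- df$cue_id[df$pair_type != "new_new"]
  expect_true(all(table(old_cues) <= 2))
})

test_that("old_match pairs carry their learned colour; mismatch decouples it", {
  df <- tibble::as_tibble(build_design("E4", seed = 10))
  m <- df[df$pair_type == "old_match", ]
  expect_equal(m$target_color_deg, m$ltm_color_deg)
  mm <- df[df$pair_type == "old_mismatch", ]
  expect_true(all(!is.na(mm$ltm_color_deg)))
  expect_gt(mean(mm$target_color_deg != mm$ltm_color_deg), 0.95)
  expect_true(all(is.na(df$ltm_color_deg[df$pair_type == "new_new"])))
})

test_that("colour wheel has 360 equally spaced CIELAB entries", {
  w <- build_color_wheel()
  expect_equal(nrow(w), 360)
  expect_equal(w$L, rep(70, 360))
  expect_equal(w$a[w$index == 0], 20 + 60)
  expect_equal(w$b[w$index == 0], 38)
  expect_equal(w$angle_deg, wrap_angle(w$index))
  # consecutive entries 1 degree apart in hue; radius 60 around (20, 38)
  expect_equal(sqrt((w$a - 20)^2 + (w$b - 38)^2), rep(60, 360))
  hue <- atan2(w$b - 38, w$a - 20) * 180 / pi
  expect_equal(wrap_angle(diff(hue)), rep(1, 359))
})

test_that("imaginary LTM colours are uniform, seed-stable, and E4-only", {
  sch <- build_design("E4", seed = 2)
  a1 <- assign_imaginary_ltm_colors(sch, seed = 5)
  a2 <- assign_imaginary_ltm_colors(sch, seed = 5)
  expect_identical(a1, a2)
  # mismatch pairs keep the true pre-learned colour
  idx <- sch$pair_type == "old_mismatch"
  expect_equal(a1$ltm_color_deg[idx], sch$ltm_color_deg[idx])
  expect_true(!anyNA(a1$ltm_color_deg))
  # pooled imaginary colours look uniform on the wheel
  pool <- unlist(lapply(1:12, function(s) {
    a <- assign_imaginary_ltm_colors(sch, seed = s)
    a$ltm_color_deg[a$pair_type %in% c("new_new", "old_match")]
  }))
  ks <- suppressWarnings(ks.test(pool, "punif", -180, 180))
  expect_gt(ks$p.value, 0.01)
  expect_error(assign_imaginary_ltm_colors(build_design("E1", 1), 1), "E4")
})

test_that("trial data survive a CSV round trip", {
  sch <- assign_imaginary_ltm_colors(build_design("E4", seed = 1), seed = 2)
  mp <- mixture_params(tibble::tibble(p_m = 0.8, p_swap = 0.1, p_ltm = 0.05,
                                      p_g = 0.05), kappa = 10)
  d <- simulate_repro_responses(sch, mp, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_data(d, path)
  back <- read_trial_data(path)
  expect_equal(back$response_deg, d$response_deg)
  expect_equal(back$pair_type, d$pair_type)
  expect_equal(back$ltm_color_deg, d$ltm_color_deg)
  expect_true(all(is.na(back$response_category)))
})
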