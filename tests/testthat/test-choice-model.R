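test_that("aggregation counts correct responses per participant and cell", {
  d <- tibble::tibble(
    participant = c(1, 1, 1, 1, 1, 1, 2, 2),
    wm_load = c(2, 2, 2, 2, 4, 4, 2, 2),
    ltm_load = 0L,
    response_category = c("target", "target", "new", "target",
                          "ltm_lure", "target", "target", "target"))
  cells <- aggregate_cells(d)
  r <- cells[cells$participant == 1 & cells$wm_load == 2, ]
  expect_equal(r$k, 3); expect_equal(r$n, 4)
  expect_equal(sum(cells$n), nrow(d))  # brute-force recount
  r2 <- cells[cells$participant == 2 & cells$wm_load == 2, ]
  expect_equal(r2$k, r2$n)
  # participant 2 never saw WM load 4: retained with n = 0
  empty <- cells[cells$participant == 2 & cells$wm_load == 4, ]
  expect_equal(empty$n, 0L)
  expect_error(aggregate_cells(dplyr::select(d, -response_category)),
               "response_category")
})

test_that("the cell design matrix is full rank, incl. the 6-of-8 E1 layout", {
  g <- e1_choice_group()
  pop <- simulate_population("E1", g, 3, seed = 30)
  spec <- glmm_spec(aggregate_cells(pop$data))
  expect_equal(nrow(spec$cell_table), 6)
  expect_equal(qr(spec$X_cell)$rank, ncol(spec$X_cell))
  expect_lte(ncol(spec$X_cell), 6)
  expect_equal(spec$prior_sd[1], 1.5)
  expect_true(all(spec$prior_sd[-1] == 1))
})

test_that("intercept-only fit at 50% accuracy centres the intercept at 0", {
  cells <- tibble::tibble(participant = 1L, condition = "all",
                          k = 500L, n = 1000L)
  fit <- suppressWarnings(
    fit_binomial_glmm(cells, chains = 2, warmup = 300, samples = 700,
                      seed = 5))
  draws <- wmltm:::pool_draws_(fit$draws[, , 1])
  expect_lt(abs(mean(draws)), 0.15)
})

test_that("contrasts are linear, antisymmetric, and match brute force", {
  g <- e1_choice_group(ltm_effect_at_wm2 = -1)
  pop <- simulate_population("E1", g, 12, seed = 31)
  fit <- suppressWarnings(
    fit_binomial_glmm(aggregate_cells(pop$data), chains = 2, warmup = 400,
                      samples = 800, seed = 6))
  labs <- fit$spec$cell_labels
  self <- contrast(fit, stats::setNames(c(1, -1), labs[c(1, 1)]))
  expect_equal(self$draws, rep(0, length(self$draws)))
  cw <- stats::setNames(c(1, -1), labs[c(2, 4)])
  a <- contrast(fit, cw)
  b <- contrast(fit, -cw)
  expect_equal(a$draws, -b$draws)
  # brute-force recomputation from the raw draw matrix
  cm <- cell_mean_draws(fit)
  expect_equal(a$draws, cm[, labs[2]] - cm[, labs[4]])
  expect_error(contrast(fit, c(nonexistent_cell = 1)), "cell labels")
})

test_that("a +1 logit effect is recovered within +-0.3 at cohort scale", {
  g <- e1_choice_group(ltm_effect_at_wm2 = 1)
  pop <- simulate_population("E1", g, 30, seed = 32)
  fit <- suppressWarnings(
    fit_binomial_glmm(aggregate_cells(pop$data), chains = 2, warmup = 500,
                      samples = 1000, seed = 7))
  ct <- fit$spec$cell_table
  lab2 <- fit$spec$cell_labels[ct$wm_load == 2 & ct$ltm_load == 2]
  lab0 <- fit$spec$cell_labels[ct$wm_load == 2 & ct$ltm_load == 0]
  eff <- contrast(fit, stats::setNames(c(1, -1), c(lab2, lab0)))
  expect_equal(mean(eff$draws), 1, tolerance = 0.3)
  # monotonicity across true effect sizes (0 vs 1 logit)
  g0 <- e1_choice_group(ltm_effect_at_wm2 = 0)
  fit0 <- suppressWarnings(
    fit_binomial_glmm(aggregate_cells(simulate_population("E1", g0, 30,
                                                          seed = 33)$data),
                      chains = 2, warmup = 500, samples = 1000, seed = 7))
  eff0 <- contrast(fit0, stats::setNames(c(1, -1), c(lab2, lab0)))
  expect_lt(mean(eff0$draws), mean(eff$draws))
  expect_lt(abs(mean(eff0$draws)), 0.3)
})

test_that("PF/PI contrasts equal their generic contrast definitions", {
  g <- default_group_params("E3")
  pop <- simulate_population("E3", g, 15, seed = 34)
  fit <- suppressWarnings(
    fit_binomial_glmm(aggregate_cells(pop$data), chains = 2, warmup = 400,
                      samples = 800, seed = 8))
  pp <- pf_pi_contrasts(fit, 4)
  ct <- fit$spec$cell_table
  lab <- function(pt) fit$spec$cell_labels[ct$set_size == 4 &
                                             ct$pair_type == pt]
  ref <- contrast(fit, stats::setNames(c(1, -1),
                                       c(lab("old_match"), lab("new_new"))))
  expect_equal(pp$facilitation$draws, ref$draws)
  expect_equal(pp$facilitation$prior_sd, ref$prior_sd)
  # generating pattern at SS4: facilitation positive, interference negative
  expect_gt(mean(pp$facilitation$draws > 0), 0.8)
  expect_gt(mean(pp$interference$draws < 0), 0.8)
  expect_error(pf_pi_contrasts(fit, 9), "absent")
})

test_that("a vanishing coefficient prior collapses effects to zero", {
  g <- e1_choice_group(ltm_effect_at_wm2 = 1)
  pop <- simulate_population("E1", g, 10, seed = 36)
  cells <- aggregate_cells(pop$data)
  spec0 <- glmm_spec(cells, coef_sd = 1e-3)
  fit <- suppressWarnings(
    fit_binomial_glmm(cells, spec0, chains = 2, warmup = 300, samples = 600,
                      seed = 10))
  coefs <- matrix(fit$draws, ncol = dim(fit$draws)[3])[, -1, drop = FALSE]
  expect_lt(max(abs(colMeans(coefs))), 0.01)
})

test_that("posterior predictive cell means stay inside (0, 1)", {
  g <- e1_choice_group()
  pop <- simulate_population("E1", g, 8, seed = 35)
  fit <- suppressWarnings(
    fit_binomial_glmm(aggregate_cells(pop$data), chains = 2, warmup = 300,
                      samples = 600, seed = 9))
  p <- plogis(cell_mean_draws(fit))
  expect_true(all(p > 0 & p < 1))

  # JSON/CSV export round-trips the reported quantities
  jpath <- withr::local_tempfile(fileext = ".json")
  dpath <- withr::local_tempfile(fileext = ".csv")
  export_fit(fit, jpath, dpath)
  js <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(nrow(js$summary), ncol(p))
  expect_equal(js$summary$mean, unname(colMeans(cell_mean_draws(fit))),
               tolerance = 1e-9)
  dr <- readr::read_csv(dpath, show_col_types = FALSE)
  expect_equal(nrow(dr), prod(dim(fit$draws)[1:2]))
})
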