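# Shared fixtures and independent oracle implementations.

# equal-propensity 4AFC responding (chance performance)
uniform_choice_tab <- function() {
  choice_propensities(p_target = 0.25, p_intrusion = 0.25,
                      p_ltm_lure = 0.25, p_new = 0.25)
}

# replicate one schedule k times (distinct participants) so simulators
# can be exercised at large n without rebuilding designs
replicate_schedule <- function(schedule, k) {
  dplyr::bind_rows(lapply(seq_len(k), function(i) {
    s <- tibble::as_tibble(schedule)
    s$participant <- i
    s
  }))
}

# Independent re-derivation of the four-component reproduction density,
# written directly from the Bessel-normalised von Mises form (not via
# the package's vm_density), used as the term-by-term oracle.
oracle_mixture_density <- function(response, target, others, ltm, w, kappa) {
  vm <- function(x, mu) {
    d <- ((x - mu + 180) %% 360 - 180) * pi / 180
    exp(kappa * cos(d)) / (2 * pi * besselI(kappa, 0)) * pi / 180
  }
  w[1] * vm(response, target) +
    w[2] * mean(sapply(others, function(o) vm(response, o))) +
    w[3] * vm(response, ltm) +
    w[4] / 360
}

# Closed-form Bayes factor for the conjugate normal-known-variance
# problem: prior theta ~ N(0, 1), data mean xbar of n observations with
# unit variance. Marginal likelihood ratio of H1 (prior) vs H0
# (theta = 0).
oracle_conjugate_bf <- function(xbar, n) {
  dnorm(xbar, 0, sqrt(1 + 1 / n)) / dnorm(xbar, 0, sqrt(1 / n))
}

# exact posterior of that conjugate problem
conjugate_posterior <- function(xbar, n) {
  list(mean = xbar * n / (n + 1), sd = sqrt(1 / (n + 1)))
}

# small E4-style generating parameters with flat structure
flat_repro_group <- function(p = c(0.7, 0.1, 0.1, 0.1), kappa = 12,
                             sigma = c(l_m = 0.3, log_kappa = 0.2)) {
  grid <- tidyr::expand_grid(set_size = 2:4,
                             pair_type = c("new_new", "old_match",
                                           "old_mismatch"))
  group_params(
    repro_logits = dplyr::bind_cols(grid, tibble::tibble(
      l_m = log(p[1] / p[4]), l_swap = log(p[2] / p[4]),
      l_ltm = log(p[3] / p[4]))),
    log_kappa = tibble::tibble(set_size = 2:4, log_kappa = log(kappa)),
    sigma = sigma)
}

# E1-style choice cohort parameters with a controllable LTM-load shift
# (in logits of the target category) applied at WM load 2
e1_choice_group <- function(ltm_effect_at_wm2 = 0, base_logit = 1.4,
                            sigma = c(l_target = 0.5)) {
  cond <- tibble::tribble(
    ~wm_load, ~ltm_load,
    2L, 0L, 4L, 0L, 6L, 0L, 0L, 2L, 2L, 2L, 4L, 2L)
  l <- rep(base_logit, 6)
  l[cond$wm_load == 2 & cond$ltm_load == 2] <- base_logit + ltm_effect_at_wm2
  group_params(choice_logits = dplyr::bind_cols(
    cond, tibble::tibble(l_target = l, l_intrusion = 0, l_ltm_lure = 0)),
    sigma = sigma)
}
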