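#' Savage-Dickey density-ratio Bayes factor
#'
#' For a point null at 0 and a parameter with prior density
#' `prior_density0` at 0, the Bayes factor in favour of an effect is
#' the ratio of prior to posterior density at zero:
#' `bf10 = p(0 | prior) / p(0 | posterior)`. The posterior density at 0
#' is estimated from the draws either by a normal approximation (mean
#' and SD of the draws; accurate for the near-Gaussian logit-scale
#' marginals this package produces) or by a Gaussian kernel-density
#' estimate evaluated at 0.
#'
#' @param draws Numeric vector of posterior draws (>= 1000).
#' @param prior_density0 Prior density at 0 (positive). For a linear
#'   contrast with induced normal prior SD `s`, this is `dnorm(0, 0, s)`.
#' @param estimator `"normal"` (default) or `"kde"`.
#' @param parameter Optional parameter label carried in the result.
#' @return A `bf_result` list: `bf10`, `bf01`, `kind`, `parameter`,
#'   `estimator`, `prior_density0`, `posterior_density0`.
#' @export
savage_dickey_bf <- function(draws, prior_density0,
                             estimator = c("normal", "kde"),
                             parameter = NULL) {
  estimator <- match.arg(estimator)
  if (length(draws) < 1000) {
    stop("Savage-Dickey estimation needs at least 1000 draws", call. = FALSE)
  }
  if (!is.numeric(prior_density0) || prior_density0 <= 0) {
    stop("`prior_density0` must be positive", call. = FALSE)
  }
  post0 <- switch(estimator,
    normal = stats::dnorm(0, mean(draws), stats::sd(draws)),
    kde = {
      d <- stats::density(draws)
      stats::approx(d$x, d$y, xout = 0, yleft = 0, yright = 0)$y
    }
  )
  if (!is.finite(post0) || post0 <= 0) {
    stop("posterior density at 0 is not positive; the posterior mass is ",
         "too far from the null for a stable Savage-Dickey estimate",
         call. = FALSE)
  }
  new_bf_(prior_density0 / post0, kind = "point_null_savage_dickey",
          parameter = parameter, estimator = estimator,
          prior_density0 = prior_density0, posterior_density0 = post0)
}

#' Directed (one-sided) Bayes factor by draw counting
#'
#' Evidence for a directed hypothesis computed as the ratio of
#' posterior mass in the expected direction to the mass in the other
#' direction, i.e. a simple count ratio over the draws. When no draw
#' falls in the minority direction the result is reported as a bound
#' (`bf10 >= n_draws`), flagged by `bound = TRUE`.
#'
#' @param draws Numeric vector of posterior draws (>= 1000).
#' @param direction `"positive"` or `"negative"`.
#' @param parameter Optional parameter label.
#' @return A `bf_result` with `bf10`, `bf01`, `bound`, counts.
#' @export
directed_bf <- function(draws, direction = c("positive", "negative"),
                        parameter = NULL) {
  direction <- match.arg(direction)
  if (length(draws) < 1000) {
    stop("directed Bayes factors need at least 1000 draws", call. = FALSE)
  }
  n_pos <- sum(draws > 0)
  n_neg <- sum(draws < 0)
  num <- if (direction == "positive") n_pos else n_neg
  den <- if (direction == "positive") n_neg else n_pos
  if (den == 0) {
    res <- new_bf_(length(draws), kind = "directed", parameter = parameter,
                   direction = direction, n_for = num, n_against = den)
    res$bound <- TRUE
    return(res)
  }
  res <- new_bf_(num / den, kind = "directed", parameter = parameter,
                 direction = direction, n_for = num, n_against = den)
  res$bound <- FALSE
  res
}

new_bf_ <- function(bf10, kind, parameter = NULL, ...) {
  if (!is.finite(bf10) || bf10 <= 0) stop("bf10 must be positive", call. = FALSE)
  structure(list(bf10 = bf10, bf01 = 1 / bf10, kind = kind,
                 parameter = parameter, ...),
            class = "bf_result")
}

#' Classify a Bayes factor by the BF > 3 convention
#'
#' Bayes factors above 3 count as substantial evidence for an effect,
#' below 1/3 (i.e. `bf01 > 3`) as substantial evidence for the null;
#' anything in between is inconclusive.
#'
#' @param bf10 Positive Bayes factor for the effect, or a `bf_result`.
#' @return One of `"substantial_for_effect"`, `"substantial_for_null"`,
#'   `"inconclusive"`.
#' @export
classify_bf <- function(bf10) {
  if (inherits(bf10, "bf_result")) bf10 <- bf10$bf10
  if (!is.numeric(bf10) || length(bf10) != 1 || !is.finite(bf10) || bf10 <= 0) {
    stop("`bf10` must be a positive number", call. = FALSE)
  }
  if (bf10 > 3) "substantial_for_effect"
  else if (1 / bf10 > 3) "substantial_for_null"
  else "inconclusive"
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (BF01 = %.4g), %s%s [%s]\n",
              x$bf10, x$bf01, x$kind,
              if (isTRUE(x$bound)) ", lower bound" else "",
              classify_bf(x$bf10)))
  invisible(x)
}

#' Bayes factor for a fitted contrast
#'
#' Convenience wrapper applying [savage_dickey_bf()] (using the
#' contrast's analytically induced normal prior) or [directed_bf()] to
#' a `contrast_draws` object produced by [contrast()] or
#' [pf_pi_contrasts()].
#'
#' @param x A `contrast_draws` object.
#' @param type `"savage_dickey"` or `"directed"`.
#' @param direction Direction for directed BFs.
#' @param ... Passed on to the underlying BF function.
#' @return A `bf_result`.
#' @export
bf_contrast <- function(x, type = c("savage_dickey", "directed"),
                        direction = "positive", ...) {
  stopifnot(inherits(x, "contrast_draws"))
  type <- match.arg(type)
  if (type == "savage_dickey") {
    if (is.null(x$prior_sd)) {
      stop("contrast has no induced prior SD; use a directed BF", call. = FALSE)
    }
    savage_dickey_bf(x$draws, stats::dnorm(0, 0, x$prior_sd),
                     parameter = x$label, ...)
  } else {
    directed_bf(x$draws, direction = direction, parameter = x$label, ...)
  }
}
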