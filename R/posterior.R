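#' Highest-density interval of a draw vector
#'
#' The narrowest contiguous interval containing `prob` of the draws,
#' computed by the shortest-window scan over the sorted sample. For
#' unimodal posteriors this is the HDI; its width never exceeds the
#' equal-tailed interval's.
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Interval mass (default 0.95).
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.95) {
  stopifnot(is.numeric(draws), prob > 0, prob <= 1)
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  width <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(width)
  c(x[i], x[i + m])
}

#' Posterior mean and 95% highest-density interval
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param prob HDI mass.
#' @return Tibble with `mean`, `lower`, `upper`, `prob`.
#' @export
posterior_summary <- function(draws, prob = 0.95) {
  if (length(draws) < 100) {
    stop("need at least 100 draws for a posterior summary", call. = FALSE)
  }
  h <- hdi(draws, prob)
  tibble::tibble(mean = mean(draws), lower = h[1], upper = h[2], prob = prob)
}

#' Split-chain R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half, i.e. the ratio of pooled to within-chain variance. Values
#' below 1.01 for all parameters are taken as evidence that the chains
#' mixed.
#'
#' @param x Matrix of draws (iterations x chains) for one parameter.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  parts <- cbind(x[seq_len(half), , drop = FALSE],
                 x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(parts)
  means <- colMeans(parts)
  vars <- apply(parts, 2, stats::var)
  b <- half * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  v <- (half - 1) / half * w + b / half
  sqrt(v / w)
}

#' Convergence report over a parameter draw array
#'
#' @param draws3-d array (iterations x chains x parameters) with
#'   parameter dimnames, as stored in the model fit objects.
#' @param threshold R-hat threshold (default 1.01).
#' @return List of class `convergence_report` with a per-parameter
#'   tibble and a logical `pass` (all R-hat below threshold).
#' @export
convergence_report <- function(draws, threshold = 1.01) {
  stopifnot(length(dim(draws)) == 3)
  pars <- dimnames(draws)[[3]]
  rhat <- vapply(seq_len(dim(draws)[3]),
                 function(j) split_rhat(draws[, , j]), numeric(1))
  tab <- tibble::tibble(parameter = pars %||% as.character(seq_along(rhat)),
                        rhat = rhat)
  structure(list(table = tab, threshold = threshold,
                 pass = all(rhat < threshold)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence: %s (max R-hat = %.4f, threshold %.2f)\n",
              if (x$pass) "PASS" else "FAIL",
              max(x$table$rhat), x$threshold))
  invisible(x)
}

# flatten an (iterations x chains) matrix into one draw vector
pool_draws_ <- function(x) as.vector(as.matrix(x))
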