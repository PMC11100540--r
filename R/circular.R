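#' Wrap angles onto the half-open interval [-180, 180)
#'
#' All angles in wmltm live on the response wheel's degree scale,
#' represented on `[-180, 180)`. `wrap_angle()` maps any finite degree
#' value onto that interval, preserving the value modulo 360. By the
#' half-open convention, `wrap_angle(180)` is `-180`.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, in `[-180, 180)`.
#' @examples
#' wrap_angle(370)   # 10
#' wrap_angle(-185)  # 175
#' wrap_angle(180)   # -180
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("angles must be finite", call. = FALSE)
  ((x + 180) %% 360) - 180
}

#' Signed circular difference between two angles
#'
#' Returns `a - b` wrapped onto `[-180, 180)`, i.e. the signed shortest
#' arc from `b` to `a`. Its absolute value is the circular distance used
#' as the recall-error measure in continuous-reproduction tasks.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Signed differences in degrees, in `[-180, 180)`.
#' @examples
#' circ_diff(10, 350)    # 20
#' circ_diff(-170, 170)  # 20
#' @export
circ_diff <- function(a, b) {
  wrap_angle(wrap_angle(a) - wrap_angle(b))
}

#' Von Mises density on the degree wheel
#'
#' Density of the von Mises distribution with centre `mu` (degrees) and
#' concentration `kappa`. The default scale is per degree, so that the
#' density integrates to 1 over the 360-degree wheel and `kappa = 0`
#' gives the uniform guessing density `1/360`. The per-radian scale
#' (the textbook normalisation) is larger by the factor `180/pi`.
#'
#' Computed on the log scale with an exponentially scaled Bessel
#' function, so it is stable for large `kappa`.
#'
#' @param x Numeric vector of angles in degrees.
#' @param mu Centre in degrees.
#' @param kappa Concentration, `>= 0`; `kappa = 0` is the circular uniform.
#' @param scale `"degree"` (default) or `"radian"`.
#' @param log Return log density?
#' @return Numeric vector of (log) densities.
#' @examples
#' vm_density(0, mu = 0, kappa = 0)  # 1/360
#' @export
vm_density <- function(x, mu, kappa, scale = c("degree", "radian"),
                       log = FALSE) {
  scale <- match.arg(scale)
  if (any(kappa < 0)) stop("`kappa` must be nonnegative", call. = FALSE)
  d <- circ_diff(x, mu) * pi / 180
  # log I0(kappa) from the exponentially scaled Bessel: I0(k) = scaled * e^k
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(d) - log(2 * pi) - log_i0
  if (scale == "degree") ld <- ld + log(pi / 180)
  if (log) ld else exp(ld)
}

#' Draw samples from a von Mises distribution
#'
#' Random angles (degrees on `[-180, 180)`) from a von Mises
#' distribution, via the Best-Fisher wrapped-Cauchy rejection sampler;
#' `kappa = 0` falls back to uniform sampling on the wheel. Uses R's
#' global RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param n Number of draws.
#' @param mu Centre in degrees (scalar or length-`n`).
#' @param kappa Concentration, `>= 0` (scalar or length-`n`).
#' @return Numeric vector of `n` angles in degrees.
#' @references Best, D. J., & Fisher, N. I. (1979). Efficient simulation
#'   of the von Mises distribution. Applied Statistics, 28, 152-157.
#' @export
vm_sample <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 1)
  if (any(kappa < 0)) stop("`kappa` must be nonnegative", call. = FALSE)
  mu <- rep_len(wrap_angle(mu), n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa == 0
  if (any(unif)) out[unif] <- stats::runif(sum(unif), -180, 180)
  todo <- which(!unif)
  if (length(todo)) {
    k <- kappa[todo]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    r <- (1 + rho^2) / (2 * rho)
    theta <- rep(NA_real_, length(todo))
    pending <- seq_along(todo)
    while (length(pending)) {
      m <- length(pending)
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[pending] * z) / (r[pending] + z)
      c_ <- k[pending] * (r[pending] - f)
      accept <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
      ok <- pending[accept]
      theta[ok] <- sign(u3[accept] - 0.5) * acos(f[accept])
      pending <- pending[!accept]
    }
    out[todo] <- wrap_angle(theta * 180 / pi + mu[todo])
  }
  out
}

#' Mean absolute circular error
#'
#' Mean over trials of the absolute circular distance between response
#' and target, in degrees. Uniform (guessing) responding has expectation
#' 90 degrees, the chance anchor for continuous reproduction.
#'
#' @param response,target Numeric vectors of angles in degrees.
#' @return Scalar mean absolute error in `[0, 180]`.
#' @export
mean_abs_error <- function(response, target) {
  mean(abs(circ_diff(response, target)))
}
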