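#' Gamma-variate bolus parameters
#'
#' The standard first-pass bolus model of nuclear medicine:
#' `C(t) = K * (t - t0)^alpha * exp(-(t - t0) / beta)` for `t > t0`, zero
#' before the appearance time `t0`.
#'
#' @param k_scale Amplitude `K` (> 0), counts per second^alpha.
#' @param alpha_shape Dimensionless shape exponent (> 0).
#' @param beta_scale_s Time constant `beta` in seconds (> 0).
#' @param t0_s Appearance time in seconds (>= 0).
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(k_scale, alpha_shape, beta_scale_s, t0_s = 0) {
  if (k_scale <= 0 || alpha_shape <= 0 || beta_scale_s <= 0 || t0_s < 0)
    stop("invalid gamma-variate parameters: require K, alpha, beta > 0 and t0 >= 0")
  structure(list(k_scale = k_scale, alpha_shape = alpha_shape,
                 beta_scale_s = beta_scale_s, t0_s = t0_s),
            class = "gamma_params")
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf("Gamma variate: K=%.4g, alpha=%.4g, beta=%.4g s, t0=%.4g s (peak %.4g s)\n",
              x$k_scale, x$alpha_shape, x$beta_scale_s,
              x$t0_s, x$t0_s + x$alpha_shape * x$beta_scale_s))
  invisible(x)
}

## Vectorized evaluation of the gamma variate at times t.
gamma_value <- function(params, t) {
  u <- t - params$t0_s
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- params$k_scale * u[pos]^params$alpha_shape *
    exp(-u[pos] / params$beta_scale_s)
  out
}

#' Sample a gamma-variate curve as a TAC
#'
#' @param params A [gamma_params()].
#' @param times Strictly increasing sample times, seconds.
#' @return A [time_activity_curve()] of the curve values.
#' @export
gamma_curve <- function(params, times) {
  if (!inherits(params, "gamma_params")) stop("`params` must be gamma_params")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  time_activity_curve(times, gamma_value(params, times))
}

#' Analytic integral of a gamma variate
#'
#' The full integral over `[t0, Inf)`:
#' `K * beta^(alpha + 1) * Gamma(alpha + 1)`.
#'
#' @param params A [gamma_params()].
#' @return Integral in counts * s.
#' @export
gamma_integral <- function(params) {
  exp(log(params$k_scale) +
        (params$alpha_shape + 1) * log(params$beta_scale_s) +
        lgamma(params$alpha_shape + 1))
}

## Cumulative analytic integral from t0 to t (vectorized), via the
## regularized lower incomplete gamma function (pgamma).
gamma_cumint <- function(params, t) {
  u <- pmax(t - params$t0_s, 0)
  gamma_integral(params) *
    pgamma(u / params$beta_scale_s, shape = params$alpha_shape + 1)
}
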