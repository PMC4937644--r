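#' Fit a gamma variate to a TAC window
#'
#' Bounded nonlinear least squares of the bolus model
#' `K (t - t0)^alpha exp(-(t - t0)/beta)` on the windowed samples
#' (Levenberg-Marquardt). The starting point comes from a log-linearization
#' of the windowed samples over a grid of candidate appearance times; on
#' failure the fit is restarted from three perturbed initializations. The
#' bounds `alpha <= 10`, `beta <= 60` s keep the optimizer away from
#' degenerate spike fits.
#'
#' @param tac A [time_activity_curve()].
#' @param window Integer index range `(lo, hi)` into the TAC, e.g. the
#'   `second_peak_window` of [split_peaks()]; >= 5 samples.
#' @param init Optional [gamma_params()] starting point.
#' @return An object of class `gamma_fit`: `params` ([gamma_params()]),
#'   `rss`, `converged`, and `integral_counts`, the analytic integral
#'   `K beta^(alpha+1) Gamma(alpha+1)` of the fitted curve.
#' @export
fit_gamma <- function(tac, window, init = NULL) {
  window <- as.integer(range(window))
  idx <- seq(window[1], window[2])
  if (length(idx) < 5) stop("fit window must contain at least 5 samples")
  t <- tac$times_s[idx]
  y <- tac$counts[idx]
  if (max(y) <= 0) stop("fit window contains no counts")

  model <- function(t, K, alpha, beta, t0) {
    u <- pmax(t - t0, 0)
    ifelse(u > 0, K * u^alpha * exp(-u / beta), 0)
  }
  ## t0 may sit inside the window (the model is zero before it) but must
  ## precede the observed peak
  t_peak <- t[which.max(y)]
  lower <- c(K = 1e-12, alpha = 1e-3, beta = 1e-3, t0 = 0)
  upper <- c(K = Inf, alpha = 10, beta = 60, t0 = t_peak - 1e-3)

  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- c(K = init$k_scale, alpha = init$alpha_shape,
                     beta = init$beta_scale_s, t0 = init$t0_s)
  } else {
    starts[[1]] <- loglin_init(t, y)
  }
  base <- starts[[1]]
  for (j in 1:3)
    starts[[j + 1]] <- base * c(1, 0.7 + 0.3 * j, 0.7 + 0.2 * j, 0.9)
  starts[[5]] <- c(base[1], base[2], base[3],
                   min(base[4] + 0.25 * (t_peak - base[4]), t_peak - 0.01))
  starts[[6]] <- c(K = max(y) / max(t_peak - min(t), 1)^2, alpha = 2,
                   beta = max((max(t) - t_peak) / 2, 0.5),
                   t0 = max(min(t) - (max(t) - min(t)) / 4, 0))

  fit <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-9), c(Inf, upper[2:4] - 1e-9))
    names(st) <- names(lower)
    res <- tryCatch(
      minpack.lm::nlsLM(y ~ model(t, K, alpha, beta, t0),
                        start = as.list(st),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$convInfo$isConv)) { fit <- res; break }
  }
  if (is.null(fit))
    stop("gamma-variate fit failed to converge after multi-start; ",
         "inspect the peak window (n = ", length(idx), ", peak = ", max(y), ")")
  cf <- coef(fit)
  params <- gamma_params(cf[["K"]], cf[["alpha"]], cf[["beta"]], cf[["t0"]])
  rss <- sum(stats::residuals(fit)^2)
  structure(list(params = params, rss = rss, converged = TRUE,
                 integral_counts = gamma_integral(params),
                 window = window),
            class = "gamma_fit")
}

## Starting values from the linearization
## log y = log K + alpha log(t - t0) - (t - t0)/beta
## over a small grid of candidate appearance times below the window start.
loglin_init <- function(t, y) {
  span <- max(t) - min(t)
  t_peak <- t[which.max(y)]
  ## candidate appearance times from well before the window up to just
  ## before the peak; samples at or before a candidate t0 are treated as
  ## pre-appearance and excluded from its linearization
  cand <- unique(pmax(c(min(t) - c(1, 0.5, 0.25) * span,
                        min(t) + c(0.1, 0.3, 0.5, 0.7, 0.9) *
                          (t_peak - min(t))), 0))
  best <- NULL; best_rss <- Inf
  for (t0 in cand) {
    use <- t > t0 + 1e-9 & y > max(y) * 1e-3
    if (sum(use) < 4) next
    u <- t[use] - t0
    X <- cbind(1, log(u), -u)
    co <- tryCatch(qr.solve(X, log(y[use])), error = function(e) NULL)
    if (is.null(co) || co[2] <= 0 || co[3] <= 0) next
    pars <- c(K = exp(co[1]), alpha = co[2], beta = 1 / co[3], t0 = t0)
    pred <- ifelse(t > t0, pars[1] * pmax(t - t0, 0)^pars[2] *
                     exp(-pmax(t - t0, 0) / pars[3]), 0)
    rss <- sum((pred - y)^2)
    if (rss < best_rss) { best <- pars; best_rss <- rss }
  }
  if (is.null(best)) {
    best <- c(K = max(y) / max(t_peak - min(t), 1)^2,
              alpha = 2, beta = max((max(t) - t_peak) / 2, 0.5),
              t0 = max(min(t) - span * 0.25, 0))
  }
  best
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma fit (%s): integral %.5g counts*s, rss %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$integral_counts, x$rss))
  print(x$params)
  invisible(x)
}

#' Input counts from a fitted gamma variate
#'
#' The arterial input counts are the full analytic integral of the fitted
#' bolus curve over `[t0, Inf)`.
#'
#' @param fit A converged [fit_gamma()] result.
#' @return Input counts (counts * s).
#' @export
input_counts <- function(fit) {
  if (!inherits(fit, "gamma_fit")) stop("`fit` must be a gamma_fit")
  if (!isTRUE(fit$converged)) stop("gamma fit did not converge")
  fit$integral_counts
}
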