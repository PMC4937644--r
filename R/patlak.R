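#' Patlak graphical transform
#'
#' For an irreversibly trapped tracer, plotting the tissue-to-input ratio
#' `y(t) = Cb(t)/Ca(t)` against the normalized integrated input
#' `x(t) = (integral of Ca to t) / Ca(t)` yields a straight line whose slope
#' is the unidirectional uptake rate Ku. The cumulative input integral is
#' trapezoidal; points where the input falls below `min_input_frac` of its
#' peak are dropped (the ratio is unstable there).
#'
#' @param brain_tac Tissue (hemispheric) TAC.
#' @param input_tac Arterial input TAC on the same timebase.
#' @param min_input_frac Retention threshold on `Ca` relative to its peak
#'   (default 0.05).
#' @return An object of class `patlak_plot`: a data frame (`time_s`, `x`,
#'   `y`) plus the index of the input peak among retained points.
#' @export
patlak_transform <- function(brain_tac, input_tac, min_input_frac = 0.05) {
  if (length(brain_tac$times_s) != length(input_tac$times_s) ||
      any(abs(brain_tac$times_s - input_tac$times_s) > 1e-9))
    stop("brain and input TACs must share a timebase")
  t <- input_tac$times_s
  ca <- input_tac$counts
  cb <- brain_tac$counts
  ## trapezoidal cumulative integral of Ca; the unobserved leading segment
  ## [0, t_1] uses the rectangle Ca(t_1) * t_1, exact for a constant input
  ## and vanishing for a bolus that has not yet appeared
  cum <- cumsum(c(ca[1] * t[1],
                  (ca[-1] + ca[-length(ca)]) / 2 * diff(t)))
  keep <- ca >= min_input_frac * max(ca) & ca > 0
  if (!any(keep)) stop("no valid Patlak points: input is below threshold everywhere")
  pts <- data.frame(time_s = t[keep],
                    x = cum[keep] / ca[keep],
                    y = cb[keep] / ca[keep])
  structure(list(points = pts,
                 input_peak_index = which.max(ca[keep])),
            class = "patlak_plot")
}

#' @export
print.patlak_plot <- function(x, ...) {
  cat(sprintf("Patlak plot: %d points, x in [%.3g, %.3g] s\n",
              nrow(x$points), min(x$points$x), max(x$points$x)))
  invisible(x)
}

#' Patlak slope (Ku) by ordinary least squares
#'
#' Fits `y = ku * x + intercept` over the fit window. The default window is
#' the post-input-peak linear phase: all retained points after the peak of
#' the input curve.
#'
#' @param plot A [patlak_transform()] result.
#' @param fit_window Optional integer index range into the retained points.
#' @return A list: `ku` (1/s), `intercept`, `r2`, `n`.
#' @export
estimate_ku <- function(plot, fit_window = NULL) {
  pts <- plot$points
  idx <- if (is.null(fit_window)) {
    seq(min(plot$input_peak_index + 1L, nrow(pts)), nrow(pts))
  } else seq(min(fit_window), max(fit_window))
  if (length(idx) < 3) stop("need at least 3 points in the Patlak fit window")
  x <- pts$x[idx]; y <- pts$y[idx]
  if (var(x) < .Machine$double.eps * max(1, mean(x)^2))
    stop("degenerate abscissa: no variance in normalized integrated input")
  fit <- lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(ku = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       n = length(idx))
}

#' Brain perfusion index from the Patlak slope
#'
#' `BPI = scale * Ku`. The normalization constant is a convention of the PP
#' software chain; it is explicit configuration here (see
#' [analysis_config()]).
#'
#' @param ku Patlak slope, 1/s.
#' @param scale Positive normalization constant.
#' @return A list of class `bpi_result`: `bpi`, `ku`, `scale`.
#' @export
ku_to_bpi <- function(ku, scale) {
  if (scale <= 0) stop("`scale` must be > 0")
  structure(list(bpi = scale * ku, ku = ku, scale = scale),
            class = "bpi_result")
}

#' PP calibration: brain perfusion index to mean CBF
#'
#' The Xe-133-anchored calibration line of the PP method:
#' `mCBF = 2.60 * BPI + 19.8` ml/100g/min. Its intercept, 19.8, is the PP
#' method's minimum flow.
#'
#' @param bpi Brain perfusion index (>= 0), or a [ku_to_bpi()] result.
#' @return mCBF in ml/100g/min.
#' @export
bpi_to_mcbf <- function(bpi) {
  if (inherits(bpi, "bpi_result")) bpi <- bpi$bpi
  if (any(bpi < 0)) stop("`bpi` must be >= 0")
  .PP_SLOPE * bpi + .PP_INTERCEPT
}

#' Distribute mean CBF regionally through the SPECT count distribution
#'
#' The PP method's regional step: Lassen-correct the segment counts against
#' the basal-ganglia reference, then scale so the basal-ganglia reference
#' equals the mCBF: `rCBF_s = mcbf * corrected_s / corrected_reference`.
#'
#' @param spect_counts_map Named vector of raw segment mean counts.
#' @param mcbf Mean CBF from [bpi_to_mcbf()], ml/100g/min.
#' @param config An [analysis_config()].
#' @param template A [region_template()] (validates segment names).
#' @return A [regional_cbf()] with method `"PP"`. The basal-ganglia
#'   reference maps to `mcbf` exactly.
#' @export
distribute_rcbf_pp <- function(spect_counts_map, mcbf, config, template) {
  bg <- bg_segments(config, template)
  missing <- setdiff(bg, names(spect_counts_map))
  if (length(missing))
    stop("basal-ganglia segments missing from counts: ",
         paste(missing, collapse = ", "))
  ref <- mean(spect_counts_map[bg])
  corrected <- lassen_correct(spect_counts_map, config$lassen_alpha, ref)
  rcbf <- mcbf * corrected / ref
  regional_cbf("PP", rcbf, mcbf, config$normal_side)
}

#' Full Patlak-plot pipeline for one subject
#'
#' Aortic input and hemispheric output TACs (manual ROI positions from the
#' config, automatic detection as fallback for the input), Patlak transform
#' and slope, BPI, mCBF through the Xe-133 calibration line, and regional
#' distribution through the Lassen-corrected SPECT counts.
#'
#' @inheritParams ibur_pipeline
#' @return A [regional_cbf()] with method `"PP"`; the Patlak plot, slope
#'   fit and BPI are attached as attributes `plot`, `ku_fit`, `bpi`.
#' @export
patlak_pipeline <- function(series, volume, template, config) {
  grid <- dim(series$frames)[2:3]
  input_roi <- if (!is.null(config$pp_input_roi)) {
    roi_mask(config$pp_input_roi, config$roi_diameter_px, grid)
  } else detect_aorta_roi(series, diameter_px = config$roi_diameter_px)
  if (is.null(config$pp_hemisphere_roi))
    stop("PP requires `pp_hemisphere_roi` in the config (manual ROI)")
  hemi_roi <- roi_mask(config$pp_hemisphere_roi,
                       config$pp_hemisphere_diameter_px, grid)
  input_tac <- extract_tac(series, input_roi)
  brain_tac <- extract_tac_mean(series, hemi_roi)
  if (config$pp_input_integral == "gamma") {
    ## optional variant: replace the raw input by its second-peak gamma fit
    split <- split_peaks(input_tac)
    fit <- fit_gamma(input_tac, split$second_peak_window)
    input_tac <- gamma_curve(fit$params, input_tac$times_s)
  }

  pl <- patlak_transform(brain_tac, input_tac)
  kf <- estimate_ku(pl, config$patlak_fit_window)
  bpi <- ku_to_bpi(kf$ku, config$bpi_scale)
  mcbf <- bpi_to_mcbf(bpi)

  counts <- segment_mean_counts(volume, template)
  out <- distribute_rcbf_pp(counts, mcbf, config, template)
  attr(out, "plot") <- pl
  attr(out, "ku_fit") <- kf
  attr(out, "bpi") <- bpi
  out
}
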