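#' Mean SPECT counts per template segment
#'
#' @param volume A [spect_volume()].
#' @param template A [region_template()] on the same grid.
#' @return Named numeric vector: mean voxel counts per segment.
#' @export
segment_mean_counts <- function(volume, template) {
  if (!identical(dim(volume$voxels), dim(template$labels)))
    stop("volume and template grids differ")
  lab <- as.vector(template$labels)
  vox <- as.vector(volume$voxels)
  keep <- lab > 0L
  sums <- tapply(vox[keep], lab[keep], mean)
  out <- setNames(rep(NA_real_, nrow(template$segments)),
                  template$segments$name)
  out[as.integer(names(sums))] <- as.numeric(sums)
  if (anyNA(out))
    stop("empty segments: ",
         paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Lassen linearization correction
#'
#' Compensates the saturation of flow-tracer retention at high flow. With
#' reference count `C_r` and correction constant `alpha`, each segment count
#' `C_s` maps to
#' `corrected = C_r * alpha * (C_s / C_r) / (1 + alpha - C_s / C_r)`,
#' which leaves the reference value fixed and tends to the identity as
#' `alpha` grows.
#'
#' @param counts_map Named numeric vector of segment counts.
#' @param alpha Lassen constant (> 0).
#' @param reference The reference count `C_r`: either a numeric value (e.g. a
#'   basal-ganglia mean) or the name of a segment in `counts_map`.
#' @return Named numeric vector of corrected counts.
#' @export
lassen_correct <- function(counts_map, alpha, reference) {
  if (alpha <= 0) stop("`alpha` must be > 0")
  cr <- if (is.character(reference)) {
    if (!reference %in% names(counts_map))
      stop("reference segment '", reference, "' not in counts map")
    counts_map[[reference]]
  } else as.numeric(reference)
  if (!is.finite(cr) || cr <= 0) stop("reference count must be positive")
  x <- counts_map / cr
  bad <- x >= 1 + alpha
  if (any(bad))
    stop("count ratio >= 1 + alpha (nonphysical) for segment(s): ",
         paste(names(counts_map)[bad], collapse = ", "))
  cr * alpha * x / (1 + alpha - x)
}

#' Regional brain uptake ratio
#'
#' `rBUR = CCF * corrected_counts / input_counts`: Lassen-corrected SPECT
#' segment counts divided by the integrated arterial input, cross-calibrated
#' between the planar and tomographic modalities.
#'
#' @param segment_counts Named vector of (Lassen-corrected) segment counts.
#' @param input_counts Integrated input (counts * s), > 0.
#' @param ccf Cross-calibration factor, > 0.
#' @return Named vector of rBUR values.
#' @export
compute_rbur <- function(segment_counts, input_counts, ccf) {
  if (!is.numeric(input_counts) || input_counts <= 0)
    stop("`input_counts` must be > 0")
  if (ccf <= 0) stop("`ccf` must be > 0")
  ccf * segment_counts / input_counts
}

#' IBUR calibration: uptake ratio to flow
#'
#' The PET-anchored calibration line of the IBUR method:
#' `rCBF = 3.23 * BUR + 4.66` ml/100g/min. Its intercept, 4.66, is the
#' method's minimum reportable flow.
#'
#' @param rbur Brain uptake ratio(s), >= 0.
#' @return rCBF in ml/100g/min.
#' @export
rbur_to_rcbf <- function(rbur) {
  if (any(rbur < 0)) stop("`rbur` must be >= 0")
  .IBUR_SLOPE * rbur + .IBUR_INTERCEPT
}

#' Regional CBF table
#'
#' @param method `"IBUR"` or `"PP"`.
#' @param per_segment Named vector of rCBF values, ml/100g/min.
#' @param mcbf Mean CBF, ml/100g/min.
#' @param normal_side `"left"` or `"right"`.
#' @return An object of class `regional_cbf`.
#' @export
regional_cbf <- function(method = c("IBUR", "PP"), per_segment, mcbf,
                         normal_side = c("left", "right")) {
  method <- match.arg(method)
  normal_side <- match.arg(normal_side)
  if (any(!is.finite(per_segment)) || any(per_segment < 0))
    stop("rCBF values must be finite and >= 0")
  structure(list(method = method, per_segment = per_segment,
                 mcbf = mcbf, normal_side = normal_side),
            class = "regional_cbf")
}

#' @export
print.regional_cbf <- function(x, ...) {
  cat(sprintf("%s regional CBF: mCBF %.1f ml/100g/min (normal side %s)\n",
              x$method, x$mcbf, x$normal_side))
  rng <- range(x$per_segment)
  cat(sprintf("  %d segments, rCBF %.1f-%.1f ml/100g/min\n",
              length(x$per_segment), rng[1], rng[2]))
  invisible(x)
}

#' @export
as.data.frame.regional_cbf <- function(x, ...) {
  data.frame(segment = names(x$per_segment),
             side = ifelse(grepl("^left_", names(x$per_segment)),
                           "left", "right"),
             rcbf = as.numeric(x$per_segment),
             method = x$method,
             row.names = NULL)
}

#' Mean CBF for the IBUR method
#'
#' Unweighted mean of the rCBF values of the configured basal-ganglia
#' segments on the configured normal hemisphere.
#'
#' @param per_segment_rcbf Named vector of rCBF per segment.
#' @param config An [analysis_config()].
#' @return mCBF in ml/100g/min.
#' @export
mcbf_ibur <- function(per_segment_rcbf, config) {
  nm <- paste0(config$normal_side, "_", config$basal_ganglia_segments)
  missing <- setdiff(nm, names(per_segment_rcbf))
  if (length(missing))
    stop("basal-ganglia segments missing from rCBF table: ",
         paste(missing, collapse = ", "))
  mean(per_segment_rcbf[nm])
}

#' Cross-calibration factor from a uniform phantom pair
#'
#' Auxiliary estimator: for a phantom imaged in both modalities, the CCF is
#' the ratio of the mean planar count to the mean SPECT count over the
#' phantom region.
#'
#' @param planar_counts Planar counts over the phantom ROI.
#' @param spect_counts SPECT counts over the phantom volume.
#' @return Estimated CCF.
#' @export
estimate_ccf <- function(planar_counts, spect_counts) {
  if (mean(spect_counts) <= 0) stop("SPECT phantom counts must be positive")
  mean(planar_counts) / mean(spect_counts)
}

#' Full IBUR pipeline for one subject
#'
#' Automatic aortic ROI detection, second-peak gamma-variate fit, analytic
#' input integration, Lassen correction of SPECT segment counts against the
#' basal-ganglia reference, uptake-ratio computation and calibration to
#' rCBF/mCBF.
#'
#' @param series Dynamic planar series.
#' @param volume SPECT volume.
#' @param template Region template aligned to `volume`.
#' @param config An [analysis_config()] (supplies `ccf`, `lassen_alpha`,
#'   basal-ganglia definition and normal side).
#' @return A [regional_cbf()] with method `"IBUR"`; the gamma fit and rBUR
#'   map are attached as attributes `fit` and `rbur`.
#' @export
ibur_pipeline <- function(series, volume, template, config) {
  roi <- detect_aorta_roi(series, diameter_px = config$roi_diameter_px)
  tac <- extract_tac(series, roi)
  split <- split_peaks(tac)
  fit <- fit_gamma(tac, split$second_peak_window)
  input <- input_counts(fit)

  counts <- segment_mean_counts(volume, template)
  ref <- mean(counts[bg_segments(config, template)])
  corrected <- lassen_correct(counts, config$lassen_alpha, ref)
  rbur <- compute_rbur(corrected, input, config$ccf)
  rcbf <- rbur_to_rcbf(rbur)
  out <- regional_cbf("IBUR", rcbf, mcbf_ibur(rcbf, config),
                      config$normal_side)
  attr(out, "fit") <- fit
  attr(out, "rbur") <- rbur
  out
}
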