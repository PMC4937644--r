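## Synthetic acquisition simulator.
##
## Forward model, in the reconstructed-count domain (no projection physics):
##  * planar chest/brain view: a pulmonary first-pass disc (early gamma
##    variate), an ascending-aorta disc (later gamma variate, radially
##    tapered so the max-count pixel is its centre) partially overlapped by
##    the pulmonary disc, and a brain disc following microsphere kinetics
##    Cb(t) = Ku * integral of the aortic-ROI input curve;
##  * SPECT: per-segment counts built by inverting the Lassen correction on
##    flow-proportional target values, so the analysis pipeline's
##    correct-then-anchor path recovers flow exactly in the noiseless case;
##  * optional per-pixel/per-voxel Poisson noise.

## Default bolus shapes (s): pulmonary transit peaks ~5 s, aortic ~20 s.
default_input_shape <- function() list(alpha = 3, beta = 2, t0 = 14)
default_pulmonary_shape <- function() list(alpha = 3, beta = 1.1, t0 = 2)

## Radial amplitude taper of the aortic disc; strict maximum at the centre
## makes automatic max-count detection deterministic.
aorta_taper <- function(d2) 1 - 0.02 * d2

## Scene geometry scaled to the planar grid (fractions of a 64x64 layout).
planar_scene <- function(planar_dim) {
  s <- planar_dim[1] / 64
  list(brain_center = round(c(12, 32) * s), brain_radius = 9 * s,
       pulm_center = round(c(40, 30) * s), pulm_radius = 5.5 * s,
       ## ascending aorta ~30 mm caliber: radius 3.75 px at 4 mm pixels
       aorta_center = round(c(40, 34) * s), aorta_radius = 3.75 * s)
}

disc_pixels <- function(center, radius, dim) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  which(d2 <= radius^2 + 1e-9)
}

#' Build a synthetic stereotaxic region template
#'
#' A geometric stand-in for the anatomically standardized 24-segment
#' parcellation: an ellipsoidal brain mask split into left/right halves and
#' 12 axial slabs per side, labelled with the canonical segment names. It is
#' synthetic — segment shapes carry no anatomical meaning, only the label
#' structure the regional readout needs.
#'
#' @param spect_dim 3-D grid dimensions (default `c(32, 32, 32)`).
#' @return A [region_template()].
#' @export
make_srt_template <- function(spect_dim = c(32, 32, 32)) {
  ctr <- (spect_dim + 1) / 2
  radii <- spect_dim * c(0.34, 0.40, 0.34)
  x <- (seq_len(spect_dim[1]) - ctr[1]) / radii[1]
  y <- (seq_len(spect_dim[2]) - ctr[2]) / radii[2]
  z <- (seq_len(spect_dim[3]) - ctr[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  mask <- d2 <= 1
  labels <- array(0L, dim = spect_dim)
  idx <- which(mask, arr.ind = TRUE)
  side_right <- idx[, 1] > ctr[1]
  ## per side, order voxels along z and split into 12 equal-count slabs so
  ## every segment is nonempty even on small grids
  for (right in c(FALSE, TRUE)) {
    sel <- which(side_right == right)
    ord <- sel[order(idx[sel, 3], idx[sel, 2], idx[sel, 1])]
    slab <- ceiling(12 * seq_along(ord) / length(ord))
    labels[cbind(idx[ord, 1], idx[ord, 2], idx[ord, 3])] <-
      as.integer(slab + if (right) 12L else 0L)
  }
  region_template(labels)
}

#' Simulate one subject's acquisition with known ground truth
#'
#' Generates a dynamic planar series, a SPECT volume and a region template
#' whose hidden flows and calibration constants are returned alongside, so
#' that every downstream stage can be tested by parameter recovery.
#'
#' @param segment_flow Named vector of true rCBF (ml/100g/min) for all 24
#'   template segments (names as in [srt_segment_names()]). All values must
#'   exceed the IBUR calibration floor of 4.66 ml/100g/min.
#' @param noise `"none"` or `"poisson"` (per-pixel / per-voxel).
#' @param seed Integer seed; with `noise = "none"` the output is
#'   deterministic regardless of seed.
#' @param planar_dim,n_frames,frame_duration_s Planar acquisition geometry;
#'   defaults 64x64, 120 frames of 1 s (the full-resolution 128x128 matrix is
#'   available via `planar_dim`).
#' @param spect_dim SPECT grid (default 32^3).
#' @param lassen_alpha True Lassen constant used in the forward model.
#' @param bpi_scale BPI normalization tying Ku to mean CBF.
#' @param normal_side,basal_ganglia_segments Which segments define mCBF.
#' @param aortic_peak_counts Noiseless aorta-ROI TAC peak, counts/frame.
#' @param spect_bg_counts Approximate raw SPECT counts/voxel at the
#'   basal-ganglia reference level.
#' @param input_shape,pulmonary_shape Lists `(alpha, beta, t0)` giving the
#'   bolus shapes of the aortic and pulmonary components.
#' @return A list of class `ecd_subject`: `series`, `volume`, `template`,
#'   `truth` (class `ground_truth`) and a ready [analysis_config()] carrying
#'   the true calibration constants.
#' @export
simulate_subject <- function(segment_flow,
                             noise = c("none", "poisson"),
                             seed = 1L,
                             planar_dim = c(64, 64),
                             n_frames = 120,
                             frame_duration_s = 1,
                             spect_dim = c(32, 32, 32),
                             lassen_alpha = 1.5,
                             bpi_scale = 2000,
                             normal_side = "left",
                             basal_ganglia_segments = c("lenticular_nucleus",
                                                        "thalamus"),
                             aortic_peak_counts = 1000,
                             spect_bg_counts = 400,
                             input_shape = default_input_shape(),
                             pulmonary_shape = default_pulmonary_shape()) {
  noise <- match.arg(noise)
  template <- make_srt_template(spect_dim)
  seg_names <- template$segments$name
  missing <- setdiff(names(segment_flow), seg_names)
  if (length(missing))
    stop("segments in truth absent from template: ",
         paste(missing, collapse = ", "))
  if (!all(seg_names %in% names(segment_flow)))
    stop("`segment_flow` must name all ", length(seg_names), " segments")
  segment_flow <- segment_flow[seg_names]
  if (any(segment_flow <= .IBUR_INTERCEPT))
    stop("all segment flows must exceed the calibration floor of ",
         .IBUR_INTERCEPT, " ml/100g/min")

  cfg0 <- analysis_config(lassen_alpha = lassen_alpha, bpi_scale = bpi_scale,
                          normal_side = normal_side,
                          basal_ganglia_segments = basal_ganglia_segments)
  bg <- bg_segments(cfg0, template)
  true_mcbf <- mean(segment_flow[bg])
  ## flows at or below the PP calibration floor of 19.8 ml/100g/min have no
  ## representable BPI; such subjects get a minimal positive uptake slope,
  ## so the PP readout overestimates them — the method's real low-flow
  ## behaviour
  bpi_true <- max((true_mcbf - .PP_INTERCEPT) / .PP_SLOPE, 0.1)
  ku_true <- bpi_true / bpi_scale

  ## ---- planar scene -------------------------------------------------------
  scene <- planar_scene(planar_dim)
  times <- (seq_len(n_frames) - 0.5) * frame_duration_s
  g_peak <- function(sh) (sh$alpha * sh$beta)^sh$alpha * exp(-sh$alpha)
  roi <- roi_mask(scene$aorta_center, 4, planar_dim)
  d2 <- (roi$mask[, 1] - scene$aorta_center[1])^2 +
    (roi$mask[, 2] - scene$aorta_center[2])^2
  w_roi <- sum(aorta_taper(d2))
  k_a <- aortic_peak_counts / (w_roi * g_peak(input_shape))
  k_p <- 0.7 * k_a * g_peak(input_shape) / g_peak(pulmonary_shape)

  ## pulmonary spill into the aortic ROI (uniform pulmonary disc)
  dp2 <- (roi$mask[, 1] - scene$pulm_center[1])^2 +
    (roi$mask[, 2] - scene$pulm_center[2])^2
  n_overlap <- sum(dp2 <= scene$pulm_radius^2 + 1e-9)
  input_params <- gamma_params(w_roi * k_a, input_shape$alpha,
                               input_shape$beta, input_shape$t0)
  pulm_tac_params <- if (n_overlap > 0)
    gamma_params(n_overlap * k_p, pulmonary_shape$alpha,
                 pulmonary_shape$beta, pulmonary_shape$t0) else NULL
  input_counts_true <- gamma_integral(input_params)

  pulm_px <- disc_pixels(scene$pulm_center, scene$pulm_radius, planar_dim)
  brain_px <- disc_pixels(scene$brain_center, scene$brain_radius, planar_dim)
  a_rows <- matrix(seq_len(planar_dim[1]), planar_dim[1], planar_dim[2])
  a_cols <- matrix(seq_len(planar_dim[2]), planar_dim[1], planar_dim[2],
                   byrow = TRUE)
  a_d2 <- (a_rows - scene$aorta_center[1])^2 +
    (a_cols - scene$aorta_center[2])^2
  aorta_px <- which(a_d2 <= scene$aorta_radius^2 + 1e-9)
  aorta_w <- aorta_taper(a_d2[aorta_px])

  pulm_curve <- gamma_value(gamma_params(k_p, pulmonary_shape$alpha,
                                         pulmonary_shape$beta,
                                         pulmonary_shape$t0), times)
  aorta_curve <- gamma_value(gamma_params(k_a, input_shape$alpha,
                                          input_shape$beta, input_shape$t0),
                             times)
  ## brain follows the microsphere model on the full measured input TAC
  brain_curve <- ku_true * (gamma_cumint(input_params, times) +
                              if (is.null(pulm_tac_params)) 0 else
                                gamma_cumint(pulm_tac_params, times))

  frames <- array(0, dim = c(n_frames, planar_dim))
  npx <- prod(planar_dim)
  for (i in seq_len(n_frames)) {
    fr <- numeric(npx)
    fr[pulm_px] <- fr[pulm_px] + pulm_curve[i]
    fr[aorta_px] <- fr[aorta_px] + aorta_curve[i] * aorta_w
    fr[brain_px] <- fr[brain_px] + brain_curve[i]
    frames[i, , ] <- fr
  }

  ## ---- SPECT volume via inverse Lassen ------------------------------------
  ## Target corrected counts proportional to (flow - floor); the scalar c0
  ## puts the basal-ganglia reference near spect_bg_counts.
  c0 <- spect_bg_counts / (true_mcbf - .IBUR_INTERCEPT)
  f_target <- c0 * (segment_flow - .IBUR_INTERCEPT)
  raw_of <- function(R) (1 + lassen_alpha) * R * f_target /
    (lassen_alpha * R + f_target)
  ref <- uniroot(function(R) mean(raw_of(R)[bg]) - R,
                 interval = c(min(f_target[bg]) / 2, max(f_target[bg]) * 2),
                 tol = 1e-12)$root
  raw_counts <- raw_of(ref)
  voxels <- array(0, dim = spect_dim)
  for (k in seq_along(seg_names))
    voxels[template$labels == k] <- raw_counts[k]

  ccf_true <- input_counts_true / (.IBUR_SLOPE * c0)

  if (noise == "poisson") {
    set.seed(seed)
    frames[] <- rpois(length(frames), frames)
    voxels[] <- rpois(length(voxels), voxels)
  }

  series <- dynamic_planar_series(frames, frame_duration_s)
  volume <- spect_volume(voxels)
  truth <- structure(
    list(segment_flow = segment_flow, true_mcbf = true_mcbf,
         input_params = input_params, pulmonary_params = pulm_tac_params,
         ccf_true = ccf_true, lassen_alpha_true = lassen_alpha,
         ku_true = ku_true, input_counts_true = input_counts_true,
         aorta_center = scene$aorta_center, brain_center = scene$brain_center,
         spect_raw_counts = raw_counts),
    class = "ground_truth")
  config <- analysis_config(
    lassen_alpha = lassen_alpha, ccf = ccf_true,
    basal_ganglia_segments = basal_ganglia_segments,
    normal_side = normal_side, bpi_scale = bpi_scale,
    pp_input_roi = scene$aorta_center,
    pp_hemisphere_roi = scene$brain_center,
    pp_hemisphere_diameter_px = max(4, round(scene$brain_radius)),
    seed = seed)
  structure(list(series = series, volume = volume, template = template,
                 truth = truth, config = config),
            class = "ecd_subject")
}

#' @export
print.ecd_subject <- function(x, ...) {
  cat(sprintf("Simulated subject: true mCBF %.1f ml/100g/min, Ku %.3g /s\n",
              x$truth$true_mcbf, x$truth$ku_true))
  invisible(x)
}

#' Draw a per-segment flow map around a target mean CBF
#'
#' Segment flows are the target multiplied by independent lognormal-like
#' relative perturbations (normal on the relative scale, floored well above
#' the calibration floor).
#'
#' @param mcbf_target Target mean flow, ml/100g/min.
#' @param rel_sd Relative standard deviation of regional variation
#'   (default 0.12, giving a regional spread comparable to clinical series).
#' @param seed Integer seed.
#' @return Named numeric vector over [srt_segment_names()].
#' @export
make_segment_flows <- function(mcbf_target, rel_sd = 0.12, seed = 1L) {
  nm <- srt_segment_names()
  set.seed(seed)
  flows <- mcbf_target * (1 + rnorm(length(nm), 0, rel_sd))
  flows <- pmax(flows, 8)
  setNames(flows, nm)
}

#' Simulate a cohort of subjects
#'
#' Per-subject true mean CBF drawn uniformly from `flow_range`; per-segment
#' flows perturbed around it. Reproducible from `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param flow_range `(lo, hi)` of true mCBF, ml/100g/min; default (19, 45),
#'   the span seen in clinical mCBF series. Must lie within 10-70.
#' @param seed Integer seed.
#' @param noise Passed to [simulate_subject()].
#' @param rel_sd Regional relative spread, passed to [make_segment_flows()].
#' @param ... Further arguments for [simulate_subject()].
#' @return List of `ecd_subject` bundles.
#' @export
simulate_cohort <- function(n_subjects, flow_range = c(19, 45), seed = 1L,
                            noise = "none", rel_sd = 0.12, ...) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  if (length(flow_range) != 2L || diff(flow_range) < 0)
    stop("`flow_range` must be (lo, hi) with lo <= hi")
  if (flow_range[1] < 10 || flow_range[2] > 70)
    stop("`flow_range` must lie within the physiological 10-70 ml/100g/min")
  set.seed(seed)
  mcbf <- runif(n_subjects, flow_range[1], flow_range[2])
  sub_seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    flows <- make_segment_flows(mcbf[i], rel_sd = rel_sd,
                                seed = sub_seeds[i])
    simulate_subject(flows, noise = noise, seed = sub_seeds[i], ...)
  })
}
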