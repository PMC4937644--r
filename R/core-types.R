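#' Dynamic planar series
#'
#' Container for a dynamic planar radionuclide angiography acquisition: a
#' stack of 2-D count frames on a fixed grid with a uniform frame duration.
#' This is the source of every time-activity curve in the pipelines.
#'
#' @param frames Numeric 3-D array indexed `[frame, row, col]`; counts must be
#'   non-negative.
#' @param frame_duration_s Seconds per frame (> 0).
#' @param start_time_s Acquisition start offset in seconds (default 0).
#' @param pixel_size_mm Square pixel edge in millimetres.
#'
#' @return An object of class `dynamic_planar_series`.
#' @export
dynamic_planar_series <- function(frames, frame_duration_s,
                                  start_time_s = 0, pixel_size_mm = 4) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array indexed [frame, row, col]")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame counts must be finite and non-negative")
  if (!is.numeric(frame_duration_s) || length(frame_duration_s) != 1L ||
      frame_duration_s <= 0)
    stop("`frame_duration_s` must be a single positive number")
  structure(
    list(frames = frames,
         frame_duration_s = as.numeric(frame_duration_s),
         start_time_s = as.numeric(start_time_s),
         pixel_size_mm = as.numeric(pixel_size_mm)),
    class = "dynamic_planar_series")
}

#' @export
print.dynamic_planar_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Dynamic planar series: %d frames of %dx%d px, %.3g s/frame (%.3g mm px)\n",
              d[1], d[2], d[3], x$frame_duration_s, x$pixel_size_mm))
  invisible(x)
}

#' Frame mid-times of a dynamic series
#'
#' Sample times assigned to each frame: the frame midpoint
#' `start + (i - 0.5) * duration`, the convention used for all TACs.
#'
#' @param series A [dynamic_planar_series()].
#' @return Numeric vector of mid-frame times in seconds.
#' @export
frame_times <- function(series) {
  n <- dim(series$frames)[1]
  series$start_time_s + (seq_len(n) - 0.5) * series$frame_duration_s
}

#' SPECT volume
#'
#' A reconstructed brain SPECT count volume. Reconstruction itself (OSEM,
#' filtering, attenuation) is upstream of this package; voxel values are
#' taken as reconstructed counts.
#'
#' @param voxels Non-negative numeric 3-D array.
#' @param voxel_size_mm Per-axis voxel size (length 1 or 3), millimetres.
#' @param scan_midtime_min Scan mid-time in minutes post injection.
#' @return An object of class `spect_volume`.
#' @export
spect_volume <- function(voxels, voxel_size_mm = 2, scan_midtime_min = 30) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel values must be finite and non-negative")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  structure(
    list(voxels = voxels, voxel_size_mm = voxel_size_mm,
         scan_midtime_min = as.numeric(scan_midtime_min)),
    class = "spect_volume")
}

#' @export
print.spect_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("SPECT volume: %dx%dx%d voxels, mid-scan %g min\n",
              d[1], d[2], d[3], x$scan_midtime_min))
  invisible(x)
}

#' Canonical 24-segment names of the stereotaxic region template
#'
#' The 12 anatomical segments per hemisphere of the 3-D stereotaxic ROI
#' template used for regional readout, prefixed with the side
#' (`left_anterior`, ..., `right_cerebellum`). Label values 1..12 are the
#' left-side segments in this order, 13..24 the right side.
#'
#' @return Character vector of 24 segment names (left side first).
#' @export
srt_segment_names <- function() {
  base <- c("anterior", "precentral", "central", "parietal", "angular",
            "temporal", "occipital", "pericallosal", "lenticular_nucleus",
            "thalamus", "hippocampus", "cerebellum")
  c(paste0("left_", base), paste0("right_", base))
}

#' Region template
#'
#' Integer label volume aligned to a SPECT grid, with 12 segments per
#' hemisphere. Label 0 is background; label `k` maps to `segment_names[k]`.
#'
#' @param labels Integer 3-D array of labels in `0..length(segment_names)`.
#' @param segment_names Ordered segment names; defaults to
#'   [srt_segment_names()]. Must contain 12 `left_*` and 12 `right_*` names.
#' @return An object of class `region_template` with a `segments` table
#'   (label, name, side).
#' @export
region_template <- function(labels, segment_names = srt_segment_names()) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  side <- ifelse(grepl("^left_", segment_names), "left",
                 ifelse(grepl("^right_", segment_names), "right", NA))
  if (anyNA(side))
    stop("segment names must be prefixed 'left_' or 'right_'")
  if (sum(side == "left") != 12L || sum(side == "right") != 12L)
    stop("template must declare exactly 12 segments per side")
  if (anyDuplicated(segment_names))
    stop("segment names must be unique")
  lab <- as.integer(round(labels))
  if (any(lab < 0L) || any(lab > length(segment_names)))
    stop("labels outside 0..", length(segment_names),
         " do not map to a declared segment")
  present <- sort(unique(lab[lab > 0L]))
  missing <- setdiff(seq_along(segment_names), present)
  if (length(missing))
    stop("template is missing segments: ",
         paste(segment_names[missing], collapse = ", "))
  arr <- array(lab, dim = dim(labels))
  structure(
    list(labels = arr,
         segments = data.frame(label = seq_along(segment_names),
                               name = segment_names,
                               side = side,
                               stringsAsFactors = FALSE)),
    class = "region_template")
}

#' @export
print.region_template <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Region template: %dx%dx%d voxels, %d segments (%d per side)\n",
              d[1], d[2], d[3], nrow(x$segments), nrow(x$segments) / 2L))
  invisible(x)
}

#' Segment names on one side
#'
#' @param template A [region_template()].
#' @param side `"left"` or `"right"`.
#' @return Character vector of segment names on that side.
#' @export
segments_on_side <- function(template, side = c("left", "right")) {
  side <- match.arg(side)
  template$segments$name[template$segments$side == side]
}

#' Time-activity curve
#'
#' Counts sampled over a region of interest per dynamic frame. Counts are
#' ROI *totals* (summed over the mask) unless `kind` says otherwise; totals
#' preserve Poisson statistics for downstream integration.
#'
#' @param times_s Strictly increasing sample times (frame midpoints), s.
#' @param counts Non-negative counts, one per time.
#' @param roi Provenance ROI, or `NULL`.
#' @param kind `"total"` or `"mean"` — how ROI pixels were aggregated.
#' @return An object of class `time_activity_curve`.
#' @export
time_activity_curve <- function(times_s, counts, roi = NULL,
                                kind = c("total", "mean")) {
  kind <- match.arg(kind)
  if (length(times_s) != length(counts))
    stop("`times_s` and `counts` must have equal length")
  if (any(diff(times_s) <= 0))
    stop("`times_s` must be strictly increasing")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  structure(
    list(times_s = as.numeric(times_s), counts = as.numeric(counts),
         roi = roi, kind = kind),
    class = "time_activity_curve")
}

#' @export
print.time_activity_curve <- function(x, ...) {
  cat(sprintf("TAC: %d samples over [%.3g, %.3g] s, peak %.4g (%s counts)\n",
              length(x$counts), min(x$times_s), max(x$times_s),
              max(x$counts), x$kind))
  invisible(x)
}

#' Analysis configuration
#'
#' All tunable constants of the two quantification pipelines. Defaults hold
#' the package-wide conventions; everything is overridable, and a YAML file
#' with any subset of fields can be read with [read_config()].
#'
#' @param lassen_alpha Dimensionless Lassen linearization constant (> 0);
#'   default 1.5, the classical value.
#' @param ccf Planar-to-SPECT cross-calibration factor (> 0).
#' @param basal_ganglia_segments Base segment names (without side prefix)
#'   averaged for mCBF and used as the Lassen reference; default the two deep
#'   grey segments, lenticular nucleus and thalamus.
#' @param normal_side `"left"` or `"right"`: the clinically normal hemisphere
#'   used for mCBF.
#' @param bpi_scale BPI normalization constant: `BPI = bpi_scale * Ku`.
#' @param patlak_fit_window Optional integer index range (into retained Patlak
#'   points) for the slope fit; `NULL` means from the post-input-peak point on.
#' @param pp_input_roi `(row, col)` centre of the manually placed PP aortic
#'   input ROI, or `NULL` to reuse automatic detection.
#' @param pp_hemisphere_roi `(row, col)` centre of the hemispheric output ROI.
#' @param pp_hemisphere_diameter_px Diameter of the hemispheric ROI, pixels.
#' @param pp_input_integral `"tac"` (trapezoidal raw-TAC cumulative integral,
#'   default) or `"gamma"` (use the fitted second-peak gamma variate).
#' @param roi_diameter_px Diameter of arterial input ROIs, pixels.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(lassen_alpha = 1.5,
                            ccf = 1,
                            basal_ganglia_segments = c("lenticular_nucleus",
                                                       "thalamus"),
                            normal_side = c("left", "right"),
                            bpi_scale = 2000,
                            patlak_fit_window = NULL,
                            pp_input_roi = NULL,
                            pp_hemisphere_roi = NULL,
                            pp_hemisphere_diameter_px = 10,
                            pp_input_integral = c("tac", "gamma"),
                            roi_diameter_px = 4,
                            seed = 1L) {
  normal_side <- match.arg(normal_side)
  pp_input_integral <- match.arg(pp_input_integral)
  if (lassen_alpha <= 0) stop("`lassen_alpha` must be > 0")
  if (ccf <= 0) stop("`ccf` must be > 0")
  if (bpi_scale <= 0) stop("`bpi_scale` must be > 0")
  if (!length(basal_ganglia_segments))
    stop("`basal_ganglia_segments` must be nonempty")
  structure(
    list(lassen_alpha = lassen_alpha, ccf = ccf,
         basal_ganglia_segments = basal_ganglia_segments,
         normal_side = normal_side, bpi_scale = bpi_scale,
         patlak_fit_window = patlak_fit_window,
         pp_input_roi = pp_input_roi,
         pp_hemisphere_roi = pp_hemisphere_roi,
         pp_hemisphere_diameter_px = pp_hemisphere_diameter_px,
         pp_input_integral = pp_input_integral,
         roi_diameter_px = roi_diameter_px,
         seed = as.integer(seed)),
    class = "analysis_config")
}

## Basal-ganglia segment names on the configured normal side, validated
## against a template.
bg_segments <- function(config, template) {
  nm <- paste0(config$normal_side, "_", config$basal_ganglia_segments)
  missing <- setdiff(nm, template$segments$name)
  if (length(missing))
    stop("basal-ganglia segments absent from template: ",
         paste(missing, collapse = ", "))
  nm
}
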