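## File I/O: NIfTI images (via RNifti), YAML configs/sidecars, CSV TACs.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Write a dynamic planar series to NIfTI (+ YAML sidecar)
#'
#' The frame stack is stored as a 4-D NIfTI volume `(row, col, 1, frame)`;
#' the timebase and pixel size go into a YAML sidecar next to the image so
#' that integer counts and timing survive a round trip exactly.
#'
#' @param series A [dynamic_planar_series()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_dynamic_series <- function(series, path) {
  d <- dim(series$frames)
  arr <- aperm(series$frames, c(2, 3, 1))
  dim(arr) <- c(d[2], d[3], 1L, d[1])
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  yaml::write_yaml(
    list(frame_duration_s = series$frame_duration_s,
         start_time_s = series$start_time_s,
         pixel_size_mm = series$pixel_size_mm),
    sidecar_path(path))
  invisible(path)
}

#' Read a dynamic planar series from NIfTI
#'
#' Expects a 4-D image with the time axis last. The frame duration comes from
#' the YAML sidecar written by [write_dynamic_series()] when present,
#' otherwise from the header's fourth pixdim entry.
#'
#' @param path A 4-D NIfTI file.
#' @return A [dynamic_planar_series()].
#' @export
read_dynamic_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) != 4L)
    stop("expected 4D dynamic series, got ", length(d), "D image")
  if (d[3] != 1L)
    stop("expected a planar stack (singleton third axis), got z = ", d[3])
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    duration <- meta$frame_duration_s
    start <- if (is.null(meta$start_time_s)) 0 else meta$start_time_s
    px <- if (is.null(meta$pixel_size_mm)) 4 else meta$pixel_size_mm
  } else {
    pd <- attr(img, "pixdim")
    duration <- if (length(pd) >= 4) pd[4] else NA_real_
    start <- 0
    px <- if (length(pd) >= 1) pd[1] else 4
  }
  if (!is.finite(duration) || duration <= 0)
    stop("nonpositive or missing frame duration for ", path)
  ## collapse the singleton z axis: arr[r, c, 1, f] -> frames[f, r, c]
  frames <- aperm(array(arr[, , 1, ], dim = d[c(1, 2, 4)]), c(3, 1, 2))
  dynamic_planar_series(frames, frame_duration_s = duration,
                        start_time_s = start, pixel_size_mm = px)
}

#' Write a SPECT volume or label template to NIfTI
#'
#' @param x A [spect_volume()] or [region_template()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "region_template")) x$labels else x$voxels
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a SPECT volume and its aligned region template
#'
#' Both files must be 3-D and on the same grid; the template must contain
#' every declared segment label and nothing else.
#'
#' @param vol_path 3-D NIfTI SPECT count volume.
#' @param tpl_path 3-D NIfTI integer label volume on the same grid.
#' @param segment_names Ordered segment names (default [srt_segment_names()]).
#' @param scan_midtime_min Scan mid-time metadata for the volume.
#' @return A list with elements `volume` ([spect_volume()]) and `template`
#'   ([region_template()]).
#' @export
read_volume_and_template <- function(vol_path, tpl_path,
                                     segment_names = srt_segment_names(),
                                     scan_midtime_min = 30) {
  for (p in c(vol_path, tpl_path))
    if (!file.exists(p)) stop("file not found: ", p)
  vox <- as.array(RNifti::readNifti(vol_path))
  lab <- as.array(RNifti::readNifti(tpl_path))
  if (length(dim(vox)) != 3L || length(dim(lab)) != 3L)
    stop("volume and template must both be 3D images")
  if (!identical(dim(vox), dim(lab)))
    stop("volume grid ", paste(dim(vox), collapse = "x"),
         " does not match template grid ", paste(dim(lab), collapse = "x"))
  list(volume = spect_volume(vox, scan_midtime_min = scan_midtime_min),
       template = region_template(lab, segment_names))
}

#' Read an analysis configuration from YAML
#'
#' Any subset of [analysis_config()] fields may appear in the file; absent
#' fields take the package defaults.
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to YAML
#'
#' @param config An [analysis_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Export / import a TAC as CSV
#'
#' Two-column CSV (`time_s`, `counts`), the interchange format for curves.
#'
#' @param tac A [time_activity_curve()].
#' @param path CSV path.
#' @return `path` (write) or a [time_activity_curve()] (read).
#' @export
write_tac_csv <- function(tac, path) {
  write.csv(data.frame(time_s = tac$times_s, counts = tac$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- read.csv(path)
  time_activity_curve(df$time_s, df$counts)
}
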