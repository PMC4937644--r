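#' Automatic ascending-aorta ROI detection
#'
#' Implements the automatic input-function placement: the arterial ROI is
#' the circular ROI centred on the pixel attaining the largest single-frame
#' count anywhere in the dynamic series (optionally restricted to a frame
#' window). Ties are broken by the earlier frame, then by row-major pixel
#' order, so the result is deterministic.
#'
#' @param series A [dynamic_planar_series()].
#' @param search_window Integer frame-index range (default all frames).
#' @param diameter_px ROI diameter (default 4 px).
#' @return An [roi_mask()] ROI at the max-count pixel.
#' @export
detect_aorta_roi <- function(series, search_window = NULL, diameter_px = 4) {
  d <- dim(series$frames)
  frames <- if (is.null(search_window)) seq_len(d[1]) else {
    search_window <- as.integer(search_window)
    if (any(search_window < 1) || any(search_window > d[1]))
      stop("`search_window` outside the frame range")
    seq(min(search_window), max(search_window))
  }
  if (all(series$frames[frames, , ] == 0))
    stop("no signal: dynamic series is uniformly zero over the search window")
  best <- c(-Inf, NA, NA, NA)  # value, frame, row, col
  for (f in frames) {
    fr <- series$frames[f, , ]
    m <- max(fr)
    if (m > best[1]) {
      hit <- which(fr == m, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      best <- c(m, f, hit[1], hit[2])
    }
  }
  roi_mask(c(best[3], best[4]), diameter_px, d[2:3])
}

#' Extract a time-activity curve over an ROI
#'
#' Counts are ROI totals per frame; sample times are frame midpoints.
#'
#' @param series A [dynamic_planar_series()].
#' @param roi An ROI from [roi_mask()] or [detect_aorta_roi()].
#' @return A [time_activity_curve()].
#' @export
extract_tac <- function(series, roi) {
  d <- dim(series$frames)
  if (any(roi$mask[, 1] > d[2]) || any(roi$mask[, 2] > d[3]))
    stop("ROI extends beyond the image grid")
  counts <- vapply(seq_len(d[1]), function(f) {
    fr <- series$frames[f, , ]
    sum(fr[roi$mask])
  }, numeric(1))
  time_activity_curve(frame_times(series), counts, roi = roi, kind = "total")
}

#' Extract a mean-count TAC over an ROI
#'
#' Like [extract_tac()] but averaging over the ROI, the convention for
#' hemispheric output curves.
#'
#' @inheritParams extract_tac
#' @return A [time_activity_curve()] with `kind = "mean"`.
#' @export
extract_tac_mean <- function(series, roi) {
  tot <- extract_tac(series, roi)
  time_activity_curve(tot$times_s, tot$counts / nrow(roi$mask),
                      roi = roi, kind = "mean")
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  h1 <- (window - 1) %/% 2
  h2 <- window - 1L - h1
  vapply(seq_len(n),
         function(i) mean(x[max(1, i - h1):min(n, i + h2)]),
         numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Separate the pulmonary and aortic bolus peaks of an input TAC
#'
#' The first-pass input TAC shows a pulmonary/lung peak before the
#' ascending-aorta peak. After light smoothing, the two tallest local maxima
#' (in time order) are taken as the peaks; the minimum between them is the
#' valley. The second-peak window runs from the valley to the point where the
#' curve first falls below `tail_fraction` of the second peak, truncating
#' before recirculation.
#'
#' @param tac A [time_activity_curve()].
#' @param smooth_window Moving-average width for peak detection (default 3).
#' @param tail_fraction Fraction of the second-peak height at which the
#'   window is truncated (default 0.3).
#' @return A list of class `peak_split`: `first_peak_window`,
#'   `second_peak_window` (integer index ranges), `valley_index`, and the
#'   detected `peak_indices`.
#' @export
split_peaks <- function(tac, smooth_window = 3, tail_fraction = 0.3) {
  y <- moving_average(tac$counts, smooth_window)
  peaks <- local_maxima(y)
  ## ignore maxima in the noise floor
  peaks <- peaks[y[peaks] > 0.05 * max(y)]
  if (length(peaks) < 2)
    stop("fewer than two peaks detected; supply manual windows via the config")
  ord <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  p1 <- min(ord); p2 <- max(ord)
  valley <- p1 + which.min(y[p1:p2]) - 1L
  if (y[valley] > 0.9 * y[p1])
    warning("heavily overlapped peaks: valley above 90% of the first peak")
  after <- which(y[(p2 + 1):length(y)] < tail_fraction * y[p2])
  end2 <- if (length(after)) p2 + min(after) - 1L else length(y)
  first_start <- which(y[1:p1] > 0.05 * y[p1])
  first_start <- if (length(first_start)) min(first_start) else 1L
  structure(
    list(first_peak_window = c(first_start, valley - 1L),
         second_peak_window = c(valley, end2),
         valley_index = valley,
         peak_indices = c(p1, p2)),
    class = "peak_split")
}

#' @export
print.peak_split <- function(x, ...) {
  cat(sprintf("Peak split: first %d..%d | valley %d | second %d..%d\n",
              x$first_peak_window[1], x$first_peak_window[2],
              x$valley_index,
              x$second_peak_window[1], x$second_peak_window[2]))
  invisible(x)
}
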