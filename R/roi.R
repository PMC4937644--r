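#' Circular pixel ROI
#'
#' Builds the discrete disc of a stated diameter on a pixel grid: the mask
#' contains exactly the pixels whose centres lie within `diameter_px / 2`
#' (Euclidean, inclusive) of the ROI centre, clipped to the grid. A diameter
#' of 4 pixels — the arterial input ROI of both quantification methods —
#' yields a 13-pixel disc in the grid interior.
#'
#' @param center `(row, col)` pixel coordinates of the centre (1-based).
#' @param diameter_px Integer diameter, >= 1.
#' @param grid_shape `(nrow, ncol)` of the image grid.
#' @return An object of class `roi` with fields `center`, `diameter_px` and
#'   `mask` (a two-column integer matrix of row/col indices).
#' @export
roi_mask <- function(center, diameter_px, grid_shape) {
  if (length(center) != 2L || length(grid_shape) != 2L)
    stop("`center` and `grid_shape` must each have length 2")
  if (diameter_px < 1) stop("`diameter_px` must be >= 1")
  if (center[1] < 1 || center[1] > grid_shape[1] ||
      center[2] < 1 || center[2] > grid_shape[2])
    stop("ROI center lies outside the image grid")
  r <- diameter_px / 2
  span <- floor(r)
  dr <- seq(-span, span)
  offsets <- expand.grid(dr = dr, dc = dr)
  offsets <- offsets[offsets$dr^2 + offsets$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  rows <- center[1] + offsets$dr
  cols <- center[2] + offsets$dc
  keep <- rows >= 1 & rows <= grid_shape[1] & cols >= 1 & cols <= grid_shape[2]
  mask <- cbind(row = as.integer(rows[keep]), col = as.integer(cols[keep]))
  mask <- mask[order(mask[, 1], mask[, 2]), , drop = FALSE]
  structure(list(center = as.numeric(center),
                 diameter_px = as.integer(diameter_px),
                 mask = mask),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI: %d px disc (diameter %d) at (%g, %g)\n",
              nrow(x$mask), x$diameter_px, x$center[1], x$center[2]))
  invisible(x)
}
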