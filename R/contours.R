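#' Closed planar contour polygon
#'
#' Carrier for one closed contour on one axial slice: ordered patient-space
#' points (mm), implicitly closed (last connects back to first).
#'
#' @param slice_index 1-based CT slice index the contour lies on.
#' @param points n x 3 matrix of (x, y, z) mm; all z equal (0.01 mm tol).
#' @return an object of class `contour_polygon`.
#' @export
contour_polygon <- function(slice_index, points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("a contour polygon needs at least 3 points")
  if (diff(range(points[, 3])) > 0.01)
    stop("contour points must share one z (0.01 mm tolerance)")
  structure(list(slice_index = as.integer(slice_index), points = points),
            class = "contour_polygon")
}

#' Rasterize contour polygons into a binary mask
#'
#' A pixel is set iff its center lies inside the polygon under the even-odd
#' rule; centers exactly on a boundary resolve by the half-open crossing rule
#' (deterministic, "strictly inside or on the entering edge").  Multiple
#' polygons on one slice are unioned.
#'
#' @param polygons list of [contour_polygon]s (may be empty).
#' @param volume the [ct_volume] defining the grid.
#' @return logical array with the volume's dimensions.
#' @export
contours_to_mask <- function(polygons, volume) {
  d <- dim(volume$voxels)
  mask <- array(FALSE, d)
  for (p in polygons) {
    if (!inherits(p, "contour_polygon")) p <- do.call(contour_polygon, p)
    s <- p$slice_index
    if (s < 1 || s > d[3]) stop("contour slice index out of range")
    if (abs(p$points[1, 3] - volume$slice_positions[s]) > 0.01)
      stop("contour z does not match its slice position")
    cr <- mm_to_colrow(p$points[, 1:2, drop = FALSE], volume)
    sl <- .cpp_fill_polygon(cr[, 1], cr[, 2], d[1], d[2])
    mask[, , s] <- mask[, , s] | sl
  }
  mask
}

#' Trace mask boundaries into closed contour polygons
#'
#' One closed polygon per connected region per slice, traced along the 0.5
#' iso-level of the binary image (midway between inside and outside pixel
#' centers), in patient coordinates.  Interior holes are filled: hole
#' contours are not emitted.
#'
#' @param mask binary array on the volume grid.
#' @param volume the [ct_volume] defining geometry.
#' @return list of [contour_polygon]s (empty for an empty mask).
#' @export
mask_to_contours <- function(mask, volume) {
  d <- dim(volume$voxels)
  stopifnot(identical(dim(mask), d))
  out <- list()
  for (s in seq_len(d[3])) {
    sl <- mask[, , s]
    if (!any(sl)) next
    # pad with a zero border so edge-touching regions close properly
    padded <- matrix(0, d[1] + 2, d[2] + 2)
    padded[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
    # grid coordinates = 0-based pixel indices of the padded image minus 1,
    # i.e. original 0-based (row, col) indices
    lines <- grDevices::contourLines(x = seq_len(d[1] + 2) - 2,
                                     y = seq_len(d[2] + 2) - 2,
                                     z = padded, levels = 0.5)
    if (length(lines) == 0) next
    keep <- drop_hole_contours(lines)
    z <- volume$slice_positions[s]
    for (ln in keep) {
      rr <- ln$x; cc <- ln$y
      n <- length(rr)
      if (n > 1 && rr[1] == rr[n] && cc[1] == cc[n]) { rr <- rr[-n]; cc <- cc[-n] }
      if (length(rr) < 3) next
      xy <- colrow_to_mm(cbind(cc, rr), volume)
      out[[length(out) + 1]] <- contour_polygon(s, cbind(xy, z))
    }
  }
  out
}

# Containment depth by even-odd point test of one vertex against the other
# loops; odd depth = hole, dropped (holes are filled on export).
drop_hole_contours <- function(lines) {
  n <- length(lines)
  if (n <= 1) return(lines)
  depth <- integer(n)
  for (i in seq_len(n)) {
    px <- lines[[i]]$x[1]; py <- lines[[i]]$y[1]
    for (j in seq_len(n)) {
      if (i == j) next
      if (point_in_loop(px, py, lines[[j]]$x, lines[[j]]$y))
        depth[i] <- depth[i] + 1L
    }
  }
  lines[depth %% 2L == 0L]
}

point_in_loop <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xcross <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}
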