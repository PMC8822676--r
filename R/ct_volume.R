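#' CT volume in Hounsfield units
#'
#' A calibrated 3D CT volume with the geometry metadata needed to tie voxel
#' masks back to DICOM patient space.  Voxels are stored as a numeric array
#' indexed `[row, col, slice]`.  Following the DICOM convention,
#' `ImagePositionPatient` addresses the *center* of the first transmitted
#' pixel, so voxel `(r, c)` (0-based) of slice `s` sits at patient position
#' `origin + c * col_spacing * row_dir + r * row_spacing * col_dir` with the
#' slice's own z from `slice_positions`.
#'
#' @param voxels numeric array `[row, col, slice]` of HU values (finite).
#' @param pixel_spacing length-2 numeric, (row mm, col mm).
#' @param slice_thickness slice thickness in mm.
#' @param slice_positions per-slice patient z (mm), strictly monotonic with
#'   uniform gaps (0.01 mm tolerance).
#' @param origin patient coordinates (mm) of the first voxel center of the
#'   first slice.
#' @param orientation direction cosines, length 6 (row direction then column
#'   direction); only axial-aligned volumes are supported.
#' @param sop_instance_uids per-slice SOP Instance UIDs.
#' @param series_uid,frame_of_reference_uid,study_uid,patient_id opaque
#'   identifiers.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_thickness, slice_positions,
                      origin, orientation = c(1, 0, 0, 0, 1, 0),
                      sop_instance_uids = NULL, series_uid = "",
                      frame_of_reference_uid = "", study_uid = "",
                      patient_id = "") {
  stopifnot(length(dim(voxels)) == 3, length(pixel_spacing) == 2)
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  n <- dim(voxels)[3]
  if (length(slice_positions) != n)
    stop("slice_positions length must equal number of slices")
  if (is.null(sop_instance_uids)) sop_instance_uids <- rep("", n)
  if (length(sop_instance_uids) != n)
    stop("one SOP instance UID per slice required")
  if (n >= 2) {
    gaps <- diff(slice_positions)
    if (!(all(gaps > 0) || all(gaps < 0)))
      stop("slice_positions must be strictly monotonic")
    if (max(abs(gaps - gaps[1])) > 0.01)
      stop("non-uniform slice spacing beyond 0.01 mm: positions ",
           paste(signif(slice_positions, 8), collapse = ", "))
  }
  check_axial(orientation)
  structure(list(
    voxels = voxels,
    pixel_spacing = as.numeric(pixel_spacing),
    slice_thickness = as.numeric(slice_thickness),
    slice_positions = as.numeric(slice_positions),
    origin = as.numeric(origin),
    orientation = as.numeric(orientation),
    sop_instance_uids = as.character(sop_instance_uids),
    series_uid = series_uid,
    frame_of_reference_uid = frame_of_reference_uid,
    study_uid = study_uid,
    patient_id = patient_id
  ), class = "ct_volume")
}

check_axial <- function(orientation) {
  if (max(abs(orientation - c(1, 0, 0, 0, 1, 0))) > 1e-3)
    stop("only axial-aligned series are supported (orientation cosines must ",
         "be within 1e-3 of (1,0,0)/(0,1,0))")
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d slices, %.4g x %.4g mm pixels, %.3g mm slices\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_thickness))
  cat(sprintf("  HU range [%.0f, %.0f], patient '%s'\n",
              min(x$voxels), max(x$voxels), x$patient_id))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Named binary masks aligned to a CT grid
#'
#' A structure set holds one binary 3D mask per region of interest (ROI),
#' all on the grid of a single [ct_volume], plus the ROI metadata needed for
#' RT Structure Set round-tripping.
#'
#' @param rois named list of binary arrays with the CT's dimensions, or of
#'   lists `list(mask =, roi_number =, color =)`.
#' @param ct the referenced [ct_volume] (geometry is copied, not the voxels).
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(rois, ct) {
  stopifnot(inherits(ct, "ct_volume"), is.list(rois))
  if (length(rois) && is.null(names(rois))) stop("rois must be named")
  palette <- default_roi_colors(max(1L, length(rois)))
  out <- vector("list", length(rois))
  names(out) <- names(rois)
  nums <- integer(0)
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (!is.list(r)) r <- list(mask = r)
    if (is.null(r$roi_number)) r$roi_number <- i
    if (is.null(r$color)) r$color <- palette[[i %% length(palette) + 1L]]
    m <- r$mask
    if (!identical(dim(m), dim(ct$voxels)))
      stop("mask '", names(rois)[i], "' does not match the CT grid")
    storage.mode(m) <- "logical"
    if (anyNA(m)) stop("mask values must be 0/1")
    r$mask <- m
    nums <- c(nums, as.integer(r$roi_number))
    out[[i]] <- r
  }
  if (anyDuplicated(nums) || any(nums <= 0))
    stop("roi_numbers must be unique and positive")
  structure(list(
    rois = out,
    ct_ref = list(series_uid = ct$series_uid,
                  frame_of_reference_uid = ct$frame_of_reference_uid,
                  dim = dim(ct$voxels))
  ), class = "structure_set")
}

default_roi_colors <- function(n) {
  base <- list(c(255L, 0L, 0L), c(0L, 255L, 0L), c(0L, 0L, 255L),
               c(255L, 255L, 0L), c(255L, 0L, 255L), c(0L, 255L, 255L),
               c(255L, 128L, 0L), c(128L, 0L, 255L))
  rep(base, length.out = n)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROI(s) on a %s grid\n", length(x$rois),
              paste(x$ct_ref$dim, collapse = " x ")))
  for (nm in names(x$rois))
    cat(sprintf("  %-24s #%d, %d voxels\n", nm, x$rois[[nm]]$roi_number,
                sum(x$rois[[nm]]$mask)))
  invisible(x)
}

# Patient-coordinate helpers (axial orientation).  Continuous pixel index:
# col index c maps to x = origin[1] + c * col_spacing, row index r to
# y = origin[2] + r * row_spacing (0-based indices at pixel centers).
mm_to_colrow <- function(xy, volume) {
  cbind((xy[, 1] - volume$origin[1]) / volume$pixel_spacing[2],
        (xy[, 2] - volume$origin[2]) / volume$pixel_spacing[1])
}

colrow_to_mm <- function(colrow, volume) {
  cbind(volume$origin[1] + colrow[, 1] * volume$pixel_spacing[2],
        volume$origin[2] + colrow[, 2] * volume$pixel_spacing[1])
}

match_slice <- function(z, volume, tol = 0.01) {
  i <- which(abs(volume$slice_positions - z) <= tol)
  if (length(i) != 1)
    stop(sprintf("contour z = %.4f mm matches no CT slice (tolerance %.2g mm)",
                 z, tol))
  i
}
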