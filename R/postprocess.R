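#' Threshold a probability volume
#'
#' A voxel is set iff its probability is `>= threshold` (0.33 by default;
#' the tie at exactly the threshold counts positive).
#'
#' @param pred a `prediction_volume` or probability array in `[0, 1]`.
#' @param threshold scalar in (0, 1).
#' @return logical array.
#' @export
binarize <- function(pred, threshold = 0.33) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be inside (0, 1)")
  probs <- if (inherits(pred, "prediction_volume")) pred$probs else pred
  probs >= threshold
}

#' Keep only the largest connected component
#'
#' Retains the largest 26-connected 3D component; discontinuous positive
#' voxels are discarded as outliers.  Size ties break to the component with
#' the smallest minimum slice index, then smallest minimum row index.
#'
#' @param mask binary 3D array.
#' @return logical array with at most one component.
#' @export
largest_component <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2) { dim(mask) <- c(d, 1L); d <- dim(mask) }
  if (!any(mask)) return(array(FALSE, d))
  lab <- .cpp_label_components(as.logical(mask), as.integer(d))
  ord <- order(-lab$size, lab$min_slice, lab$min_row)
  array(lab$labels == ord[1], d)
}

#' Axial height of a mask in mm
#'
#' `(max positive slice - min positive slice + 1) * slice_thickness`;
#' 0 for an empty mask.
#'
#' @param mask binary 3D array.
#' @param slice_thickness mm, or a [ct_volume] to take it from.
#' @return height in mm.
#' @export
measure_height <- function(mask, slice_thickness) {
  if (inherits(slice_thickness, "ct_volume"))
    slice_thickness <- slice_thickness$slice_thickness
  pos <- which(apply(mask, 3, any))
  if (length(pos) == 0) return(0)
  (max(pos) - min(pos) + 1) * slice_thickness
}

#' Fit organ height statistics from training masks
#'
#' Mean and sample standard deviation (n - 1 denominator) of
#' [measure_height()] across patients; the basis of the axial limit.
#'
#' @param masks list of binary 3D arrays, one per patient (all nonempty).
#' @param slice_thickness mm (scalar or per-patient vector).
#' @param organ organ name recorded on the result.
#' @return list of class `height_stats`: organ, height_mean, height_sd, n.
#' @export
fit_height_stats <- function(masks, slice_thickness, organ = NA_character_) {
  if (length(masks) < 2) stop("height statistics need at least 2 patients")
  th <- rep_len(slice_thickness, length(masks))
  h <- vapply(seq_along(masks), function(i) measure_height(masks[[i]], th[i]), 0)
  if (any(h == 0)) stop("empty mask in height-statistics input")
  structure(list(organ = organ, height_mean = mean(h), height_sd = sd(h),
                 n = length(masks)), class = "height_stats")
}

#' @export
print.height_stats <- function(x, ...) {
  cat(sprintf("<height_stats> %s: %.1f +/- %.1f mm (n = %d)\n",
              x$organ, x$height_mean, x$height_sd, x$n))
  invisible(x)
}

#' Cap a mask's axial extent at mean + k SD of training heights
#'
#' If the measured height exceeds `height_mean + k * height_sd`, positive
#' slices farthest from the mask's center-of-mass slice are removed
#' (alternating between the far ends, ties toward the superior end) until
#' the height fits; prediction data in excess of the limit are discarded.
#' Run after [largest_component()].
#'
#' @param mask binary 3D array (single component).
#' @param stats a [fit_height_stats()] result.
#' @param k SD multiplier, 1 or 2.
#' @param slice_thickness mm.
#' @return trimmed logical array.
#' @export
apply_axial_limit <- function(mask, stats, k = 2, slice_thickness) {
  if (!k %in% c(1, 2)) stop("k must be 1 or 2")
  limit <- stats$height_mean + k * stats$height_sd
  counts <- apply(mask, 3, sum)
  pos <- which(counts > 0)
  if (length(pos) == 0) return(mask)
  com <- sum(pos * counts[pos]) / sum(counts[pos])
  keep <- pos
  while (length(keep) > 1 &&
         (max(keep) - min(keep) + 1) * slice_thickness > limit) {
    lo <- min(keep); hi <- max(keep)
    # superior end = larger slice index; ties trim superior first
    drop <- if ((hi - com) >= (com - lo)) hi else lo
    keep <- setdiff(keep, drop)
  }
  out <- mask
  out[, , setdiff(seq_len(dim(mask)[3]), keep)] <- FALSE
  out
}

#' Full post-processing of a probability volume
#'
#' [binarize()] at 0.33, [largest_component()], then [apply_axial_limit()]
#' for the organs subject to the height cap (parotid and submandibular
#' glands, brainstem, larynx), using the height statistics stored on the
#' organ config or passed explicitly.
#'
#' @param pred a `prediction_volume` or probability array.
#' @param organ an [organ_config()].
#' @param stats optional [fit_height_stats()]; defaults to the organ's
#'   stored height stats.
#' @param slice_thickness mm (needed when the axial limit applies).
#' @param threshold binarization threshold.
#' @return cleaned logical array (at most one component).
#' @export
postprocess_prediction <- function(pred, organ, stats = NULL,
                                   slice_thickness = NULL, threshold = 0.33) {
  mask <- largest_component(binarize(pred, threshold))
  if (is.na(organ$axial_k)) return(mask)
  if (is.null(stats)) {
    if (is.na(organ$height_mean))
      stop("organ '", organ$name, "' uses an axial limit but has no height stats")
    stats <- list(height_mean = organ$height_mean, height_sd = organ$height_sd)
  }
  if (is.null(slice_thickness))
    stop("slice_thickness is required for the axial limit")
  apply_axial_limit(mask, stats, organ$axial_k, slice_thickness)
}
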