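#' Window/level presets
#'
#' The normalization windows used before training and inference: the HU
#' interval `[L - W/2, L + W/2]` maps linearly onto `[0, 1]`.  The shipped
#' presets are the tissue filter (W/L 400/40) used for most organs and the
#' bone filter (W/L 2000/400) used for the spinal cord and brachial plexus.
#'
#' @param name `"tissue"` or `"bone"`, or pass `width`/`level` directly.
#' @param width,level window width and level in HU (width > 0).
#' @return list with `name`, `width`, `level`.
#' @export
window_preset <- function(name = c("tissue", "bone"), width = NULL, level = NULL) {
  if (is.null(width)) {
    name <- match.arg(name)
    width <- switch(name, tissue = 400, bone = 2000)
    level <- switch(name, tissue = 40, bone = 400)
  } else {
    name <- if (is.character(name)) name else "custom"
  }
  if (width <= 0) stop("window width must be positive")
  list(name = name, width = width, level = level)
}

#' Resample a CT volume in-plane to 1 mm pixels
#'
#' Bilinear interpolation onto a 1 x 1 mm grid that shares the first pixel
#' center with the input; output dimensions are `round(dim * spacing)`.
#' Through-plane geometry is untouched (2D slice model).
#'
#' @param volume a [ct_volume].
#' @return a [ct_volume] with `pixel_spacing == c(1, 1)`.
#' @export
resample_inplane <- function(volume) {
  sp <- volume$pixel_spacing
  if (any(sp <= 0)) stop("pixel spacing must be positive")
  d <- dim(volume$voxels)
  if (all(abs(sp - 1) < 1e-12)) return(volume)
  nr <- round(d[1] * sp[1]); nc <- round(d[2] * sp[2])
  vox <- array(0, c(nr, nc, d[3]))
  for (s in seq_len(d[3]))
    vox[, , s] <- .cpp_resample_bilinear(volume$voxels[, , s], sp[1], sp[2], nr, nc)
  out <- volume
  out$voxels <- vox
  out$pixel_spacing <- c(1, 1)
  out
}

#' Resample a binary mask in-plane to 1 mm pixels
#'
#' Nearest-neighbor companion of [resample_inplane()] so labels follow the
#' image geometry while staying binary.
#'
#' @param mask binary 3D (or 2D) array.
#' @param spacing length-2 (row mm, col mm) spacing of `mask`.
#' @return resampled logical array.
#' @export
resample_mask_inplane <- function(mask, spacing) {
  if (any(spacing <= 0)) stop("pixel spacing must be positive")
  two_d <- length(dim(mask)) == 2 || is.null(dim(mask))
  if (two_d) mask <- array(mask, c(dim(mask)[1] %||% length(mask), ncol(mask) %||% 1, 1))
  d <- dim(mask)
  nr <- round(d[1] * spacing[1]); nc <- round(d[2] * spacing[2])
  out <- array(FALSE, c(nr, nc, d[3]))
  for (s in seq_len(d[3])) {
    m <- matrix(as.integer(mask[, , s]), d[1], d[2])
    out[, , s] <- .cpp_resample_nearest(m, spacing[1], spacing[2], nr, nc) > 0
  }
  if (two_d) out <- out[, , 1]
  out
}

#' Crop or pad a 2D image to its centermost `size x size` pixels
#'
#' Inputs larger than `size` keep the central window (offset
#' `floor((dim - size)/2)`); smaller inputs are padded symmetrically with
#' `pad_value` (air, -1000 HU, by default).
#'
#' @param image2d numeric matrix.
#' @param size output edge length (default 256).
#' @param pad_value fill value for undersized inputs.
#' @return `size x size` matrix.
#' @export
center_crop <- function(image2d, size = 256, pad_value = -1000) {
  d <- dim(image2d)
  out <- matrix(pad_value, size, size)
  # source window
  r_off <- max(0L, floor((d[1] - size) / 2))
  c_off <- max(0L, floor((d[2] - size) / 2))
  nr <- min(d[1], size); nc <- min(d[2], size)
  # destination offset for undersized inputs
  dr <- max(0L, floor((size - d[1]) / 2))
  dc <- max(0L, floor((size - d[2]) / 2))
  out[dr + seq_len(nr), dc + seq_len(nc)] <-
    image2d[r_off + seq_len(nr), c_off + seq_len(nc)]
  out
}

# Offsets of the crop window in the resampled grid, shared by the forward
# preprocessing chain and the inverse mapping in predict_volume().
crop_offsets <- function(d, size = 256) {
  c(row = max(0L, floor((d[1] - size) / 2)) - max(0L, floor((size - d[1]) / 2)),
    col = max(0L, floor((d[2] - size) / 2)) - max(0L, floor((size - d[2]) / 2)))
}

#' Window/level normalization of an HU image
#'
#' Maps `[L - W/2, L + W/2]` linearly onto `[0, 1]`, clamping outside values.
#'
#' @param image2d HU values (finite).
#' @param preset a [window_preset()].
#' @return values in `[0, 1]`, same shape.
#' @export
window_normalize <- function(image2d, preset = window_preset("tissue")) {
  if (preset$width <= 0) stop("window width must be positive")
  lo <- preset$level - preset$width / 2
  out <- (image2d - lo) / preset$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Select training slices for one organ
#'
#' All slices carrying at least one positive label pixel are kept; of the
#' remaining empty slices, enumerated ascending, every 20th (positions 0,
#' 20, 40, ... of the empty-slice list) is added so the network also sees
#' organ-free anatomy without skewing the training focus.
#'
#' @param label_volume binary 3D array.
#' @param stride keep every `stride`-th empty slice (default 20).
#' @return sorted integer slice indices; an all-empty volume yields an empty
#'   vector with attribute `organ_absent = TRUE` so callers can exclude the
#'   patient from this organ's training set.
#' @export
select_training_slices <- function(label_volume, stride = 20L) {
  counts <- apply(label_volume, 3, sum)
  positive <- which(counts > 0)
  if (length(positive) == 0) {
    out <- integer(0)
    attr(out, "organ_absent") <- TRUE
    return(out)
  }
  empty <- which(counts == 0)
  picked <- empty[seq_along(empty) %% stride == 1L]
  if (stride == 1L) picked <- empty
  sort(c(positive, picked))
}

#' Preprocess one CT volume for one organ
#'
#' The full chain of the training/inference representation: in-plane
#' resampling to 1 mm, center 256 x 256 crop, window/level normalization.
#' Returns the normalized image stack plus the geometry needed to invert the
#' mapping.
#'
#' @param volume a [ct_volume].
#' @param window a [window_preset()].
#' @param size crop size (default 256).
#' @return list: `images` (size x size x n_slices in `[0,1]`), `resampled_dim`,
#'   `offsets` (crop offsets in the resampled grid), `spacing` (native).
#' @export
preprocess_volume <- function(volume, window = window_preset("tissue"),
                              size = 256) {
  res <- resample_inplane(volume)
  d <- dim(res$voxels)
  off <- crop_offsets(d[1:2], size)
  images <- array(0, c(size, size, d[3]))
  for (s in seq_len(d[3]))
    images[, , s] <- window_normalize(center_crop(res$voxels[, , s], size), window)
  list(images = images, resampled_dim = d[1:2], offsets = off,
       spacing = volume$pixel_spacing)
}

# Label companion: resample NN + crop with 0 padding.
preprocess_labels <- function(mask, spacing, size = 256) {
  res <- resample_mask_inplane(mask, spacing)
  d <- dim(res)
  out <- array(FALSE, c(size, size, d[3]))
  for (s in seq_len(d[3]))
    out[, , s] <- center_crop(res[, , s] * 1, size, pad_value = 0) > 0.5
  out
}

#' Build per-organ training and validation sample sets
#'
#' Applies the full preprocessing chain to each patient carrying the organ,
#' selects training slices, and splits off the last 15% of *patients*
#' (stable input order, `ceil(0.15 n)`) as validation, so no patient
#' contributes slices to both partitions.
#'
#' @param patients list of `list(ct = ct_volume, ss = structure_set,
#'   id = character)`.
#' @param organ an [organ_config()]; its `name` must match an ROI name
#'   (case-insensitive).
#' @param val_fraction validation fraction at patient granularity.
#' @param size crop size.
#' @return list with `train` and `validation`, each a list of samples
#'   `list(image, label, organ, patient_id, slice_index)`.
#' @export
build_dataset <- function(patients, organ, val_fraction = 0.15, size = 256) {
  eligible <- list()
  for (p in patients) {
    nm <- match_roi_name(organ$name, names(p$ss$rois))
    if (is.na(nm)) next
    if (!any(p$ss$rois[[nm]]$mask)) next
    eligible[[length(eligible) + 1]] <- list(ct = p$ct, id = p$id %||% p$ct$patient_id,
                                             mask = p$ss$rois[[nm]]$mask)
  }
  if (length(eligible) < 2)
    stop("need at least 2 patients carrying organ '", organ$name, "'")
  n_val <- ceiling(val_fraction * length(eligible))
  if (n_val >= length(eligible)) n_val <- length(eligible) - 1
  window <- window_preset(organ$window)
  make_samples <- function(pt) {
    prep <- preprocess_volume(pt$ct, window, size)
    labels <- preprocess_labels(pt$mask, pt$ct$pixel_spacing, size)
    idx <- select_training_slices(labels)
    lapply(idx, function(s) list(
      image = prep$images[, , s], label = labels[, , s],
      organ = organ$name, patient_id = pt$id, slice_index = s))
  }
  n_train <- length(eligible) - n_val
  train <- do.call(c, lapply(eligible[seq_len(n_train)], make_samples))
  validation <- do.call(c, lapply(eligible[n_train + seq_len(n_val)], make_samples))
  list(train = train, validation = validation)
}

match_roi_name <- function(name, candidates, aliases = NULL) {
  if (!is.null(aliases) && tolower(name) %in% tolower(names(aliases)))
    name <- aliases[[match(tolower(name), tolower(names(aliases)))]]
  hit <- which(tolower(candidates) == tolower(name))
  if (length(hit)) candidates[hit[1]] else NA_character_
}
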