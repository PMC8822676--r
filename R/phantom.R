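#' Synthetic head-phantom specification
#'
#' Deterministic desk-scale stand-in for a clinical head-and-neck planning
#' CT: an elliptical soft-tissue head cross-section with a bony ring, air
#' background, and simple high-contrast "organs" (ellipsoids / cylinders)
#' whose exact supports double as ground truth.  Defaults mirror the
#' acquisition this package targets (512 x 512 matrix, sub-millimeter pixel
#' spacing so in-plane resampling is always exercised, 2.5 mm slices) at a
#' limited axial range that keeps training tractable on a laptop CPU.
#'
#' @param matrix_size (rows, cols), default 512 x 512.
#' @param n_slices number of axial slices (default 12, a 30 mm range).
#' @param pixel_spacing mm; deliberately not 1.0 (default 0.977) so the
#'   1 mm resampling step never degenerates to the identity.
#' @param slice_thickness mm (default 2.5).
#' @param body list(semi_axes = c(row mm, col mm), hu): soft-tissue ellipse.
#' @param skull list(thickness mm, hu): bony ring just inside the body edge.
#' @param organs list of organ specs: list(name, shape = "ellipsoid" or
#'   "cylinder", center mm (x, y, z offsets from body center / mid-scan),
#'   semi_axes mm (for a cylinder: radius, radius, half-height), hu).
#'   Organ HU must differ from body HU by at least 80 (learnable contrast).
#' @param noise_sd Gaussian HU noise (default 10).
#' @param seed RNG seed: fixed seed, identical phantom.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(512, 512), n_slices = 12,
                         pixel_spacing = c(0.977, 0.977),
                         slice_thickness = 2.5,
                         body = list(semi_axes = c(95, 75), hu = 40),
                         skull = list(thickness = 6, hu = 700),
                         organs = default_phantom_organs(),
                         noise_sd = 10, seed = 1L) {
  for (o in organs) {
    if (abs(o$hu - body$hu) < 80)
      stop("organ '", o$name, "' has less than 80 HU contrast against the body")
  }
  structure(list(matrix_size = matrix_size, n_slices = n_slices,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, body = body,
                 skull = skull, organs = organs, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "phantom_spec")
}

#' Default phantom organs
#'
#' Three structures spanning the shapes the pipeline must handle: a bright
#' central cylinder and two dark lateral ellipsoid glands, sized like the
#' glandular organs at risk (parotid-scale cross-sections) so that a small
#' network can learn them from a desk-scale cohort — the phantom validates
#' plumbing and learnability, not clinical difficulty.
#'
#' @return list of organ specs for [phantom_spec()].
#' @export
default_phantom_organs <- function() {
  list(
    list(name = "stem", shape = "cylinder", center = c(0, 10, 0),
         semi_axes = c(16, 16, 7.5), hu = 160),
    list(name = "gland_l", shape = "ellipsoid", center = c(-44, 12, 0),
         semi_axes = c(16, 13, 8), hu = -80),
    list(name = "gland_r", shape = "ellipsoid", center = c(44, 12, 0),
         semi_axes = c(16, 13, 8), hu = -80)
  )
}

#' Generate a synthetic head phantom
#'
#' Paints air (-1000 HU), the soft-tissue body ellipse, the bony ring and
#' each organ, then adds seeded Gaussian noise.  The returned structure set
#' holds the exact pre-noise organ supports as ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id identifier stamped into the DICOM metadata.
#' @return list(ct = [ct_volume], ss = [structure_set]).
#' @export
generate_phantom <- function(spec = phantom_spec(), patient_id = "PHANTOM") {
  set.seed(spec$seed)
  nr <- spec$matrix_size[1]; nc <- spec$matrix_size[2]; ns <- spec$n_slices
  sp <- spec$pixel_spacing; th <- spec$slice_thickness
  # patient coords: x along columns, y along rows, (0,0) at the body center
  origin <- c(-(nc - 1) / 2 * sp[2], -(nr - 1) / 2 * sp[1], 0)
  x <- origin[1] + (seq_len(nc) - 1) * sp[2]
  y <- origin[2] + (seq_len(nr) - 1) * sp[1]
  z <- (seq_len(ns) - 1) * th
  zc <- mean(range(z))
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)

  a_col <- spec$body$semi_axes[2]; a_row <- spec$body$semi_axes[1]
  r2 <- (X / a_col)^2 + (Y / a_row)^2
  body2d <- r2 <= 1
  inner <- (X / (a_col - spec$skull$thickness))^2 +
           (Y / (a_row - spec$skull$thickness))^2 <= 1
  skull2d <- body2d & !inner

  slice0 <- matrix(-1000, nr, nc)
  slice0[body2d] <- spec$body$hu
  slice0[skull2d] <- spec$skull$hu
  vox <- array(rep(slice0, ns), c(nr, nc, ns))

  body3d <- array(rep(inner, ns), c(nr, nc, ns))
  masks <- list()
  for (o in spec$organs) {
    m <- array(FALSE, c(nr, nc, ns))
    for (s in seq_len(ns)) {
      dz <- z[s] - (zc + o$center[3])
      if (o$shape == "cylinder") {
        if (abs(dz) > o$semi_axes[3]) next
        m[, , s] <- ((X - o$center[1]) / o$semi_axes[1])^2 +
                    ((Y - o$center[2]) / o$semi_axes[2])^2 <= 1
      } else {
        rem <- 1 - (dz / o$semi_axes[3])^2
        if (rem <= 0) next
        m[, , s] <- ((X - o$center[1]) / o$semi_axes[1])^2 +
                    ((Y - o$center[2]) / o$semi_axes[2])^2 <= rem
      }
    }
    if (any(m & !body3d))
      stop("organ '", o$name, "' extends outside the body")
    if (!any(m))
      stop("organ '", o$name, "' has empty support on this grid")
    vox[m] <- o$hu
    masks[[o$name]] <- m
  }
  if (spec$noise_sd > 0)
    vox <- vox + array(rnorm(length(vox), sd = spec$noise_sd), dim(vox))

  ct <- ct_volume(
    voxels = vox, pixel_spacing = sp, slice_thickness = th,
    slice_positions = z, origin = origin,
    sop_instance_uids = oar_uid(ns),
    series_uid = oar_uid(1), frame_of_reference_uid = oar_uid(1),
    study_uid = oar_uid(1), patient_id = patient_id)
  list(ct = ct, ss = structure_set(masks, ct))
}

#' Write a phantom as a DICOM CT series plus RTSTRUCT
#'
#' One CT file per slice (integer HU storage, so reading recovers values to
#' within 0.5 HU quantization) and one RT Structure Set referencing the
#' series.
#'
#' @param volume a [ct_volume].
#' @param structs the matching [structure_set].
#' @param out_dir output directory (created).
#' @return list(ct_dir, rtstruct), invisibly.
#' @export
write_phantom_dicom <- function(volume, structs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct_dir <- file.path(out_dir, "CT")
  write_ct_series(volume, ct_dir)
  rs <- file.path(out_dir, "RS.dcm")
  write_rtstruct(structs, volume, rs)
  invisible(list(ct_dir = ct_dir, rtstruct = rs))
}

#' Generate a cohort of jittered phantoms on disk
#'
#' `n` patient directories, each a phantom with organ centers and semi-axes
#' perturbed by a deterministic per-patient seed derived from the cohort
#' seed.  A manifest records per-patient, per-organ ground-truth heights.
#'
#' @param n number of patients (>= 2).
#' @param out_dir cohort root directory.
#' @param base_spec the unjittered [phantom_spec()].
#' @param center_jitter_mm max absolute in-plane center shift (uniform).
#' @param axis_jitter_frac max relative semi-axis change (uniform).
#' @param seed cohort seed.
#' @return path of the manifest file, invisibly.
#' @export
make_cohort <- function(n, out_dir, base_spec = phantom_spec(),
                        center_jitter_mm = 6, axis_jitter_frac = 0.15,
                        seed = 1L) {
  if (n < 2) stop("a cohort needs at least 2 patients")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (i in seq_len(n)) {
    pt_seed <- (seed * 1000L + i) %% .Machine$integer.max
    pid <- sprintf("PHANTOM%03d", i)
    spec <- NULL
    set.seed(pt_seed)
    for (try in seq_len(100)) {
      organs <- lapply(base_spec$organs, function(o) {
        o$center[1:2] <- o$center[1:2] + runif(2, -1, 1) * center_jitter_mm
        o$semi_axes <- o$semi_axes * (1 + runif(3, -1, 1) * axis_jitter_frac)
        o
      })
      cand <- base_spec
      cand$organs <- organs
      cand$seed <- pt_seed + try
      ok <- tryCatch({ generate_phantom(cand, pid); TRUE },
                     error = function(e) FALSE)
      if (ok) { spec <- cand; break }
    }
    if (is.null(spec))
      stop("could not place organs inside the body for patient ", i,
           " after 100 tries")
    ph <- generate_phantom(spec, pid)
    pdir <- file.path(out_dir, sprintf("pt_%03d", i))
    write_phantom_dicom(ph$ct, ph$ss, pdir)
    for (org in names(ph$ss$rois)) {
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        patient = pid, dir = pdir, organ = org,
        height_mm = measure_height(ph$ss$rois[[org]]$mask, ph$ct),
        seed = spec$seed)
    }
  }
  manifest <- do.call(rbind, manifest)
  path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
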