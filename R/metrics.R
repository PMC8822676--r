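#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1.0 by convention
#' (agreement on absence).
#'
#' @param a,b binary arrays of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Surface voxel centers of a mask, in mm
#'
#' The surface is the set of positive voxels with at least one face-adjacent
#' (6-connectivity) background or out-of-bounds neighbor; returned as point
#' coordinates scaled by (row, col, slice) spacing.  Surface-distance
#' metrics are convention-sensitive: this package measures distances between
#' boundary voxel *centers*, not inter-voxel faces.
#'
#' @param mask binary 3D array.
#' @param spacing length-3 numeric: (row mm, col mm, slice mm).
#' @return n x 3 matrix of points (mm); zero rows for an empty mask.
#' @export
surface_points <- function(mask, spacing) {
  d <- dim(mask)
  surf <- .cpp_surface_mask(as.logical(mask), as.integer(d))
  idx <- which(surf) - 1L
  r <- idx %% d[1]
  c <- (idx %/% d[1]) %% d[2]
  s <- idx %/% (d[1] * d[2])
  cbind(r * spacing[1], c * spacing[2], s * spacing[3])
}

# Directed nearest-surface distances from each point of A to the set B,
# using the C++ scan with points sorted on the first coordinate.
directed_distances <- function(pa, pb) {
  ord <- order(pb[, 1])
  .cpp_nearest_distances(pa, pb[ord, , drop = FALSE])
}

surface_pair <- function(a, b, spacing) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (!any(a) || !any(b)) return(NULL)
  list(a = surface_points(a, spacing), b = surface_points(b, spacing))
}

#' Symmetric mean surface distance (mm)
#'
#' Average of the two directed mean nearest-surface distances,
#' `(mean_a min d(a, surf B) + mean_b min d(b, surf A)) / 2`.
#' Undefined (NA) if either mask is empty, so failed structures cannot fake
#' good scores.
#'
#' @param a,b binary arrays of equal shape.
#' @param spacing length-3 (row mm, col mm, slice mm).
#' @return mm, or `NA` for an empty input.
#' @export
mean_surface_distance <- function(a, b, spacing) {
  sp <- surface_pair(a, b, spacing)
  if (is.null(sp)) return(NA_real_)
  (mean(directed_distances(sp$a, sp$b)) +
     mean(directed_distances(sp$b, sp$a))) / 2
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Pools both directed nearest-distance multisets (A to B and B to A) and
#' takes the 95th percentile of the pooled multiset, with linear
#' interpolation between order statistics.  (Conventions differ; the pooled
#' percentile is used and named in all reports.)
#'
#' @param a,b binary arrays of equal shape.
#' @param spacing length-3 (row mm, col mm, slice mm).
#' @param probs percentile (default 0.95).
#' @return mm, or `NA` for an empty input.
#' @export
hausdorff95 <- function(a, b, spacing, probs = 0.95) {
  sp <- surface_pair(a, b, spacing)
  if (is.null(sp)) return(NA_real_)
  pooled <- c(directed_distances(sp$a, sp$b), directed_distances(sp$b, sp$a))
  as.numeric(quantile(pooled, probs = probs, type = 7, names = FALSE))
}

#' Paired two-tailed Student t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`
#' (sample SD), with a two-tailed p from the t distribution on n - 1 df.
#' All-zero differences give t = 0, p = 1 by convention; NA pairs are
#' dropped pairwise with the count reported.
#'
#' @param x,y matched per-patient scores (equal length >= 2).
#' @param metric,organ,methods optional labels carried into the result.
#' @return tibble with organ, metric, method_1, method_2, t, df, p, n,
#'   n_dropped, significant (p < 0.05).
#' @export
paired_ttest <- function(x, y, metric = NA_character_, organ = NA_character_,
                         methods = c(NA_character_, NA_character_)) {
  if (length(x) != length(y)) stop("x and y must be matched (equal length)")
  ok <- !(is.na(x) | is.na(y))
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("paired t test needs at least 2 complete pairs")
  d <- x - y
  if (all(d == 0)) {
    tstat <- 0; p <- 1.0
  } else if (sd(d) == 0) {
    # constant nonzero differences: degenerate variance, certain direction
    tstat <- sign(mean(d)) * Inf; p <- 0.0
  } else {
    ht <- t.test(x, y, paired = TRUE, alternative = "two.sided")
    tstat <- unname(ht$statistic); p <- ht$p.value
  }
  tibble::tibble(organ = organ, metric = metric,
                 method_1 = methods[1], method_2 = methods[2],
                 t = tstat, df = n - 1L, p = p, n = n,
                 n_dropped = n_dropped, significant = p < 0.05)
}

#' Score predicted against ground-truth structure sets across a cohort
#'
#' One record per patient x organ x method with DSC, MSD (mm) and HD95 (mm);
#' per organ x metric paired t tests for every method pair; and a Table-style
#' summary of mean and SD per organ/metric/method.
#'
#' @param predictions named list: method -> named list: patient ->
#'   [structure_set] (or named list of masks).
#' @param truth named list: patient -> [structure_set] (or mask list).
#' @param volumes named list: patient -> [ct_volume] (for spacing).
#' @param organs organ names to score; default: union of truth ROI names.
#' @return list of tibbles: `records`, `tests`, `summary`.
#' @export
evaluate_cohort <- function(predictions, truth, volumes, organs = NULL) {
  get_masks <- function(x) {
    if (inherits(x, "structure_set"))
      lapply(x$rois, `[[`, "mask")
    else x
  }
  patients <- names(truth)
  if (is.null(organs))
    organs <- unique(unlist(lapply(truth, function(t) names(get_masks(t)))))
  rows <- list()
  for (method in names(predictions)) {
    pred_m <- predictions[[method]]
    for (pt in patients) {
      if (!pt %in% names(pred_m)) next
      vol <- volumes[[pt]]
      spacing <- c(vol$pixel_spacing, vol$slice_thickness)
      tr <- get_masks(truth[[pt]])
      pr <- get_masks(pred_m[[pt]])
      for (org in organs) {
        tnm <- match_roi_name(org, names(tr))
        pnm <- match_roi_name(org, names(pr))
        tm <- if (!is.na(tnm)) tr[[tnm]] else NULL
        pm <- if (!is.na(pnm)) pr[[pnm]] else array(FALSE, dim(tm))
        if (is.null(tm)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            patient_id = pt, organ = org, method = method,
            dsc = NA_real_, msd = NA_real_, hd95 = NA_real_)
          next
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = pt, organ = org, method = method,
          dsc = dsc(tm, pm),
          msd = mean_surface_distance(tm, pm, spacing),
          hd95 = hausdorff95(tm, pm, spacing))
      }
    }
  }
  records <- do.call(rbind, rows)

  tests <- list()
  methods <- names(predictions)
  if (length(methods) >= 2) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    for (pairm in pairs) {
      for (org in organs) {
        for (metric in c("dsc", "msd", "hd95")) {
          r1 <- records[records$organ == org & records$method == pairm[1], ]
          r2 <- records[records$organ == org & records$method == pairm[2], ]
          common <- intersect(r1$patient_id, r2$patient_id)
          if (length(common) < 2) next
          x <- r1[[metric]][match(common, r1$patient_id)]
          y <- r2[[metric]][match(common, r2$patient_id)]
          if (sum(!(is.na(x) | is.na(y))) < 2) next
          tests[[length(tests) + 1]] <-
            paired_ttest(x, y, metric = metric, organ = org, methods = pairm)
        }
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    tibble::tibble(organ = character(), metric = character(),
                   method_1 = character(), method_2 = character(),
                   t = numeric(), df = integer(), p = numeric(),
                   n = integer(), n_dropped = integer(),
                   significant = logical())

  summ <- list()
  for (method in methods) {
    for (org in organs) {
      sub <- records[records$organ == org & records$method == method, ]
      for (metric in c("dsc", "msd", "hd95")) {
        v <- sub[[metric]]
        summ[[length(summ) + 1]] <- tibble::tibble(
          organ = org, metric = metric, method = method,
          mean = mean(v, na.rm = TRUE),
          sd = if (sum(!is.na(v)) >= 2) sd(v, na.rm = TRUE) else NA_real_,
          n = sum(!is.na(v)))
      }
    }
  }
  list(records = records, tests = tests, summary = do.call(rbind, summ))
}

#' Write cohort evaluation tables to CSV
#'
#' @param evaluation result of [evaluate_cohort()].
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("records.csv", "paired_tests.csv", "summary.csv"))
  write.csv(evaluation$records, paths[1], row.names = FALSE)
  write.csv(evaluation$tests, paths[2], row.names = FALSE)
  write.csv(evaluation$summary, paths[3], row.names = FALSE)
  invisible(paths)
}
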