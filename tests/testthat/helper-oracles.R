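# Independent brute-force oracles.  Everything here is deliberately written
# without touching the package's computational paths: plain R, O(n^2) where
# that is the honest thing to do.

# Even-odd point-in-polygon test (ray casting), one point at a time.
oracle_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xc <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xc) inside <- !inside
    }
    j <- i
  }
  inside
}

# Rasterize a polygon (pixel-index coordinates) by testing every center.
oracle_fill_polygon <- function(px, py, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      out[r, c] <- oracle_point_in_polygon(c - 1, r - 1, px, py)
    }
  }
  out
}

# Random convex polygon in pixel coordinates: points on a jittered circle,
# ordered by angle (convex hull of its own vertices).
random_convex_polygon <- function(nrow, ncol, nv = sample(3:8, 1)) {
  cx <- runif(1, 5, ncol - 6)
  cy <- runif(1, 5, nrow - 6)
  rad <- runif(1, 2, min(cx, cy, ncol - 1 - cx, nrow - 1 - cy))
  ang <- sort(runif(nv, 0, 2 * pi))
  list(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

# Flood-fill connected components (26-connectivity), pure R.
oracle_label_components <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nxt <- 0L
  idx_of <- function(r, c, s) r + (c - 1L) * d[1] + (s - 1L) * d[1] * d[2]
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      s <- (v - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (v - 1L) %% (d[1] * d[2])
      c <- rem %/% d[1] + 1L
      r <- rem %% d[1] + 1L
      for (ds in -1:1) for (dc in -1:1) for (dr in -1:1) {
        if (dr == 0 && dc == 0 && ds == 0) next
        rr <- r + dr; cc <- c + dc; ss <- s + ds
        if (rr < 1 || rr > d[1] || cc < 1 || cc > d[2] || ss < 1 || ss > d[3]) next
        w <- idx_of(rr, cc, ss)
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# Surface voxels by array shifting (6-connectivity), pure R.
oracle_surface <- function(mask) {
  d <- dim(mask)
  padded <- array(FALSE, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- function(dr, dc, ds)
    padded[2:(d[1] + 1) + dr, 2:(d[2] + 1) + dc, 2:(d[3] + 1) + ds]
  interior <- core(1, 0, 0) & core(-1, 0, 0) & core(0, 1, 0) &
    core(0, -1, 0) & core(0, 0, 1) & core(0, 0, -1)
  mask & !interior
}

oracle_surface_points <- function(mask, spacing) {
  idx <- which(oracle_surface(mask)) - 1L
  d <- dim(mask)
  r <- idx %% d[1]
  c <- (idx %/% d[1]) %% d[2]
  s <- idx %/% (d[1] * d[2])
  cbind(r * spacing[1], c * spacing[2], s * spacing[3])
}

# All-pairs directed nearest distances, O(n * m).
oracle_directed <- function(pa, pb) {
  apply(pa, 1, function(p) {
    sqrt(min(colSums((t(pb) - p)^2)))
  })
}

oracle_msd <- function(a, b, spacing) {
  pa <- oracle_surface_points(a, spacing)
  pb <- oracle_surface_points(b, spacing)
  (mean(oracle_directed(pa, pb)) + mean(oracle_directed(pb, pa))) / 2
}

oracle_hd95 <- function(a, b, spacing) {
  pa <- oracle_surface_points(a, spacing)
  pb <- oracle_surface_points(b, spacing)
  pooled <- c(oracle_directed(pa, pb), oracle_directed(pb, pa))
  as.numeric(quantile(pooled, 0.95, type = 7, names = FALSE))
}

# Student t CDF by numerical integration of the closed-form density;
# two-tailed p for a paired test.
oracle_t_p2 <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
  2 * tail
}

# Random solid-ish 3D blob: union of a few random balls, optionally grown
# until every nonempty slice holds at least `min_px` voxels.
random_blob <- function(d = c(32, 32, 4), n_balls = sample(1:3, 1),
                        r_range = c(5, 9), min_px = 0) {
  mask <- array(FALSE, d)
  grid <- expand.grid(r = seq_len(d[1]), c = seq_len(d[2]), s = seq_len(d[3]))
  for (i in seq_len(n_balls)) {
    r0 <- runif(1, r_range[1] + 2, d[1] - r_range[1] - 2)
    c0 <- runif(1, r_range[1] + 2, d[2] - r_range[1] - 2)
    s0 <- runif(1, 1, d[3])
    rad <- runif(1, r_range[1], r_range[2])
    inside <- ((grid$r - r0)^2 + (grid$c - c0)^2 +
                 ((grid$s - s0) * 2)^2) <= rad^2
    mask[cbind(grid$r, grid$c, grid$s)[inside, , drop = FALSE]] <- TRUE
  }
  if (min_px > 0) {
    counts <- apply(mask, 3, sum)
    mask[, , counts > 0 & counts < min_px] <- FALSE
  }
  mask
}

# Small in-memory CT volume on a given grid for mask-geometry tests.
toy_volume <- function(d = c(32, 32, 4), spacing = c(1, 1), thickness = 2.5,
                       hu = -1000) {
  ct_volume(
    voxels = array(hu, d),
    pixel_spacing = spacing,
    slice_thickness = thickness,
    slice_positions = (seq_len(d[3]) - 1) * thickness,
    origin = c(0, 0, 0),
    sop_instance_uids = sprintf("1.2.3.%d", seq_len(d[3])),
    series_uid = "1.2.3.100", frame_of_reference_uid = "1.2.3.200",
    study_uid = "1.2.3.300", patient_id = "TOY")
}
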