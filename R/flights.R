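# Flight segmentation, path clustering, position-derived kinematics and
# flight-to-flight reproducibility.

#' Segment flights from a body trajectory
#'
#' Flights are maximal epochs where the Gaussian-smoothed speed stays above
#' `speed_threshold` for at least `min_duration`; each epoch is then padded
#' outward to the nearest local speed minimum so that the slow takeoff and
#' landing ramps are included.
#'
#' @param traj data.frame with columns `t, x, y, z`, uniformly sampled.
#' @param fs sampling rate (Hz); inferred from `t` when `NULL`.
#' @param speed_threshold flight detection threshold (m/s).
#' @param min_duration minimum above-threshold duration (s).
#' @param smooth_ms Gaussian smoothing sd applied to positions (ms).
#' @return data.frame with `flight_id`, `start`, `end` (s). Empty (zero
#'   rows) when nothing exceeds threshold.
#' @export
segment_flights <- function(traj, fs = NULL, speed_threshold = 1,
                            min_duration = 1, smooth_ms = 25) {
  if (!nrow(traj)) stop("empty trajectory")
  if (is.null(fs)) fs <- 1 / stats::median(diff(traj$t))
  sd_bins <- smooth_ms / 1000 * fs
  P <- cbind(gauss_smooth(traj$x, sd_bins), gauss_smooth(traj$y, sd_bins),
             gauss_smooth(traj$z, sd_bins))
  v <- apply(P, 2, num_deriv, dt = 1 / fs)
  speed <- sqrt(rowSums(v^2))
  above <- speed > speed_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_duration * fs)
  if (!length(keep))
    return(data.frame(flight_id = integer(), start = numeric(),
                      end = numeric()))
  out <- lapply(seq_along(keep), function(j) {
    i0 <- starts[keep[j]]; i1 <- ends[keep[j]]
    floor_v <- 0.02 * speed_threshold
    while (i0 > 1 && speed[i0 - 1] < speed[i0] &&
             speed[i0 - 1] > floor_v) i0 <- i0 - 1L
    while (i1 < length(speed) && speed[i1 + 1] < speed[i1] &&
             speed[i1 + 1] > floor_v) i1 <- i1 + 1L
    c(i0, i1)
  })
  out <- do.call(rbind, out)
  # merge overlaps created by padding
  merged <- list(out[1, ])
  if (nrow(out) > 1) {
    for (j in 2:nrow(out)) {
      last <- merged[[length(merged)]]
      if (out[j, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], out[j, 2]))
      } else merged[[length(merged) + 1L]] <- out[j, ]
    }
  }
  m <- do.call(rbind, merged)
  data.frame(flight_id = seq_len(nrow(m)), start = traj$t[m[, 1]],
             end = traj$t[m[, 2]])
}

#' Resample flight trajectories to a fixed point count
#' @keywords internal
resample_flight <- function(traj, start, end, n_points = 200) {
  idx <- which(traj$t >= start & traj$t <= end)
  cbind(resample_series(traj$x[idx], n_points),
        resample_series(traj$y[idx], n_points),
        resample_series(traj$z[idx], n_points))
}

#' Cluster flights into paths
#'
#' Agglomerative clustering (average linkage) on the pairwise RMS distance
#' between time-resampled trajectories. The metric is direction-sensitive:
#' the same spatial loop flown in opposite directions yields large RMS
#' distance and therefore distinct paths. Clusters smaller than
#' `min_cluster` are labeled 0 ("unclustered").
#'
#' @param traj session trajectory data.frame (`t,x,y,z`).
#' @param flights data.frame from [segment_flights()].
#' @param distance_cutoff tree cut height: RMS distance (m) below which
#'   flights are merged.
#' @param n_points resampled points per flight.
#' @param min_cluster minimum flights per retained path.
#' @return integer path labels (one per flight; 0 = unclustered), with the
#'   pairwise distance matrix in attribute `"dist"`.
#' @export
cluster_paths <- function(traj, flights, distance_cutoff = 0.3,
                          n_points = 200, min_cluster = 2) {
  nf <- nrow(flights)
  if (nf == 1)
    return(structure(1L, dist = NULL))
  M <- t(vapply(seq_len(nf), function(i) {
    as.numeric(resample_flight(traj, flights$start[i], flights$end[i],
                               n_points))
  }, numeric(3 * n_points)))
  D <- stats::dist(M) / sqrt(3 * n_points)   # euclidean -> RMS
  hc <- stats::hclust(D, method = "average")
  lab <- stats::cutree(hc, h = distance_cutoff)
  sizes <- table(lab)
  small <- as.integer(names(sizes)[sizes < min_cluster])
  lab[lab %in% small] <- 0L
  # relabel retained clusters 1..K in order of first occurrence
  kept <- unique(lab[lab != 0L])
  new <- stats::setNames(seq_along(kept), kept)
  lab[lab != 0L] <- new[as.character(lab[lab != 0L])]
  structure(as.integer(lab), dist = as.matrix(D))
}

#' Derive kinematic series from a flight trajectory
#'
#' Positions are smoothed with a zero-phase Gaussian (default sd 25 ms,
#' well below the ~125 ms wingbeat period) before central-difference
#' differentiation. Returns per-sample speed `|v|`, g-force `|a|/9.81`,
#' angular velocity of the velocity direction `|v x a| / |v|^2`, flight
#' path angle `asin(vz/|v|)`, and the velocity/acceleration components.
#' Samples with zero speed have the angle quantities masked (`NA`).
#'
#' @param traj data.frame `t,x,y,z` covering one flight (or any epoch).
#' @param fs sampling rate (Hz); inferred when `NULL`.
#' @param smooth_ms Gaussian sd in ms (0 disables smoothing).
#' @return data.frame: `t, speed, g_force, ang_vel, fpa, vx, vy, vz,
#'   ax, ay, az`.
#' @export
derive_kinematics <- function(traj, fs = NULL, smooth_ms = 25) {
  if (is.null(fs)) fs <- 1 / stats::median(diff(traj$t))
  sd_bins <- smooth_ms / 1000 * fs
  P <- cbind(gauss_smooth(traj$x, sd_bins), gauss_smooth(traj$y, sd_bins),
             gauss_smooth(traj$z, sd_bins))
  v <- apply(P, 2, num_deriv, dt = 1 / fs)
  a <- apply(v, 2, num_deriv, dt = 1 / fs)
  speed <- sqrt(rowSums(v^2))
  cx <- v[, 2] * a[, 3] - v[, 3] * a[, 2]
  cy <- v[, 3] * a[, 1] - v[, 1] * a[, 3]
  cz <- v[, 1] * a[, 2] - v[, 2] * a[, 1]
  ang_vel <- sqrt(cx^2 + cy^2 + cz^2) / speed^2
  fpa <- asin(pmin(pmax(v[, 3] / speed, -1), 1))
  zero <- speed < 1e-9
  ang_vel[zero] <- NA_real_
  fpa[zero] <- NA_real_
  data.frame(t = traj$t, speed = speed,
             g_force = sqrt(rowSums(a^2)) / 9.81,
             ang_vel = ang_vel, fpa = fpa,
             vx = v[, 1], vy = v[, 2], vz = v[, 3],
             ax = a[, 1], ay = a[, 2], az = a[, 3])
}

#' Flight-to-flight reproducibility of feature traces
#'
#' Each flight's feature trace (resampled to a common length) is correlated
#' with the leave-one-out mean of the remaining flights of the same path;
#' correlations are pooled across flights and features. Position features
#' (named `x`, `y`, `z`) are range-normalized to 0-1 per flight first.
#' Constant traces have undefined correlation and are excluded (counted in
#' `n_excluded`).
#'
#' @param feature_list list (one element per flight) of numeric matrices /
#'   data.frames with identical column names: rows = time, cols = features.
#' @param n_points resampled trace length.
#' @return list with `correlations` (vector), `median`, `iqr`,
#'   `n_excluded`.
#' @export
path_reproducibility <- function(feature_list, n_points = 200) {
  stopifnot(length(feature_list) >= 2)
  nf <- length(feature_list)
  feats <- colnames(feature_list[[1]])
  arr <- array(NA_real_, c(n_points, length(feats), nf))
  for (f in seq_len(nf)) {
    M <- as.matrix(feature_list[[f]])[, feats, drop = FALSE]
    for (j in seq_along(feats)) {
      x <- resample_series(M[, j], n_points)
      if (feats[j] %in% c("x", "y", "z")) {
        rg <- range(x, na.rm = TRUE)
        if (diff(rg) > 0) x <- (x - rg[1]) / diff(rg)
      }
      arr[, j, f] <- x
    }
  }
  cors <- c(); n_excl <- 0L
  for (f in seq_len(nf)) {
    for (j in seq_along(feats)) {
      x <- arr[, j, f]
      mu <- rowMeans(arr[, j, -f, drop = FALSE], na.rm = TRUE)
      if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(mu, na.rm = TRUE) == 0
          || anyNA(x)) {
        n_excl <- n_excl + 1L
        next
      }
      cors <- c(cors, stats::cor(x, mu, use = "complete.obs"))
    }
  }
  list(correlations = cors,
       median = stats::median(cors), iqr = stats::IQR(cors),
       n_excluded = n_excl)
}

#' Re-project world-frame keypoints into the body reference frame
#'
#' Body axes per frame: forward = `head - tail` (normalized), left = the
#' lateral keypoint difference orthogonalized against forward, up =
#' forward x left; origin at the `origin` keypoint. Frames whose axis
#' keypoints are collinear / degenerate are masked with `NA`.
#'
#' @param kp array `n x K x 3` of world-frame keypoints with named
#'   keypoints in `dimnames(kp)[[2]]`.
#' @param forward_pair character(2): head-side and tail-side keypoint.
#' @param lateral_pair character(2): left and right keypoint defining the
#'   lateral axis.
#' @param origin keypoint mapped to the body-frame origin.
#' @return array `n x K x 3` of body-frame coordinates.
#' @export
body_frame_transform <- function(kp,
                                 forward_pair = c("head", "tail_base"),
                                 lateral_pair = c("shoulder_l",
                                                  "shoulder_r"),
                                 origin = "sternum") {
  nm <- dimnames(kp)[[2]]
  stopifnot(all(c(forward_pair, lateral_pair, origin) %in% nm))
  n <- dim(kp)[1]
  f <- kp[, forward_pair[1], ] - kp[, forward_pair[2], ]
  l <- kp[, lateral_pair[1], ] - kp[, lateral_pair[2], ]
  fn <- sqrt(rowSums(f^2))
  bad <- fn < 1e-9
  f <- f / pmax(fn, 1e-9)
  l <- l - f * rowSums(l * f)          # orthogonalize
  ln <- sqrt(rowSums(l^2))
  bad <- bad | ln < 1e-9
  l <- l / pmax(ln, 1e-9)
  u <- cbind(f[, 2] * l[, 3] - f[, 3] * l[, 2],
             f[, 3] * l[, 1] - f[, 1] * l[, 3],
             f[, 1] * l[, 2] - f[, 2] * l[, 1])
  o <- kp[, origin, ]
  out <- array(NA_real_, dim(kp), dimnames = dimnames(kp))
  for (k in seq_len(dim(kp)[2])) {
    d <- kp[, k, ] - o
    out[, k, 1] <- rowSums(d * f)
    out[, k, 2] <- rowSums(d * l)
    out[, k, 3] <- rowSums(d * u)
  }
  if (any(bad)) out[bad, , ] <- NA_real_
  out
}
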