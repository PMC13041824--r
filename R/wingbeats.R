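# Wingbeat cycle detection, phase assignment, stroke envelopes,
# asymmetries, adaptation vectors, and kinematic grouping of wingbeats.

#' Detect wingbeat cycles from the dorsoventral accelerometer
#'
#' The accelerometer trace is band-passed (zero-phase Butterworth, default
#' 4-14 Hz around the ~8 Hz wingbeat rhythm), the instantaneous phase is
#' taken from the analytic signal, and cycle boundaries are placed at
#' phase-zero crossings (sub-sample accurate by linear interpolation of the
#' unwrapped phase). The phase convention puts theta = 0 at the upward
#' zero-crossing of the dorsoventral oscillation (start of the upstroke
#' acceleration), so a planted `sin(theta)` oscillation is recovered with
#' matching phase.
#'
#' Two quality gates reject non-oscillatory input: a flight is skipped when
#' less than `min_band_frac` of its (detrended) signal variance lies in the
#' wingbeat band, and individual cycles are rejected when their analytic
#' amplitude falls below `amp_gate` times the flight median (landing
#' artifacts).
#'
#' @param accel_dv dorsoventral accelerometer trace (g), full session.
#' @param fs sampling rate (Hz).
#' @param flights data.frame with `flight_id`, `start`, `end`; cycles are
#'   only detected within flights.
#' @param t time base of `accel_dv`; default `(0:(n-1))/fs`.
#' @param band band-pass corner frequencies (Hz).
#' @param amp_gate relative analytic-amplitude gate.
#' @param min_band_frac minimum in-band variance fraction per flight.
#' @param traj optional trajectory data.frame to attach the mean 3D
#'   position of each cycle.
#' @return object of class `wb_wingbeats`: list with `wingbeats`
#'   (data.frame: wingbeat_id, flight_id, onset, offset, period_ms,
#'   ordinal, and x,y,z means when `traj` given), `theta` (per-sample
#'   phase, NA outside flights), and `phase_fun` (per-flight unwrapped
#'   phase interpolators, for sub-sample spike phase lookup).
#' @export
detect_wingbeats <- function(accel_dv, fs, flights, t = NULL,
                             band = c(4, 14), amp_gate = 0.2,
                             min_band_frac = 0.5, traj = NULL) {
  n <- length(accel_dv)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  ny <- fs / 2
  bf <- signal::butter(2, pmin(band / ny, 0.99), type = "pass")
  xb <- as.numeric(signal::filtfilt(bf, accel_dv - mean(accel_dv)))
  theta <- rep(NA_real_, n)
  phase_fun <- list()
  rows <- list()
  wid <- 0L
  for (fi in seq_len(nrow(flights))) {
    fl <- flights[fi, ]
    pad <- 0.5 / mean(band)
    idx <- which(t >= fl$start - pad & t <= fl$end + pad)
    in_fl <- which(t[idx] >= fl$start & t[idx] <= fl$end)
    if (length(in_fl) < 2 * fs / mean(band)) {
      warning("flight ", fl$flight_id, " shorter than 2 cycles; skipped")
      next
    }
    seg_raw <- accel_dv[idx][in_fl]
    seg_band <- xb[idx][in_fl]
    v_tot <- stats::var(seg_raw - mean(seg_raw))
    if (v_tot <= 0 || stats::var(seg_band) / v_tot < min_band_frac) next
    an <- analytic_signal(xb[idx])
    # Arg(analytic) of cos-phase; +pi/2 aligns theta=0 with the upward
    # zero-crossing of a planted sin(theta) oscillation
    ph <- Arg(an) + pi / 2
    phu <- ph[1] + c(0, cumsum(((diff(ph) + pi) %% (2 * pi)) - pi))
    tseg <- t[idx]
    theta[idx[in_fl]] <- phu[in_fl] %% (2 * pi)
    phase_fun[[as.character(fl$flight_id)]] <-
      list(t = tseg, phu = phu, start = fl$start, end = fl$end)
    # cycle boundaries: phu crossing multiples of 2*pi; brief phase
    # retreats (low-amplitude noise) are flattened with a running max so
    # the interpolation abscissa is monotone
    phu_m <- cummax(phu)
    m0 <- ceiling(min(phu_m) / (2 * pi))
    m1 <- floor(max(phu_m) / (2 * pi))
    if (m1 <= m0) next
    cross <- stats::approx(phu_m, tseg, xout = 2 * pi * (m0:m1),
                           ties = "ordered")$y
    cross <- cross[is.finite(cross)]
    if (length(cross) < 2) next
    amp <- Mod(an)
    onsets <- cross[-length(cross)]
    offsets <- cross[-1]
    mid <- (onsets + offsets) / 2
    keep <- mid >= fl$start & mid <= fl$end &
      onsets >= fl$start - 0.02 & offsets <= fl$end + 0.02
    onsets <- onsets[keep]; offsets <- offsets[keep]
    if (!length(onsets)) next
    med_amp <- stats::median(amp[in_fl])
    cyc_amp <- vapply(seq_along(onsets), function(i) {
      sel <- tseg >= onsets[i] & tseg < offsets[i]
      if (!any(sel)) return(0)
      mean(amp[sel])
    }, numeric(1))
    keep <- cyc_amp >= amp_gate * med_amp
    onsets <- onsets[keep]; offsets <- offsets[keep]
    if (!length(onsets)) next
    rows[[length(rows) + 1L]] <- data.frame(
      flight_id = fl$flight_id, onset = onsets, offset = offsets,
      period_ms = (offsets - onsets) * 1000,
      ordinal = seq_along(onsets))
  }
  wbt <- if (length(rows)) do.call(rbind, rows) else
    data.frame(flight_id = integer(), onset = numeric(),
               offset = numeric(), period_ms = numeric(),
               ordinal = integer())
  if (nrow(wbt)) {
    wbt <- cbind(wingbeat_id = seq_len(nrow(wbt)), wbt)
    if (!is.null(traj)) {
      pos <- vapply(seq_len(nrow(wbt)), function(i) {
        sel <- traj$t >= wbt$onset[i] & traj$t < wbt$offset[i]
        c(mean(traj$x[sel]), mean(traj$y[sel]), mean(traj$z[sel]))
      }, numeric(3))
      wbt$x <- pos[1, ]; wbt$y <- pos[2, ]; wbt$z <- pos[3, ]
    }
  }
  structure(list(wingbeats = wbt, theta = theta, t = t,
                 phase_fun = phase_fun),
            class = "wb_wingbeats")
}

#' Wingbeat phase at arbitrary times (e.g. spike times)
#'
#' Interpolates the per-flight unwrapped detected phase; times outside any
#' flight get `NA`.
#'
#' @param det a `wb_wingbeats` object from [detect_wingbeats()].
#' @param times numeric vector of times (s).
#' @return list with `phase` (radians in `[0, 2*pi)`) and `flight_id`.
#' @export
phase_at <- function(det, times) {
  phase <- rep(NA_real_, length(times))
  flight <- rep(NA_integer_, length(times))
  for (fid in names(det$phase_fun)) {
    pf <- det$phase_fun[[fid]]
    sel <- which(times >= pf$start & times <= pf$end)
    if (!length(sel)) next
    phase[sel] <- stats::approx(pf$t, pf$phu, xout = times[sel],
                                ties = "ordered")$y %% (2 * pi)
    flight[sel] <- as.integer(fid)
  }
  list(phase = phase, flight_id = flight)
}

#' Robust wingbeat period summary
#'
#' @param wingbeats data.frame with a `period_ms` column (or a
#'   `wb_wingbeats` object).
#' @return list with `median_ms`, `iqr_ms`, `n`.
#' @export
period_statistics <- function(wingbeats) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  p <- wingbeats$period_ms
  stopifnot(length(p) >= 1)
  list(median_ms = stats::median(p), iqr_ms = stats::IQR(p), n = length(p))
}

#' Per-cycle upstroke / downstroke envelopes of a keypoint trace
#'
#' For each wingbeat cycle, the upper envelope is the maximum and the lower
#' envelope the minimum of the (body-frame, dorsoventral) keypoint
#' displacement within the cycle. Cycles in which the trace is entirely
#' missing yield `NA`.
#'
#' @param disp displacement trace (same time base as `t`).
#' @param t time base (s).
#' @param wingbeats wingbeat table (or `wb_wingbeats` object).
#' @return data.frame: `wingbeat_id`, `t_mid`, `upper`, `lower`.
#' @export
extract_envelopes <- function(disp, t, wingbeats) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  n <- nrow(wingbeats)
  up <- lo <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- which(t >= wingbeats$onset[i] & t < wingbeats$offset[i])
    v <- disp[sel]
    v <- v[is.finite(v)]
    if (length(v)) {
      up[i] <- max(v); lo[i] <- min(v)
    }
  }
  data.frame(wingbeat_id = wingbeats$wingbeat_id,
             t_mid = (wingbeats$onset + wingbeats$offset) / 2,
             upper = up, lower = lo)
}

#' Smooth interpolation of a per-cycle envelope across cycles
#'
#' Natural cubic spline through the per-cycle extrema, evaluated at
#' arbitrary times.
#'
#' @param env data.frame from [extract_envelopes()].
#' @param t_out times at which to evaluate.
#' @param which `"upper"` or `"lower"`.
#' @return numeric vector.
#' @export
envelope_interpolate <- function(env, t_out, which = c("upper", "lower")) {
  which <- match.arg(which)
  ok <- is.finite(env[[which]])
  stats::spline(env$t_mid[ok], env[[which]][ok], xout = t_out,
                method = "natural")$y
}

#' Right-minus-left envelope asymmetry
#'
#' @param env_left,env_right envelope data.frames from
#'   [extract_envelopes()] for a paired left/right keypoint (matched rows).
#' @return data.frame: `wingbeat_id`, `upper` (right - left upper),
#'   `lower` (right - left lower). Missing members yield `NA`.
#' @export
left_right_asymmetry <- function(env_left, env_right) {
  stopifnot(nrow(env_left) == nrow(env_right),
            all(env_left$wingbeat_id == env_right$wingbeat_id))
  data.frame(wingbeat_id = env_left$wingbeat_id,
             upper = env_right$upper - env_left$upper,
             lower = env_right$lower - env_left$lower)
}

#' Per-wingbeat adaptation vectors
#'
#' Concatenates, for each wingbeat cycle, the upper and lower envelopes of
#' the tracked keypoints and their right-left asymmetries into one vector
#' summarizing the cycle-specific kinematic adjustments.
#'
#' @param envelopes named list of envelope data.frames (one per keypoint
#'   trace, e.g. `wrist_l`, `wrist_r`, `wingtip_l`, `wingtip_r`).
#' @param pairs list of character(2) left/right name pairs for asymmetries.
#' @return numeric matrix, rows = wingbeats (named by wingbeat_id).
#' @export
adaptation_vectors <- function(envelopes,
                               pairs = list(c("wrist_l", "wrist_r"),
                                            c("wingtip_l", "wingtip_r"))) {
  cols <- list()
  for (nm in names(envelopes)) {
    cols[[paste0(nm, "_up")]] <- envelopes[[nm]]$upper
    cols[[paste0(nm, "_lo")]] <- envelopes[[nm]]$lower
  }
  for (pr in pairs) {
    if (!all(pr %in% names(envelopes))) next
    asym <- left_right_asymmetry(envelopes[[pr[1]]], envelopes[[pr[2]]])
    cols[[paste0(pr[1], "_", pr[2], "_asym_up")]] <- asym$upper
    cols[[paste0(pr[1], "_", pr[2], "_asym_lo")]] <- asym$lower
  }
  M <- do.call(cbind, cols)
  rownames(M) <- envelopes[[1]]$wingbeat_id
  M
}

#' Cosine similarity of adaptation vectors as a function of wingbeat lag
#'
#' Within each flight, the cosine similarity between a reference wingbeat's
#' adaptation vector and the vector `k` wingbeats later is averaged across
#' references and flights. The curve equals 1 at lag 0 and its decay length
#' measures how quickly cycle-specific kinematic adjustments change.
#'
#' @param vectors matrix from [adaptation_vectors()].
#' @param flight_ids flight id per row.
#' @param max_lag maximal wingbeat lag.
#' @return data.frame from [cosine_lag_curve()].
#' @export
adaptation_similarity_curve <- function(vectors, flight_ids, max_lag = 10) {
  cosine_lag_curve(vectors, flight_ids, max_lag)
}

#' Group wingbeats of one path by kinematic similarity
#'
#' k-means on the concatenation of (z-scored) adaptation vectors, per-cycle
#' mean kinematics and the normalized ordinal position, with k set to the
#' median number of cycles per flight. Cluster centers are initialized at
#' the per-ordinal feature means, so in the noiseless limit the groups
#' reproduce the ordinal structure (the i-th cycle of every flight).
#' Group labels are re-ordered by mean ordinal so they are temporally
#' ordered, and an order-preservation score (Spearman correlation of label
#' vs ordinal) is attached.
#'
#' @param wingbeats wingbeat table (one path).
#' @param vectors adaptation-vector matrix (rows match `wingbeats`).
#' @param kinematics optional per-cycle kinematic feature matrix (rows
#'   match `wingbeats`).
#' @param k number of groups; default median cycles per flight.
#' @param ordinal_weight weight of the normalized ordinal feature
#'   (in z-score units).
#' @return integer group labels with attributes `order_score` and `k`.
#' @export
group_wingbeats <- function(wingbeats, vectors = NULL, kinematics = NULL,
                            k = NULL, ordinal_weight = 12) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  nw <- nrow(wingbeats)
  per_flight <- table(wingbeats$flight_id)
  if (is.null(k)) k <- as.integer(round(stats::median(per_flight)))
  if (k > nw) stop("k (", k, ") exceeds number of wingbeats (", nw, ")")
  ord <- wingbeats$ordinal
  if (length(per_flight) == 1) {
    lab <- ord
    return(structure(as.integer(lab), order_score = 1, k = max(lab)))
  }
  ord_norm <- (ord - 1) / max(1, max(ord) - 1)
  feats <- cbind(if (!is.null(vectors)) zscore_cols(as.matrix(vectors)),
                 if (!is.null(kinematics))
                   zscore_cols(as.matrix(kinematics)))
  # per-dimension rescaling keeps the kinematic block at ~unit total
  # variance so the ordinal term's weight is comparable across feature sets
  if (!is.null(feats)) feats <- feats / sqrt(ncol(feats))
  F <- cbind(feats, ordinal = ordinal_weight * ord_norm)
  F[!is.finite(F)] <- 0
  bin <- pmin(pmax(ceiling(ord_norm * k), 1L), k)
  centers <- do.call(rbind, lapply(seq_len(k), function(g) {
    rows <- which(bin == g)
    if (!length(rows)) rows <- which.min(abs(bin - g))
    colMeans(F[rows, , drop = FALSE])
  }))
  km <- tryCatch(
    suppressWarnings(stats::kmeans(F, centers = centers, iter.max = 50)),
    error = function(e) {
      # degenerate ordinal-seeded centers (e.g. ordinal weight 0 on
      # feature-poor input): fall back to random restarts
      suppressWarnings(stats::kmeans(F, centers = k, iter.max = 50,
                                     nstart = 5))
    })
  lab <- km$cluster
  # temporal re-ordering by mean ordinal
  mean_ord <- tapply(ord, lab, mean)
  remap <- stats::setNames(rank(mean_ord, ties.method = "first"),
                           names(mean_ord))
  lab <- as.integer(remap[as.character(lab)])
  score <- suppressWarnings(stats::cor(lab, ord, method = "spearman"))
  structure(lab, order_score = score, k = k)
}
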