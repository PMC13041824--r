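# Per-unit statistics: circular-shift flight modulation test, sparsity,
# wingbeat-phase locking with permutation nulls, sliding rasters, and
# cross-path phase decoding.

#' Spike counts per wingbeat cycle
#'
#' @param spike_times spike times of one unit (s).
#' @param wingbeats wingbeat table (or `wb_wingbeats`).
#' @return integer vector, one count per cycle.
#' @export
cycle_spike_counts <- function(spike_times, wingbeats) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  n <- nrow(wingbeats)
  if (!n) return(integer())
  counts <- integer(n)
  if (!length(spike_times)) return(counts)
  idx <- findInterval(spike_times, wingbeats$onset)
  ok <- idx >= 1 & spike_times < wingbeats$offset[pmax(idx, 1)]
  tab <- table(idx[ok])
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Fraction of wingbeats with zero spikes
#'
#' Sparsity index of a unit: the fraction of wingbeat cycles during which
#' it emitted no spikes.
#'
#' @inheritParams cycle_spike_counts
#' @return fraction in `[0, 1]`.
#' @export
silent_wingbeat_fraction <- function(spike_times, wingbeats) {
  counts <- cycle_spike_counts(spike_times, wingbeats)
  if (!length(counts)) return(NA_real_)
  mean(counts == 0)
}

# Per-flight smoothed rate traces resampled to a common length.
flight_rate_traces <- function(spike_times, flights, bin_s, smooth_sd_s,
                               n_out) {
  lapply(seq_len(nrow(flights)), function(i) {
    cnt <- bin_events(spike_times, flights$start[i], flights$end[i], bin_s)
    list(counts = cnt,
         trace = resample_series(gauss_smooth(cnt, smooth_sd_s / bin_s),
                                 n_out))
  })
}

mean_pairwise_cor <- function(traces) {
  M <- do.call(cbind, traces)
  sds <- apply(M, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2) return(NA_real_)
  C <- stats::cor(M[, keep, drop = FALSE])
  mean(C[upper.tri(C)])
}

#' Circular-shift test for flight modulation of a unit
#'
#' The statistic is the mean pairwise Pearson correlation of the unit's
#' smoothed firing-rate traces across flights of one path (10 ms bins,
#' 25 ms Gaussian smoothing, traces resampled to a common length). The
#' null distribution is obtained by circularly shifting each flight's spike
#' train by an independent uniform offset (minimum one wingbeat period, so
#' near-identity shifts are excluded) and recomputing the statistic;
#' `p = (1 + #null >= observed) / (1 + n_shuffles)`.
#'
#' @param spike_times spike times of one unit (s).
#' @param flights data.frame `start`, `end` for the flights of one path
#'   (>= 3 flights recommended).
#' @param n_shuffles permutation count.
#' @param bin_s,smooth_sd_s,n_out rate-trace parameters.
#' @param min_shift_s minimum circular shift (default one ~8 Hz period).
#' @return list with `stat`, `p`, `null` (vector). A silent unit returns
#'   `p = 1` with `stat = NA`.
#' @export
flight_modulation_test <- function(spike_times, flights, n_shuffles = 500,
                                   bin_s = 0.01, smooth_sd_s = 0.025,
                                   n_out = 200, min_shift_s = 0.125) {
  tr <- flight_rate_traces(spike_times, flights, bin_s, smooth_sd_s, n_out)
  total <- sum(vapply(tr, function(x) sum(x$counts), numeric(1)))
  if (total == 0)
    return(list(stat = NA_real_, p = 1, null = numeric()))
  obs <- mean_pairwise_cor(lapply(tr, `[[`, "trace"))
  if (is.na(obs))
    return(list(stat = NA_real_, p = 1, null = numeric()))
  sm_bins <- smooth_sd_s / bin_s
  min_shift <- max(1L, round(min_shift_s / bin_s))
  null <- vapply(seq_len(n_shuffles), function(s) {
    traces <- lapply(tr, function(x) {
      nb <- length(x$counts)
      if (nb <= 2 * min_shift) return(x$trace)
      sh <- sample(min_shift:(nb - min_shift), 1)
      cnt <- c(x$counts[(sh + 1):nb], x$counts[1:sh])
      resample_series(gauss_smooth(cnt, sm_bins), n_out)
    })
    mean_pairwise_cor(traces)
  }, numeric(1))
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= obs)) / (1 + length(null))
  list(stat = obs, p = p, null = null)
}

#' Flight-modulation test across a population with BH-FDR control
#'
#' @param spikes data.frame `unit_id`, `t`.
#' @param flights flights of one path.
#' @param units unit ids to test (default: all in `spikes`).
#' @param q FDR level for the Benjamini-Hochberg decision.
#' @param ... passed to [flight_modulation_test()].
#' @return data.frame: `unit_id`, `stat`, `p`, `p_adj`, `sig`.
#' @export
modulation_test_population <- function(spikes, flights,
                                       units = sort(unique(spikes$unit_id)),
                                       q = 0.01, ...) {
  res <- lapply(units, function(u) {
    r <- flight_modulation_test(spikes$t[spikes$unit_id == u], flights,
                                ...)
    data.frame(unit_id = u, stat = r$stat, p = r$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$sig <- out$p_adj <= q
  out
}

#' Permutation test for wingbeat-phase locking
#'
#' Tests whether a unit's spike phases are non-uniform using the resultant
#' vector length. The null preserves within-flight spike structure: each
#' flight's spike phases receive an independent uniform circular offset and
#' the RVL is recomputed; `p = (1 + #null >= observed) / (1 + n_shuffles)`.
#'
#' @param phases spike phases (radians).
#' @param flight_ids flight id per spike.
#' @param n_shuffles permutation count.
#' @param min_spikes minimum spike count; fewer returns `NA` p (excluded
#'   from testing).
#' @return list with `rvl`, `pref_phase`, `p`, `n`.
#' @export
phase_locking_test <- function(phases, flight_ids, n_shuffles = 500,
                               min_spikes = 20) {
  ok <- is.finite(phases)
  phases <- phases[ok]; flight_ids <- flight_ids[ok]
  n <- length(phases)
  r <- resultant_vector_length(phases)
  if (n < min_spikes)
    return(list(rvl = r$rvl, pref_phase = r$pref_phase, p = NA_real_,
                n = n))
  S <- vapply(split(phases, flight_ids),
              function(ph) sum(exp(1i * ph)), complex(1))
  nf <- length(S)
  null <- vapply(seq_len(n_shuffles), function(s) {
    Mod(sum(exp(1i * stats::runif(nf, 0, 2 * pi)) * S)) / n
  }, numeric(1))
  p <- (1 + sum(null >= r$rvl)) / (1 + n_shuffles)
  list(rvl = r$rvl, pref_phase = r$pref_phase, p = p, n = n)
}

#' Phase-locking statistics for all unit-path pairs with per-path BH-FDR
#'
#' @param spikes data.frame `unit_id`, `t`.
#' @param det `wb_wingbeats` detection result (for spike phases).
#' @param flights flights data.frame with `flight_id` and `path` labels.
#' @param q FDR level (applied within each path).
#' @param ... passed to [phase_locking_test()].
#' @return data.frame: `unit_id`, `path`, `n`, `rvl`, `pref_phase`, `p`,
#'   `p_adj`, `sig`.
#' @export
phase_locking_population <- function(spikes, det, flights, q = 0.05, ...) {
  units <- sort(unique(spikes$unit_id))
  out <- list()
  for (pa in sort(unique(flights$path))) {
    fl <- flights[flights$path == pa, ]
    for (u in units) {
      st <- spikes$t[spikes$unit_id == u]
      ph <- phase_at(det, st)
      sel <- !is.na(ph$phase) & ph$flight_id %in% fl$flight_id
      r <- phase_locking_test(ph$phase[sel], ph$flight_id[sel], ...)
      out[[length(out) + 1L]] <- data.frame(
        unit_id = u, path = pa, n = r$n, rvl = r$rvl,
        pref_phase = r$pref_phase, p = r$p)
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- NA_real_
  res$sig <- NA
  for (pa in unique(res$path)) {
    sel <- res$path == pa & !is.na(res$p)
    res$p_adj[sel] <- stats::p.adjust(res$p[sel], method = "BH")
    res$sig[sel] <- res$p_adj[sel] <= q
  }
  res
}

#' Sliding-window mean activity across the wingbeats of a path
#'
#' Mean per-cycle rate of each unit in sliding windows of `window`
#' wingbeat ordinal positions (default 5-wingbeat windows with 4-wingbeat
#' overlap), z-scored per unit across windows.
#'
#' @param count_matrix wingbeats x units matrix of per-cycle spike counts.
#' @param wingbeats matching wingbeat table (one path) with `ordinal` and
#'   `period_ms`.
#' @param window window size in wingbeats.
#' @param overlap window overlap in wingbeats (step = window - overlap).
#' @return matrix units x windows of z-scored mean rates, with window
#'   center positions in attribute `"position"`.
#' @export
sliding_phase_raster <- function(count_matrix, wingbeats, window = 5,
                                 overlap = 4) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  stopifnot(nrow(count_matrix) == nrow(wingbeats), overlap < window)
  max_ord <- max(wingbeats$ordinal)
  if (window > max_ord) stop("window exceeds path length in wingbeats")
  step <- window - overlap
  starts <- seq(1, max_ord - window + 1, by = step)
  rate <- count_matrix / (wingbeats$period_ms / 1000)
  M <- vapply(starts, function(s) {
    sel <- wingbeats$ordinal >= s & wingbeats$ordinal < s + window
    colMeans(rate[sel, , drop = FALSE])
  }, numeric(ncol(count_matrix)))
  M <- matrix(M, nrow = ncol(count_matrix))
  if (ncol(M) < 2) {
    # a single window spanning the path: return the plain means
    attr(M, "position") <- starts + (window - 1) / 2
    return(M)
  }
  Z <- t(apply(M, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  attr(Z, "position") <- starts + (window - 1) / 2
  Z
}

#' Binned population rates with wingbeat phase, for phase decoding
#'
#' @param spikes data.frame `unit_id`, `t`.
#' @param det `wb_wingbeats` detection result.
#' @param flights flights of one path.
#' @param units unit ids forming the population (column order).
#' @param bin_s bin width (s).
#' @return list: `R` (bins x units smoothed rates), `theta` (bin-center
#'   phase), `flight_id` per bin.
#' @export
population_phase_bins <- function(spikes, det, flights, units,
                                  bin_s = 0.025) {
  Rs <- list(); th <- c(); fid <- c()
  for (i in seq_len(nrow(flights))) {
    t0 <- flights$start[i]; t1 <- flights$end[i]
    nb <- floor((t1 - t0) / bin_s)
    if (nb < 2) next
    centers <- t0 + (seq_len(nb) - 0.5) * bin_s
    ph <- phase_at(det, centers)$phase
    M <- vapply(units, function(u) {
      cnt <- bin_events(spikes$t[spikes$unit_id == u], t0, t1, bin_s)
      gauss_smooth(cnt[seq_len(nb)], 1) / bin_s
    }, numeric(nb))
    keep <- !is.na(ph)
    Rs[[length(Rs) + 1L]] <- M[keep, , drop = FALSE]
    th <- c(th, ph[keep])
    fid <- c(fid, rep(flights$flight_id[i], sum(keep)))
  }
  list(R = do.call(rbind, Rs), theta = th, flight_id = fid)
}

# linear regression of (sin, cos) phase targets on population rates
phase_regression_fit <- function(R, theta) {
  X <- cbind(1, R)
  Y <- cbind(sin(theta), cos(theta))
  qr.solve(X, Y)
}

phase_regression_r2 <- function(B, R, theta) {
  X <- cbind(1, R)
  P <- X %*% B
  Y <- cbind(sin(theta), cos(theta))
  ss_res <- sum((Y - P)^2)
  ss_tot <- sum(sweep(Y, 2, colMeans(Y))^2)
  1 - ss_res / ss_tot
}

#' Cross-path wingbeat-phase decoding (normed R-squared)
#'
#' Least-squares regression from binned population rates onto the sine and
#' cosine of the wingbeat phase, trained on one path and evaluated on
#' another. The test-path R-squared (computed jointly on the sin/cos
#' targets; the decoded phase is `atan2(sin_hat, cos_hat)`) is normalized
#' by the within-train-path cross-validated R-squared, so a score of 1
#' means phase generalizes across paths as well as it does within the
#' training path.
#'
#' @param train,test lists from [population_phase_bins()] with matching
#'   unit columns.
#' @param k_folds cross-validation folds over training flights.
#' @return list: `r2_test`, `r2_cv_train`, `normed_r2` (NA with a warning
#'   when the denominator is <= 0), `theta_hat` (decoded test phase).
#' @export
cross_path_phase_decoder <- function(train, test, k_folds = 5) {
  B <- phase_regression_fit(train$R, train$theta)
  r2_test <- phase_regression_r2(B, test$R, test$theta)
  fl <- unique(train$flight_id)
  fold_of <- stats::setNames(rep_len(seq_len(k_folds), length(fl)), fl)
  folds <- fold_of[as.character(train$flight_id)]
  ss_res <- 0; ss_tot <- 0
  for (k in unique(folds)) {
    tr <- folds != k; te <- folds == k
    Bk <- phase_regression_fit(train$R[tr, , drop = FALSE],
                               train$theta[tr])
    Xte <- cbind(1, train$R[te, , drop = FALSE])
    Yte <- cbind(sin(train$theta[te]), cos(train$theta[te]))
    mu <- colMeans(cbind(sin(train$theta[tr]), cos(train$theta[tr])))
    ss_res <- ss_res + sum((Yte - Xte %*% Bk)^2)
    ss_tot <- ss_tot + sum(sweep(Yte, 2, mu)^2)
  }
  r2_cv <- 1 - ss_res / ss_tot
  normed <- if (r2_cv <= 0) {
    warning("within-path CV R2 <= 0; normed score undefined")
    NA_real_
  } else r2_test / r2_cv
  P <- cbind(1, test$R) %*% B
  list(r2_test = r2_test, r2_cv_train = r2_cv, normed_r2 = normed,
       theta_hat = atan2(P[, 1], P[, 2]) %% (2 * pi))
}
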