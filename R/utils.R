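# Shared numerical helpers: smoothing, resampling, analytic signal, binning.

#' Gaussian kernel normalized to unit sum
#' @keywords internal
gauss_kernel <- function(sd_bins, radius = ceiling(4 * sd_bins)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sd_bins^2))
  k / sum(k)
}

#' Zero-phase Gaussian smoothing
#'
#' Convolves `x` with a unit-sum Gaussian kernel; edges are handled by
#' replicate padding so the output has the same length and no phase lag.
#'
#' @param x numeric vector.
#' @param sd_bins kernel standard deviation in samples; `<= 0` returns `x`.
#' @return smoothed numeric vector of the same length.
#' @export
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0 || length(x) < 2) return(x)
  k <- gauss_kernel(sd_bins)
  r <- (length(k) - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1L):(r + n)]
}

#' Linear resampling of a series to a fixed number of points
#' @keywords internal
resample_series <- function(x, n_out) {
  n <- length(x)
  if (n == n_out) return(x)
  if (n < 2) return(rep(x[1], n_out))
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = n_out))$y
}

#' Central-difference derivative on a uniform grid
#' @keywords internal
num_deriv <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2) return(d)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' argument is the instantaneous phase; `Arg()` of the result for a pure
#' `cos(theta)` input is `theta`.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Bin event times into counts on a uniform grid
#' @param times event times (s).
#' @param t0,t1 interval bounds; events outside are dropped.
#' @param bin bin width (s).
#' @return integer vector of counts, one per bin.
#' @keywords internal
bin_events <- function(times, t0, t1, bin) {
  n_bins <- max(1L, ceiling((t1 - t0) / bin - 1e-9))
  times <- times[times >= t0 & times < t0 + n_bins * bin]
  if (!length(times)) return(integer(n_bins))
  idx <- floor((times - t0) / bin) + 1L
  tabulate(idx, nbins = n_bins)
}

#' Mean cosine similarity as a function of lag
#'
#' For each reference row and lag `k`, the cosine similarity between row `i`
#' and row `i + k` of the same block (e.g. wingbeats of one flight) is
#' computed and averaged across references and blocks. Zero rows are
#' excluded. At lag 0 the curve equals 1 whenever rows are nonzero.
#'
#' @param mat numeric matrix, rows = ordered observations (e.g. wingbeats).
#' @param block integer/factor vector of block ids per row (e.g. flight id);
#'   similarities are only taken within a block. Default: single block.
#' @param max_lag largest lag to evaluate.
#' @return data.frame with `lag`, `mean`, `sd`, `n` (pair count).
#' @export
cosine_lag_curve <- function(mat, block = rep(1L, nrow(mat)), max_lag = 10L) {
  stopifnot(nrow(mat) == length(block))
  nrm <- sqrt(rowSums(mat^2))
  ok <- nrm > 0
  res <- lapply(0:max_lag, function(k) {
    vals <- c()
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) <= k) next
      i <- idx[seq_len(length(idx) - k)]
      j <- idx[seq_len(length(idx) - k) + k]
      keep <- ok[i] & ok[j]
      if (!any(keep)) next
      num <- rowSums(mat[i[keep], , drop = FALSE] * mat[j[keep], , drop = FALSE])
      vals <- c(vals, num / (nrm[i[keep]] * nrm[j[keep]]))
    }
    c(mean = if (length(vals)) mean(vals) else NA_real_,
      sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
      n = length(vals))
  })
  out <- do.call(rbind, res)
  data.frame(lag = 0:max_lag, mean = out[, "mean"], sd = out[, "sd"],
             n = out[, "n"])
}

#' Fit an exponential decay constant to a similarity-lag curve
#'
#' Least-squares fit of `y = c + (y0 - c) * exp(-lag / L)` where `y0` is the
#' lag-0 value; used to compare the decay timescales of kinematic and neural
#' similarity curves.
#'
#' @param curve data.frame from [cosine_lag_curve()].
#' @return list with `L` (decay constant, lags), `asymptote`, `fitted`.
#' @export
fit_decay_constant <- function(curve) {
  lag <- curve$lag
  y <- curve$mean
  keep <- is.finite(y)
  lag <- lag[keep]; y <- y[keep]
  y0 <- y[lag == 0]
  if (!length(y0)) y0 <- max(y)
  obj <- function(par) {
    L <- exp(par[1]); cc <- par[2]
    sum((y - (cc + (y0 - cc) * exp(-lag / L)))^2)
  }
  fit <- stats::optim(c(log(2), min(y)), obj, method = "Nelder-Mead")
  L <- exp(fit$par[1]); cc <- fit$par[2]
  list(L = L, asymptote = cc,
       fitted = cc + (y0 - cc) * exp(-lag / L))
}

#' Participation ratio of a nonnegative spectrum
#'
#' `PR = (sum(v))^2 / sum(v^2)`; an effective count of how many entries of
#' `v` carry appreciable weight (1 for a single dominant entry, `length(v)`
#' for a flat spectrum).
#'
#' @param v nonnegative numeric vector (eigenvalues, squared weights, ...).
#' @return scalar participation ratio.
#' @export
participation_ratio <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v) || all(v == 0)) return(NA_real_)
  sum(v)^2 / sum(v^2)
}

#' z-score columns of a matrix, leaving constant columns at zero
#' @keywords internal
zscore_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  sweep(sweep(X, 2, mu), 2, sd, "/")
}

#' Stratified fold assignment
#' @keywords internal
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
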