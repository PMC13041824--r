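# Gaussian-process factor analysis (GPFA): shared latent factors with an
# independent squared-exponential GP prior per factor, fit to binned spike
# counts by EM; dimensionality selected by leave-one-neuron-out
# cross-validated prediction error.

# squared-exponential GP covariance over T bins (unit prior variance)
gp_kernel <- function(T_bins, tau_bins, gp_noise = 1e-3, jitter = 1e-6) {
  dt2 <- outer(seq_len(T_bins), seq_len(T_bins), "-")^2
  (1 - gp_noise) * exp(-dt2 / (2 * tau_bins^2)) +
    diag(gp_noise + jitter, T_bins)
}

# indices of factor i in the time-major latent vector (x_t stacked)
factor_idx <- function(i, k, T_bins) seq(i, by = k, length.out = T_bins)

# E-step quantities shared by all trials (same T): posterior covariance
# and the per-factor prior inverses / log-determinants
gpfa_posterior_ops <- function(C, R, tau_bins, k, T_bins,
                               gp_noise = 1e-3) {
  q <- nrow(C)
  kT <- k * T_bins
  Kinv_bar <- matrix(0, kT, kT)
  logdet_K <- 0
  for (i in seq_len(k)) {
    K <- gp_kernel(T_bins, tau_bins[i], gp_noise)
    ch <- chol(K)
    logdet_K <- logdet_K + 2 * sum(log(diag(ch)))
    idx <- factor_idx(i, k, T_bins)
    Kinv_bar[idx, idx] <- chol2inv(ch)
  }
  CRC <- t(C) %*% (C / R)            # k x k
  Sinv <- Kinv_bar
  for (t in seq_len(T_bins)) {
    idx <- ((t - 1) * k + 1):(t * k)
    Sinv[idx, idx] <- Sinv[idx, idx] + CRC
  }
  ch <- chol(Sinv)
  Sigma <- chol2inv(ch)
  list(Sigma = Sigma, logdet_Sinv = 2 * sum(log(diag(ch))),
       logdet_K = logdet_K, CRC = CRC)
}

# posterior mean of the time-major latent vector for one trial
gpfa_post_mean <- function(ops, C, d, R, Y) {
  rhs <- as.vector(t(C) %*% ((Y - d) / R))    # time-major
  ops$Sigma %*% rhs
}

#' Fit a GPFA model by EM
#'
#' Observation model `y_t = C x_t + d + eps`, `eps ~ N(0, diag(R))`, with
#' an independent unit-variance squared-exponential GP prior per latent
#' factor; each factor's timescale is optimized in the M-step, so slow
#' flight-level and fast wingbeat-level factors can coexist. Spike counts
#' are square-root transformed by default (variance stabilization).
#'
#' @param trials list of units x bins spike-count matrices (equal sizes).
#' @param n_factors number of latent factors.
#' @param bin_s bin width in seconds.
#' @param transform `"sqrt"` or `"none"`.
#' @param em_iters maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param tau_init_s initial GP timescale (s).
#' @param tau_range_s allowed timescale range (s).
#' @param gp_noise GP kernel noise floor (keeps kernels well-conditioned).
#' @return a `wb_gpfa` fit: `C`, `d`, `R`, `tau_s` (per-factor
#'   timescales), `loglik` (training trace), dimensions and settings.
#' @export
gpfa_fit <- function(trials, n_factors, bin_s = 0.02,
                     transform = c("sqrt", "none"), em_iters = 25,
                     tol = 1e-5, tau_init_s = 0.1,
                     tau_range_s = c(0.01, 1), gp_noise = 1e-3) {
  transform <- match.arg(transform)
  Ys <- lapply(trials, function(Y) {
    Y <- as.matrix(Y)
    if (transform == "sqrt") sqrt(Y) else Y
  })
  q <- nrow(Ys[[1]]); T_bins <- ncol(Ys[[1]])
  stopifnot(all(vapply(Ys, nrow, 1L) == q),
            all(vapply(Ys, ncol, 1L) == T_bins),
            n_factors >= 1, n_factors < q)
  k <- n_factors
  n_tr <- length(Ys)
  # initialization from PCA of the pooled data
  Yall <- do.call(cbind, Ys)
  d <- rowMeans(Yall)
  Yc <- Yall - d
  sv <- svd(Yc, nu = k, nv = 0)
  C <- sv$u %*% diag(sv$d[seq_len(k)] / sqrt(ncol(Yall)), k)
  R <- pmax(apply(Yc, 1, stats::var) -
              rowSums(C^2), 1e-3)
  tau <- rep(tau_init_s / bin_s, k)
  ll_trace <- numeric(0)
  for (iter in seq_len(em_iters)) {
    ops <- gpfa_posterior_ops(C, R, tau, k, T_bins, gp_noise)
    # log-likelihood via the Woodbury determinant identity
    ll <- 0
    Sx <- matrix(0, k, 1)
    Sxx <- matrix(0, k, k)
    Syx <- matrix(0, q, k)
    Sy <- matrix(0, q, 1)
    Syy2 <- numeric(q)
    Ssum <- matrix(0, k * T_bins, k * T_bins)   # sum of E[xx'] (big)
    for (m in seq_len(n_tr)) {
      Y <- Ys[[m]]
      mu <- gpfa_post_mean(ops, C, d, R, Y)
      rhs <- as.vector(t(C) %*% ((Y - d) / R))
      quad <- sum((Y - d)^2 / R) - sum(rhs * mu)
      ll <- ll - 0.5 * (T_bins * sum(log(R)) + ops$logdet_K +
                          ops$logdet_Sinv + quad +
                          q * T_bins * log(2 * pi))
      Mu <- matrix(mu, k, T_bins)               # factors x time
      Ssum <- Ssum + ops$Sigma + tcrossprod(mu)
      SigT <- matrix(0, k, k)
      for (t in seq_len(T_bins)) {
        idx <- ((t - 1) * k + 1):(t * k)
        SigT <- SigT + ops$Sigma[idx, idx]
      }
      Sxx <- Sxx + SigT + tcrossprod(Mu)
      Sx <- Sx + rowSums(Mu)
      Syx <- Syx + Y %*% t(Mu)
      Sy <- Sy + rowSums(Y)
      Syy2 <- Syy2 + rowSums(Y^2)
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1) {
      prev <- ll_trace[iter - 1]
      if (ll < prev - 1e-2 * (1 + abs(prev)))
        stop("GPFA EM log-likelihood decreased (iter ", iter, "): ",
             signif(prev, 8), " -> ", signif(ll, 8))
      if (abs(ll - prev) < tol * abs(prev)) break
    }
    N_obs <- n_tr * T_bins
    G <- rbind(cbind(Sxx, Sx), cbind(t(Sx), N_obs))
    Cd <- cbind(Syx, Sy) %*% solve(G)
    C <- Cd[, seq_len(k), drop = FALSE]
    d <- Cd[, k + 1]
    R <- pmax((Syy2 - rowSums(Cd * cbind(Syx, Sy))) / N_obs, 1e-6)
    # per-factor timescale update: minimize logdet K + tr(K^{-1} S_i)
    for (i in seq_len(k)) {
      idx <- factor_idx(i, k, T_bins)
      Si <- Ssum[idx, idx]
      obj <- function(log_tau) {
        K <- gp_kernel(T_bins, exp(log_tau), gp_noise)
        ch <- tryCatch(chol(K), error = function(e) NULL)
        if (is.null(ch)) return(1e12)
        n_tr * 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * Si)
      }
      opt <- stats::optimize(obj, log(tau_range_s / bin_s))
      tau[i] <- exp(opt$minimum)
    }
  }
  structure(list(C = C, d = d, R = R, tau_s = tau * bin_s, k = k,
                 T_bins = T_bins, bin_s = bin_s, transform = transform,
                 gp_noise = gp_noise, loglik = ll_trace),
            class = "wb_gpfa")
}

#' Held-out log-likelihood of a GPFA fit
#'
#' @param fit a `wb_gpfa` object.
#' @param trials list of units x bins count matrices.
#' @return total log-likelihood.
#' @export
gpfa_loglik <- function(fit, trials) {
  Ys <- lapply(trials, function(Y) {
    if (fit$transform == "sqrt") sqrt(as.matrix(Y)) else as.matrix(Y)
  })
  tau <- fit$tau_s / fit$bin_s
  ops <- gpfa_posterior_ops(fit$C, fit$R, tau, fit$k, fit$T_bins,
                            fit$gp_noise)
  ll <- 0
  for (Y in Ys) {
    mu <- gpfa_post_mean(ops, fit$C, fit$d, fit$R, Y)
    rhs <- as.vector(t(fit$C) %*% ((Y - fit$d) / fit$R))
    quad <- sum((Y - fit$d)^2 / fit$R) - sum(rhs * mu)
    ll <- ll - 0.5 * (fit$T_bins * sum(log(fit$R)) + ops$logdet_K +
                        ops$logdet_Sinv + quad +
                        nrow(Y) * fit$T_bins * log(2 * pi))
  }
  ll
}

#' Posterior latent trajectories
#'
#' @param fit a `wb_gpfa` object.
#' @param trials list of units x bins count matrices.
#' @return list of factors x bins posterior-mean latent trajectories.
#' @export
gpfa_latents <- function(fit, trials) {
  Ys <- lapply(trials, function(Y) {
    if (fit$transform == "sqrt") sqrt(as.matrix(Y)) else as.matrix(Y)
  })
  tau <- fit$tau_s / fit$bin_s
  ops <- gpfa_posterior_ops(fit$C, fit$R, tau, fit$k, fit$T_bins,
                            fit$gp_noise)
  lapply(Ys, function(Y) {
    matrix(gpfa_post_mean(ops, fit$C, fit$d, fit$R, Y), fit$k,
           fit$T_bins)
  })
}

#' Leave-one-neuron-out prediction error of a GPFA fit
#'
#' For each unit, latents are inferred from the remaining units only and
#' the held-out unit's (transformed) activity is predicted as
#' `C_j E[x] + d_j`; the error is the mean squared prediction error over
#' units, bins and trials.
#'
#' @param fit a `wb_gpfa` object.
#' @param trials list of units x bins count matrices.
#' @return list: `mse` (overall), `unit_mse`.
#' @export
gpfa_lono_error <- function(fit, trials) {
  Ys <- lapply(trials, function(Y) {
    if (fit$transform == "sqrt") sqrt(as.matrix(Y)) else as.matrix(Y)
  })
  q <- nrow(Ys[[1]])
  tau <- fit$tau_s / fit$bin_s
  se <- numeric(q); n_obs <- 0
  for (j in seq_len(q)) {
    Cj <- fit$C[-j, , drop = FALSE]
    Rj <- fit$R[-j]
    dj <- fit$d[-j]
    ops <- gpfa_posterior_ops(Cj, Rj, tau, fit$k, fit$T_bins,
                              fit$gp_noise)
    for (Y in Ys) {
      mu <- gpfa_post_mean(ops, Cj, dj, Rj, Y[-j, , drop = FALSE])
      Mu <- matrix(mu, fit$k, fit$T_bins)
      pred <- as.numeric(fit$C[j, , drop = FALSE] %*% Mu) + fit$d[j]
      se[j] <- se[j] + sum((Y[j, ] - pred)^2)
    }
  }
  n_obs <- length(Ys) * fit$T_bins
  list(mse = mean(se / n_obs), unit_mse = se / n_obs)
}

#' GPFA dimensionality by leave-one-neuron-out model selection
#'
#' For every candidate dimensionality the model is fit on training trials
#' and the leave-one-neuron-out prediction error is evaluated on held-out
#' trials (trial-level cross-validation keeps the per-unit loadings from
#' absorbing the held-out unit's noise). The selected range is all
#' dimensionalities whose error is within 1% of the minimum
#' (`error <= (1 + threshold) * min`).
#'
#' @param trials list of units x bins count matrices.
#' @param dims candidate factor counts (each `< #units`).
#' @param threshold relative error threshold defining the selected range.
#' @param n_folds trial-level cross-validation folds (interleaved trial
#'   assignment); 1 evaluates on the training trials.
#' @param ... passed to [gpfa_fit()].
#' @return list: `dims`, `errors`, `selected` (range of dims within
#'   threshold), `best` (argmin).
#' @export
gpfa_dimensionality <- function(trials, dims = 1:5, threshold = 0.01,
                                n_folds = 2, ...) {
  q <- nrow(as.matrix(trials[[1]]))
  dims <- dims[dims >= 1 & dims < q]
  if (!length(dims)) stop("no feasible dimensionalities in grid")
  n_tr <- length(trials)
  n_folds <- max(1L, min(n_folds, n_tr - 1L))
  fold <- rep_len(seq_len(n_folds), n_tr)
  errors <- rep(NA_real_, length(dims))
  for (i in seq_along(dims)) {
    err_i <- 0; n_i <- 0
    ok <- TRUE
    for (f in seq_len(n_folds)) {
      tr_idx <- if (n_folds == 1) seq_len(n_tr) else which(fold != f)
      te_idx <- if (n_folds == 1) seq_len(n_tr) else which(fold == f)
      fit <- tryCatch(gpfa_fit(trials[tr_idx], dims[i], ...),
                      error = function(e) {
                        message("dim ", dims[i], " skipped: ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(fit)) { ok <- FALSE; break }
      err_i <- err_i + gpfa_lono_error(fit, trials[te_idx])$mse *
        length(te_idx)
      n_i <- n_i + length(te_idx)
    }
    if (ok) errors[i] <- err_i / n_i
  }
  okd <- which(is.finite(errors))
  best <- okd[which.min(errors[okd])]
  sel <- dims[is.finite(errors) & errors <= (1 + threshold) *
                errors[best]]
  list(dims = dims, errors = errors, selected = sel, best = dims[best])
}
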