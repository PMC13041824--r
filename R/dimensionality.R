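# Group-mean population matrices and PCA dimensionality.

#' Build the group-mean population matrix
#'
#' Each wingbeat cycle is time-warped to `bins_per_cycle` equal fractions
#' of the cycle; per-unit rates are averaged across all cycles of a
#' wingbeat group, and group means are concatenated into a units x
#' (groups * bins) matrix. Units whose split-half (odd vs even cycles)
#' reliability falls below `reliability_min` are removed, as are groups
#' with fewer than `min_trials` cycles.
#'
#' @param spikes data.frame `unit_id`, `t`.
#' @param wingbeats wingbeat table with a `group` column.
#' @param units unit ids (row order).
#' @param bins_per_cycle warped time bins per cycle.
#' @param smooth_bins Gaussian sd (bins) applied along each cycle trace.
#' @param min_trials minimum cycles per retained group.
#' @param reliability_min split-half correlation threshold per unit
#'   (`-Inf` disables the filter).
#' @return list: `M` (units x groups*bins rate matrix), `units`, `groups`
#'   (retained, ordered), `bins_per_cycle`, `reliability` (per input
#'   unit).
#' @export
build_group_mean_matrix <- function(spikes, wingbeats, units,
                                    bins_per_cycle = 15, smooth_bins = 1,
                                    min_trials = 5,
                                    reliability_min = 0.3) {
  if (inherits(wingbeats, "wb_wingbeats")) wingbeats <- wingbeats$wingbeats
  tab <- table(wingbeats$group)
  groups <- as.integer(names(tab)[tab >= min_trials])
  if (!length(groups)) stop("no wingbeat group has >= min_trials cycles")
  dropped <- setdiff(unique(wingbeats$group), groups)
  if (length(dropped))
    message("dropping ", length(dropped), " groups below min_trials")
  groups <- sort(groups)
  # per-cycle warped rate traces per unit
  cyc_rate <- function(u, rows) {
    st <- spikes$t[spikes$unit_id == u]
    out <- matrix(0, length(rows), bins_per_cycle)
    for (r in seq_along(rows)) {
      i <- rows[r]
      on <- wingbeats$onset[i]; off <- wingbeats$offset[i]
      sel <- st[st >= on & st < off]
      if (length(sel)) {
        b <- pmin(floor((sel - on) / (off - on) * bins_per_cycle) + 1L,
                  bins_per_cycle)
        out[r, ] <- tabulate(b, bins_per_cycle)
      }
      out[r, ] <- out[r, ] / ((off - on) / bins_per_cycle)
    }
    out
  }
  half_means <- function(Tr, idx) {
    colMeans(Tr[idx, , drop = FALSE])
  }
  n_u <- length(units)
  M_full <- matrix(NA_real_, n_u, length(groups) * bins_per_cycle)
  rel <- rep(NA_real_, n_u)
  for (j in seq_len(n_u)) {
    odd_trace <- c(); even_trace <- c(); mean_trace <- c()
    for (g in groups) {
      rows <- which(wingbeats$group == g)
      Tr <- cyc_rate(units[j], rows)
      Tr <- t(apply(Tr, 1, gauss_smooth, sd_bins = smooth_bins))
      mean_trace <- c(mean_trace, colMeans(Tr))
      odd_trace <- c(odd_trace,
                     half_means(Tr, seq(1, nrow(Tr), by = 2)))
      even_trace <- c(even_trace,
                      half_means(Tr, seq(2, nrow(Tr), by = 2)))
    }
    M_full[j, ] <- mean_trace
    s1 <- stats::sd(odd_trace); s2 <- stats::sd(even_trace)
    rel[j] <- if (s1 > 0 && s2 > 0) stats::cor(odd_trace, even_trace)
              else NA_real_
  }
  keep <- !is.na(rel) & rel >= reliability_min
  if (is.infinite(reliability_min)) keep <- rep(TRUE, n_u)
  list(M = M_full[keep, , drop = FALSE], units = units[keep],
       groups = groups, bins_per_cycle = bins_per_cycle,
       reliability = stats::setNames(rel, units))
}

#' PCA dimensionality of a population matrix
#'
#' Rows (units) are centered; the eigenvalue spectrum of the unit
#' covariance is computed by SVD. `n90` is the smallest number of
#' principal components whose cumulative explained variance reaches 90%.
#'
#' @param M units x samples matrix (e.g. from
#'   [build_group_mean_matrix()]).
#' @param ev_target cumulative explained-variance target.
#' @return list: `eigenvalues`, `cum_ev`, `n90`, `n90_frac`
#'   (`n90 / #units`), `n_units`.
#' @export
pca_dimensionality <- function(M, ev_target = 0.9) {
  Mc <- M - rowMeans(M)
  sv <- svd(Mc, nu = 0, nv = 0)$d
  lam <- sv^2 / max(1, (ncol(M) - 1))
  lam <- c(lam, rep(0, max(0, nrow(M) - length(lam))))
  tot <- sum(lam)
  if (tot <= 0) stop("matrix has zero variance")
  cum_ev <- cumsum(lam) / tot
  n90 <- which(cum_ev >= ev_target)[1]
  list(eigenvalues = lam, cum_ev = cum_ev, n90 = n90,
       n90_frac = n90 / nrow(M), n_units = nrow(M))
}

#' Participation ratio of the core and extended subspaces
#'
#' Splits the eigenvalue spectrum at the component reaching
#' `core_fraction` (default 50%) of cumulative variance: the "core"
#' subspace is the leading PCs up to that point and the "extended"
#' subspace all remaining PCs. The participation ratio of each subset is
#' normalized by the subset size, so 1 indicates a flat (isotropic)
#' spectrum within the subset.
#'
#' @param eigenvalues nonnegative spectrum (descending).
#' @param core_fraction cumulative-variance split point.
#' @return list: `k_core`, `pr_core`, `pr_extended`, `pr_core_norm`,
#'   `pr_extended_norm` (the last is `NA` with a warning when the
#'   extended set is empty).
#' @export
participation_ratio_split <- function(eigenvalues, core_fraction = 0.5) {
  lam <- eigenvalues
  stopifnot(all(lam >= -1e-12))
  cum <- cumsum(lam) / sum(lam)
  k_core <- which(cum >= core_fraction)[1]
  core <- lam[seq_len(k_core)]
  ext <- lam[-seq_len(k_core)]
  pr_c <- participation_ratio(core)
  if (!length(ext) || all(ext == 0)) {
    warning("extended subspace is empty")
    return(list(k_core = k_core, pr_core = pr_c,
                pr_extended = NA_real_,
                pr_core_norm = pr_c / k_core,
                pr_extended_norm = NA_real_))
  }
  pr_e <- participation_ratio(ext)
  list(k_core = k_core, pr_core = pr_c, pr_extended = pr_e,
       pr_core_norm = pr_c / k_core,
       pr_extended_norm = pr_e / length(ext))
}
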