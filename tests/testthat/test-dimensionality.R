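# Group-mean matrices, PCA dimensionality, participation-ratio splits,
# dPCA and GPFA.

test_that("group-mean matrix averages match a brute-force trial loop", {
  on <- seq(0, 1.1, by = 0.1)
  w <- data.frame(wingbeat_id = 1:12, flight_id = rep(1:3, each = 4),
                  onset = on[1:12], offset = on[1:12] + 0.1,
                  period_ms = 100, ordinal = rep(1:4, 3),
                  group = rep(1:4, 3))
  set.seed(18)
  sp <- data.frame(unit_id = 1,
                   t = sort(runif(60, 0, 1.2)))
  gm <- build_group_mean_matrix(sp, w, units = 1, bins_per_cycle = 5,
                                smooth_bins = 0, min_trials = 3,
                                reliability_min = -Inf)
  # brute force: per-cycle binned rates averaged over the 3 trials
  for (g in 1:4) {
    rows <- which(w$group == g)
    acc <- matrix(0, length(rows), 5)
    for (r in seq_along(rows)) {
      st <- sp$t[sp$t >= w$onset[rows[r]] & sp$t < w$offset[rows[r]]]
      b <- pmin(floor((st - w$onset[rows[r]]) / 0.1 * 5) + 1, 5)
      acc[r, ] <- tabulate(b, 5) / 0.02
    }
    expect_equal(gm$M[1, ((g - 1) * 5 + 1):(g * 5)],
                 colMeans(acc), tolerance = 1e-9)
  }
  # a group below min_trials is dropped with a message
  w2 <- w[-c(4, 8), ]
  expect_message(
    gm2 <- build_group_mean_matrix(sp, w2, units = 1,
                                   bins_per_cycle = 5, smooth_bins = 0,
                                   min_trials = 3,
                                   reliability_min = -Inf),
    "dropping")
  expect_equal(length(gm2$groups), 3)
})

test_that("reliability filter removes inconsistent units", {
  set.seed(19)
  n_wb <- 40
  on <- (0:(n_wb - 1)) * 0.1
  w <- data.frame(wingbeat_id = 1:n_wb, flight_id = 1, onset = on,
                  offset = on + 0.1, period_ms = 100,
                  ordinal = rep(1:4, 10), group = rep(1:4, 10))
  # unit 1 reliable (fires every group-1 cycle), unit 2 pure noise
  sp <- rbind(data.frame(unit_id = 1, t = on[w$group == 1] + 0.05),
              data.frame(unit_id = 2, t = runif(15, 0, 4)))
  gm <- build_group_mean_matrix(sp, w, units = 1:2, bins_per_cycle = 5,
                                min_trials = 5, reliability_min = 0.3)
  expect_true(1 %in% gm$units)
  expect_false(2 %in% gm$units)
})

test_that("PCA spectrum equals brute-force SVD and finds planted rank", {
  set.seed(20)
  M <- matrix(rnorm(40), 5, 8)
  p <- pca_dimensionality(M)
  Mc <- M - rowMeans(M)
  lam_o <- svd(Mc)$d^2 / (ncol(M) - 1)
  expect_equal(p$eigenvalues[seq_along(lam_o)], lam_o,
               tolerance = 1e-10)
  expect_true(all(diff(p$cum_ev) >= -1e-12))
  # rank-1 matrix
  r1 <- pca_dimensionality(outer(rnorm(6), rnorm(30)))
  expect_equal(r1$n90, 1)
  expect_equal(r1$cum_ev[1], 1, tolerance = 1e-12)
  # planted k-factor data at low noise: n90 in [k-1, k+2]
  k <- 4
  L <- matrix(rnorm(30 * k), 30)
  Fm <- matrix(rnorm(k * 300), k, 300)
  X <- L %*% Fm + matrix(rnorm(30 * 300, 0, 0.05), 30)
  pk <- pca_dimensionality(X)
  expect_gte(pk$n90, k - 1)
  expect_lte(pk$n90, k + 2)
  # isotropic rows: n90/d near 0.9
  iso <- pca_dimensionality(matrix(rnorm(50 * 5000), 50))
  expect_lt(abs(iso$n90_frac - 0.9), 0.06)
})

test_that("participation ratio split follows the formula", {
  pr <- participation_ratio_split(c(2, 1), core_fraction = 0.99)
  expect_equal(pr$pr_core, 9 / 5)
  expect_equal(participation_ratio(c(2, 1)), oracle_pr(c(2, 1)))
  # flat spectrum: normalized PRs equal 1
  fl <- participation_ratio_split(rep(1, 10))
  expect_equal(fl$pr_core_norm, 1)
  expect_equal(fl$pr_extended_norm, 1)
  # one dominant eigenvalue: PR of the core is 1
  dm <- participation_ratio_split(c(10, rep(1e-6, 5)))
  expect_equal(dm$pr_core, 1, tolerance = 1e-3)
  expect_warning(participation_ratio_split(c(1)), "empty")
})

test_that("dPCA marginalizations reconstruct the centered tensor and
           split variance", {
  set.seed(21)
  X <- array(rnorm(10 * 8 * 5), c(10, 8, 5))
  m <- dpca_marginalize(X)
  expect_equal(m$Xt + m$Xg, m$Xc, tolerance = 1e-12)
  # marginalizations are orthogonal
  expect_lt(abs(sum(m$Xt * m$Xg)), 1e-9)
  # data identical across groups: group-specific EV ~ 0
  base <- array(rep(rnorm(10 * 8), 5), c(10, 8, 5))
  trials <- array(0, c(10, 8, 5, 4))
  for (r in 1:4) trials[, , , r] <- base +
      array(rnorm(10 * 8 * 5, 0, 0.05), c(10, 8, 5))
  dp <- dpca_decompose(trials)
  expect_lt(dp$ev_group, 0.1)
  expect_lt(dp$ratio, 0.15)
})

test_that("dPCA recovers a planted specific/invariant variance ratio", {
  set.seed(22)
  n_u <- 25; Tb <- 20; G <- 8; R <- 6
  sh <- outer(rnorm(n_u), sin(seq(0, 2 * pi, length.out = Tb)))
  bg <- matrix(rnorm(n_u * G), n_u, G)
  bg <- sweep(bg, 1, rowMeans(bg))
  gs <- array(0, c(n_u, Tb, G))
  for (g in 1:G) gs[, , g] <- outer(bg[, g],
                                    cos(seq(0, 2 * pi,
                                            length.out = Tb)))
  for (rho in c(2, 6)) {
    gs_s <- gs * sqrt(rho * sum(sh^2) * G / sum(gs^2))
    trials <- array(0, c(n_u, Tb, G, R))
    for (r in 1:R) for (g in 1:G)
      trials[, , g, r] <- sh + gs_s[, , g] +
        matrix(rnorm(n_u * Tb, 0, 0.3), n_u)
    dp <- dpca_decompose(trials)
    expect_lt(abs(dp$ratio - rho) / rho, 0.15)
    # the invariant dPC1 traces overlap across groups for the shared
    # component
    inv1 <- dp$components$time$scores[1, , ]
    expect_gt(min(cor(inv1)), 0.95)
  }
})

test_that("GPFA recovers planted loadings, timescales and model order", {
  set.seed(23)
  q <- 12; Tb <- 40
  # zero-noise single-factor data: loading direction recovered
  tau_b <- 8
  Kc <- chol(wingbeat:::gp_kernel(Tb, tau_b))
  C1 <- rnorm(q)
  trials1 <- lapply(1:6, function(m) {
    x <- as.numeric(t(Kc) %*% rnorm(Tb))
    outer(C1, x) + matrix(rnorm(q * Tb, 0, 0.01), q)
  })
  f1 <- gpfa_fit(trials1, 1, transform = "none", em_iters = 40)
  ch <- abs(sum(f1$C[, 1] * C1) / sqrt(sum(f1$C^2) * sum(C1^2)))
  expect_gt(ch, 0.99)
  # timescale recovered within a factor of 2 at moderate noise
  trials2 <- lapply(1:10, function(m) {
    x <- as.numeric(t(Kc) %*% rnorm(Tb))
    outer(C1, x) + matrix(rnorm(q * Tb, 0, 0.5), q)
  })
  f2 <- gpfa_fit(trials2, 1, transform = "none", em_iters = 40,
                 bin_s = 0.02)
  tau_fit_b <- f2$tau_s / 0.02
  expect_gt(tau_fit_b, tau_b / 2)
  expect_lt(tau_fit_b, tau_b * 2)
  # training log-likelihood is non-decreasing over EM iterations
  expect_true(all(diff(f2$loglik) > -1e-6 * abs(f2$loglik[-1])))
})

test_that("held-out likelihood prefers the planted dimensionality over
           an undersized model", {
  set.seed(24)
  trials <- simulate_factor_trials(n_units = 12, n_bins = 30,
                                   n_trials = 10, n_factors = 3)
  f3 <- gpfa_fit(trials[1:8], 3, em_iters = 30)
  f1 <- gpfa_fit(trials[1:8], 1, em_iters = 30)
  expect_gt(gpfa_loglik(f3, trials[9:10]),
            gpfa_loglik(f1, trials[9:10]))
})

test_that("independent units select dimensionality 1 and the error
           curve has no gaps", {
  set.seed(25)
  trials <- lapply(1:8, function(m) matrix(rpois(12 * 30, 3), 12, 30))
  gd <- gpfa_dimensionality(trials, dims = 1:3, em_iters = 15)
  expect_true(all(is.finite(gd$errors)))
  expect_equal(length(gd$errors), 3)
  expect_true(1 %in% gd$selected)
})
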