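# Per-unit statistics: RVL, sparsity, circular-shift modulation test,
# phase-locking permutation test, sliding rasters and phase decoding.

test_that("resultant vector length matches the complex-sum oracle", {
  r <- resultant_vector_length(rep(1.3, 7))
  expect_equal(r$rvl, 1, tolerance = 1e-12)
  expect_equal(r$pref_phase, 1.3, tolerance = 1e-12)
  # symmetric four-point configuration cancels
  r2 <- resultant_vector_length(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(r2$rvl, 0, tolerance = 1e-12)
  # {0, 0, pi/2}: RVL sqrt(5)/3, preferred atan2(1, 2)
  r3 <- resultant_vector_length(c(0, 0, pi / 2))
  expect_equal(r3$rvl, sqrt(5) / 3, tolerance = 1e-12)
  expect_equal(r3$pref_phase, atan2(1, 2), tolerance = 1e-12)
  o <- oracle_rvl(c(0, 0, pi / 2))
  expect_equal(r3$rvl, o$rvl)
  expect_equal(r3$pref_phase, o$pref)
  # empty input flagged
  r4 <- resultant_vector_length(numeric())
  expect_true(is.na(r4$rvl) && r4$n == 0)
})

test_that("RVL of von Mises samples converges to the Bessel ratio", {
  set.seed(4)
  for (kappa in c(1, 4)) {
    # inversion-free von Mises sampling via rejection (Best-Fisher)
    n <- 1e4
    ph <- numeric(0)
    while (length(ph) < n) {
      cand <- runif(n, -pi, pi)
      keep <- runif(n) < exp(kappa * (cos(cand) - 1))
      ph <- c(ph, cand[keep])
    }
    ph <- ph[1:n]
    r <- resultant_vector_length(ph)
    expect_lt(abs(r$rvl - von_mises_rvl(kappa)), 0.02)
  }
})

test_that("silent wingbeat fraction counts empty cycles", {
  on <- seq(0, 0.9, by = 0.1)
  w <- data.frame(wingbeat_id = 1:10, onset = on, offset = on + 0.1)
  # spikes in 3 of 10 cycles -> 0.7
  expect_equal(silent_wingbeat_fraction(c(0.05, 0.32, 0.85), w), 0.7)
  expect_equal(silent_wingbeat_fraction(on + 0.05, w), 0)
  expect_equal(silent_wingbeat_fraction(numeric(), w), 1)
  # barcode row sums equal per-cycle active-unit counts
  sp <- data.frame(unit_id = c(1, 1, 2), t = c(0.05, 0.32, 0.32))
  B <- build_barcodes(sp, w, units = 1:2)
  expect_equal(unname(rowSums(B)), c(1, 0, 0, 2, rep(0, 6)))
  expect_equal(unname(colSums(B)), c(2, 1))
})

test_that("circular-shift modulation test separates structure from
           noise", {
  s <- std_session()
  p1 <- std_path_wingbeats(1)
  set.seed(6)
  # a group-selective unit (sparse, reliable) is strongly modulated
  gsel <- which(vapply(s$ground_truth$units,
                       function(u) u$class == "group_selective",
                       logical(1)))[1]
  r <- flight_modulation_test(s$spikes$t[s$spikes$unit_id == gsel],
                              p1$flights, n_shuffles = 200)
  expect_lte(r$p, 0.01)
  # permutation convention: p >= 1/(1+N)
  expect_gte(r$p, 1 / 201)
  # a silent unit returns p = 1 by convention
  r0 <- flight_modulation_test(numeric(), p1$flights, n_shuffles = 50)
  expect_equal(r0$p, 1)
  # the statistic is invariant to a common shift of all flights
  st <- s$spikes$t[s$spikes$unit_id == gsel]
  shift_all <- function(ts, fl, dt) {
    out <- ts
    for (i in seq_len(nrow(fl))) {
      sel <- ts >= fl$start[i] & ts <= fl$end[i]
      dur <- fl$end[i] - fl$start[i]
      out[sel] <- fl$start[i] + (ts[sel] - fl$start[i] + dt) %% dur
    }
    out
  }
  r1 <- flight_modulation_test(st, p1$flights, n_shuffles = 2)
  r2 <- flight_modulation_test(shift_all(st, p1$flights, 0.4),
                               p1$flights, n_shuffles = 2)
  expect_equal(r1$stat, r2$stat, tolerance = 0.05)
})

test_that("phase-locking test has power for planted units and respects
           invariances", {
  s <- std_session()
  a <- std_analysis()
  gt <- s$ground_truth
  tonic <- which(vapply(gt$units,
                        function(u) u$class == "tonic_phase_locked",
                        logical(1)))
  set.seed(7)
  st <- s$spikes$t[s$spikes$unit_id == tonic[1]]
  ph <- phase_at(a$det, st)
  ok <- !is.na(ph$phase)
  r <- phase_locking_test(ph$phase[ok], ph$flight_id[ok],
                          n_shuffles = 200)
  expect_lte(r$p, 1 / 100)
  # global rotation leaves RVL and p unchanged (same null seed)
  set.seed(8)
  ra <- phase_locking_test(ph$phase[ok], ph$flight_id[ok],
                           n_shuffles = 100)
  set.seed(8)
  rb <- phase_locking_test((ph$phase[ok] + 1.1) %% (2 * pi),
                           ph$flight_id[ok], n_shuffles = 100)
  expect_equal(ra$rvl, rb$rvl, tolerance = 1e-12)
  expect_equal(ra$p, rb$p)
  # too few spikes: excluded (NA p)
  rf <- phase_locking_test(runif(5, 0, 2 * pi), rep(1, 5),
                           n_shuffles = 50)
  expect_true(is.na(rf$p))
})

test_that("BH decisions equal the textbook step-up procedure", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    p <- round(runif(n), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    ours <- stats::p.adjust(p, method = "BH") <= q
    expect_equal(ours, oracle_bh(p, q))
  }
})

test_that("sliding wingbeat raster z-scores and localizes activity", {
  # constant-rate unit: flat zero after z-scoring
  n_wb <- 20
  w <- data.frame(wingbeat_id = 1:n_wb, flight_id = 1,
                  onset = (0:(n_wb - 1)) * 0.125,
                  offset = (1:n_wb) * 0.125,
                  period_ms = 125, ordinal = 1:n_wb)
  counts <- cbind(const = rep(2, n_wb),
                  bump = c(rep(0, 9), 5, 6, 5, rep(0, 8)))
  Z <- sliding_phase_raster(counts, w, window = 5, overlap = 4)
  expect_equal(unname(Z[1, ]), rep(0, ncol(Z)))
  pos <- attr(Z, "position")
  expect_equal(pos[which.max(Z[2, ])], 11, tolerance = 1)
  # window equal to path length: a single column of plain path means
  Z2 <- sliding_phase_raster(counts, w, window = n_wb, overlap = 0)
  expect_equal(ncol(Z2), 1)
  expect_equal(Z2[, 1], unname(colMeans(counts / 0.125)))
  expect_error(sliding_phase_raster(counts, w, window = 50),
               "exceeds")
})

test_that("wingbeat phase decodes across paths through shared
           phase-locked units", {
  units <- lapply(1:8, function(i) {
    unit_spec("tonic_phase_locked", baseline_rate = 8, kappa = 4,
              preferred_phase = 2 * pi * i / 8)
  })
  cfg <- generator_config(seed = 21, n_paths = 2, flights_per_path = 6,
                          units = units)
  s <- simulate_session(cfg)
  fs <- s$meta$sample_rate_hz
  fl <- segment_flights(s$trajectory, fs)
  fl$path <- as.integer(cluster_paths(s$trajectory, fl))
  det <- detect_wingbeats(s$accel$az, fs, fl, t = s$accel$t)
  tr <- population_phase_bins(s$spikes, det, fl[fl$path == 1, ],
                              units = 1:8)
  te <- population_phase_bins(s$spikes, det, fl[fl$path == 2, ],
                              units = 1:8)
  set.seed(10)
  dec <- cross_path_phase_decoder(tr, te)
  expect_gte(dec$normed_r2, 0.8)
  # train = test via CV folds: normed score 1 by construction
  dec_self <- cross_path_phase_decoder(tr, tr)
  expect_equal(dec_self$r2_test / dec_self$r2_cv_train,
               dec_self$normed_r2)
  # unit-shuffled test population: no cross-path generalization
  set.seed(11)
  te_sh <- te
  te_sh$R <- te$R[, sample(ncol(te$R))]
  dec_sh <- cross_path_phase_decoder(tr, te_sh)
  expect_lt(dec_sh$normed_r2, 0.3)
})
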