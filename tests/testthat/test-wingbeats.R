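# Wingbeat detection, period statistics, envelopes, asymmetries,
# adaptation vectors and wingbeat grouping.

test_that("a pure 8 Hz oscillation yields 125 ms cycles", {
  fs <- 120
  t <- seq(0, 12, by = 1 / fs)
  az <- 1 + 0.8 * sin(2 * pi * 8 * t)
  fl <- data.frame(flight_id = 1, start = 1, end = 11)
  det <- detect_wingbeats(az, fs, fl, t = t)
  n <- nrow(det$wingbeats)
  expect_true(n >= 79 && n <= 80)
  expect_equal(det$wingbeats$period_ms, rep(125, n), tolerance = 0.01)
  # phase is monotone within flight and cycle count matches the
  # unwrapped phase range
  pf <- det$phase_fun[["1"]]
  in_fl <- pf$t >= 1 & pf$t <= 11
  expect_true(all(diff(pf$phu[in_fl]) > 0))
  expect_lt(abs(diff(range(pf$phu[in_fl])) / (2 * pi) - n), 1.5)
})

test_that("white noise produces no accepted cycles", {
  set.seed(11)
  fs <- 120
  t <- seq(0, 12, by = 1 / fs)
  az <- 1 + rnorm(length(t), 0, 0.05)
  fl <- data.frame(flight_id = 1, start = 1, end = 11)
  det <- detect_wingbeats(az, fs, fl, t = t)
  expect_equal(nrow(det$wingbeats), 0)
})

test_that("planted jittered periods are recovered to 2 ms", {
  s <- std_session()
  a <- std_analysis()
  gt <- s$ground_truth$wingbeats
  wbt <- a$wbt
  d <- vapply(seq_len(nrow(gt)), function(i) {
    j <- which.min(abs(wbt$onset - gt$onset[i]))
    c(abs(wbt$onset[j] - gt$onset[i]),
      abs(wbt$period_ms[j] - gt$period_ms[i]))
  }, numeric(2))
  match_rate <- mean(d[1, ] < 0.03)
  expect_gte(match_rate, 0.99)
  expect_lte(median(d[2, ]), 2)
})

test_that("short flights warn and produce no cycles", {
  fs <- 120
  t <- seq(0, 3, by = 1 / fs)
  az <- 1 + 0.8 * sin(2 * pi * 8 * t)
  fl <- data.frame(flight_id = 1, start = 1, end = 1.1)
  expect_warning(det <- detect_wingbeats(az, fs, fl, t = t),
                 "shorter than 2 cycles")
  expect_equal(nrow(det$wingbeats), 0)
})

test_that("period statistics agree with a brute-force sort", {
  w <- data.frame(period_ms = c(120, 125, 130))
  ps <- period_statistics(w)
  expect_equal(ps$median_ms, 125)
  w2 <- data.frame(period_ms = rep(125, 40))
  ps2 <- period_statistics(w2)
  expect_equal(ps2$median_ms, 125)
  expect_equal(ps2$iqr_ms, 0)
  set.seed(2)
  p <- rnorm(501, 125, 3)
  ps3 <- period_statistics(data.frame(period_ms = p))
  sp <- sort(p)
  expect_equal(ps3$median_ms, sp[251])
  expect_equal(ps3$n, 501)
})

test_that("envelope extraction recovers amplitude structure", {
  fs <- 120
  t <- seq(0, 10, by = 1 / fs)
  A <- 0.1
  disp <- A * sin(2 * pi * 8 * t)
  on <- seq(0, 9.8, by = 0.125)
  w <- data.frame(wingbeat_id = seq_along(on), onset = on,
                  offset = on + 0.125)
  env <- extract_envelopes(disp, t, w)
  expect_equal(env$upper, rep(A, nrow(w)), tolerance = 0.01)
  expect_equal(env$lower, rep(-A, nrow(w)), tolerance = 0.01)
  # amplitude step x2 midway doubles the envelope after the step
  disp2 <- disp * ifelse(t < 5, 1, 2)
  env2 <- extract_envelopes(disp2, t, w)
  expect_equal(env2$upper[env2$t_mid > 5.2],
               rep(2 * A, sum(env2$t_mid > 5.2)), tolerance = 0.01)
  # scaling commutes: scale input by c, envelopes scale by c
  env3 <- extract_envelopes(3 * disp, t, w)
  expect_equal(env3$upper, 3 * env$upper, tolerance = 1e-9)
  # fully-masked cycle yields NA
  disp4 <- disp; disp4[t >= 0 & t < 0.125] <- NA
  env4 <- extract_envelopes(disp4, t, w)
  expect_true(is.na(env4$upper[1]) && !is.na(env4$upper[2]))
})

test_that("extracted envelopes track the planted turn modulation", {
  s <- std_session()
  a <- std_analysis()
  env <- a$env$wrist_l
  idx <- findInterval(env$t_mid, s$trajectory$t)
  planted <- s$ground_truth$env_l[idx]
  ok <- !is.na(planted)
  expect_gt(cor(env$upper[ok], planted[ok]), 0.95)
})

test_that("left-right asymmetry is antisymmetric and sign-stable in a
           turn", {
  a <- std_analysis()
  asym <- left_right_asymmetry(a$env$wrist_l, a$env$wrist_r)
  flipped <- left_right_asymmetry(a$env$wrist_r, a$env$wrist_l)
  expect_equal(asym$upper, -flipped$upper)
  # identical envelopes: zero asymmetry
  zero <- left_right_asymmetry(a$env$wrist_l, a$env$wrist_l)
  expect_true(all(zero$upper == 0, na.rm = TRUE))
  # path 1 is the ccw ellipse (left turn): right envelope above left;
  # path 2 is the same loop flown cw, so the sign flips
  p1 <- std_path_wingbeats(1); p2 <- std_path_wingbeats(2)
  expect_gt(mean(asym$upper[p1$sel], na.rm = TRUE), 0)
  expect_lt(mean(asym$upper[p2$sel], na.rm = TRUE), 0)
})

test_that("adaptation similarity curve matches hand-computed cosines", {
  v <- rbind(c(1, 1, 0), c(1, 0, 0))
  curve <- adaptation_similarity_curve(v, c(1, 1), max_lag = 1)
  expect_equal(curve$mean[1], 1)
  expect_equal(curve$mean[2], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(curve$mean[2], oracle_cosine(v[1, ], v[2, ]))
  # identical vectors: curve identically 1
  vi <- rbind(c(1, 2), c(1, 2), c(1, 2))
  ci <- adaptation_similarity_curve(vi, rep(1, 3), max_lag = 2)
  expect_equal(ci$mean, rep(1, 3))
  # orthogonal consecutive vectors: similarity 0 at lag 1
  vo <- rbind(c(1, 0), c(0, 1))
  co <- adaptation_similarity_curve(vo, c(1, 1), max_lag = 1)
  expect_equal(co$mean[2], 0)
})

test_that("wingbeat grouping reproduces ordinal structure", {
  # noiseless generator: groups equal the i-th cycle of every flight
  cfg <- generator_config(seed = 31, n_paths = 1, flights_per_path = 4,
                          path_jitter_sd = 0, envelope_cycle_sd = 0,
                          period_jitter_ms = 0, keypoint_noise_sd = 0)
  s <- simulate_session(cfg)
  fs <- s$meta$sample_rate_hz
  fl <- segment_flights(s$trajectory, fs)
  det <- detect_wingbeats(s$accel$az, fs, fl, t = s$accel$t)
  kin <- derive_kinematics(s$trajectory, fs)
  body <- body_frame_transform(s$keypoints)
  env <- list()
  for (nm in c("wrist_l", "wrist_r", "wingtip_l", "wingtip_r"))
    env[[nm]] <- extract_envelopes(body[, nm, 3], s$accel$t,
                                   det$wingbeats)
  set.seed(1)
  g <- group_wingbeats(det$wingbeats, adaptation_vectors(env),
                       cycle_kinematic_means(kin, det$wingbeats))
  expect_equal(as.integer(g), det$wingbeats$ordinal)
  expect_equal(attr(g, "order_score"), 1, tolerance = 1e-9)
})

test_that("grouping holds under default noise and degrades under
           shuffling", {
  a <- std_analysis()
  p1 <- std_path_wingbeats(1)
  set.seed(2)
  g <- group_wingbeats(p1$wbt, a$adapt[p1$sel, ],
                       a$kin_cyc[p1$sel, ])
  expect_gte(adjusted_rand(as.integer(g), p1$wbt$ordinal), 0.9)
  expect_gte(attr(g, "order_score"), 0.99)
  # shuffling the feature rows destroys order preservation
  set.seed(3)
  perm <- sample(nrow(p1$wbt))
  g_sh <- group_wingbeats(p1$wbt, a$adapt[p1$sel, ][perm, ],
                          a$kin_cyc[p1$sel, ][perm, ],
                          ordinal_weight = 0)
  # labels are always relabeled by mean ordinal, which biases the
  # Spearman score upward even for random clusters; shuffled features
  # must still fall far below the intact score
  expect_lt(abs(attr(g_sh, "order_score")), 0.5)
  expect_lt(abs(attr(g_sh, "order_score")),
            attr(g, "order_score") - 0.4)
  # single flight: groups are the ordinal indices
  one <- p1$wbt[p1$wbt$flight_id == p1$wbt$flight_id[1], ]
  g1 <- group_wingbeats(one)
  expect_equal(as.integer(g1), one$ordinal)
  # k larger than the wingbeat count is rejected
  expect_error(group_wingbeats(one, k = nrow(one) + 5), "exceeds")
})
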