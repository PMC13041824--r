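# Synthetic session generator: determinism, planted structure, unit
# classes, I/O round trips.

test_that("generator is deterministic and lays out balanced flights", {
  cfg <- generator_config(seed = 3, n_paths = 2, flights_per_path = 3)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$accel, s2$accel)
  fl <- s1$ground_truth$flights
  expect_equal(nrow(fl), 6)
  expect_equal(as.integer(table(fl$path)), c(3L, 3L))
  # different seed gives a different session
  s3 <- simulate_session(generator_config(seed = 4, n_paths = 2,
                                          flights_per_path = 3))
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("zero perturbation makes within-path flights identical", {
  cfg <- generator_config(seed = 5, n_paths = 1, flights_per_path = 3,
                          path_jitter_sd = 0, envelope_cycle_sd = 0,
                          keypoint_noise_sd = 0)
  s <- simulate_session(cfg)
  fl <- s$ground_truth$flights
  n <- round((fl$end[1] - fl$start[1]) * 120)
  tr <- lapply(seq_len(3), function(i) {
    idx <- which(s$trajectory$t >= fl$start[i] &
                   s$trajectory$t <= fl$end[i])[seq_len(n)]
    cbind(s$trajectory$x[idx], s$trajectory$y[idx], s$trajectory$z[idx])
  })
  expect_equal(tr[[1]], tr[[2]], tolerance = 1e-12)
  expect_gt(cor(as.numeric(tr[[1]]), as.numeric(tr[[3]])), 1 - 1e-12)
})

test_that("planted wingbeat phase and periods obey the configuration", {
  s <- std_session()
  gt <- s$ground_truth
  # theta in [0, 2pi), defined exactly within flights
  th <- gt$theta
  expect_true(all(th[!is.na(th)] >= 0 & th[!is.na(th)] < 2 * pi))
  # jitter truncated at 3 sd around the 125 ms nominal period
  expect_true(all(abs(gt$wingbeats$period_ms - 125) <= 9 + 1e-9))
  # zero jitter means exactly 125 ms cycles
  s0 <- simulate_session(generator_config(seed = 8, n_paths = 1,
                                          flights_per_path = 2,
                                          period_jitter_ms = 0))
  expect_equal(s0$ground_truth$wingbeats$period_ms,
               rep(125, nrow(s0$ground_truth$wingbeats)),
               tolerance = 1e-9)
  # zero turn gain and cycle noise: all envelope gains equal 1 in flight
  sflat <- simulate_session(generator_config(seed = 8, n_paths = 1,
                                             flights_per_path = 2,
                                             envelope_turn_gain = 0,
                                             envelope_cycle_sd = 0))
  in_fl <- !is.na(sflat$ground_truth$theta)
  expect_equal(sflat$ground_truth$env_l[in_fl],
               rep(1, sum(in_fl)), tolerance = 1e-9)
})

test_that("planted asymmetry has fixed sign through a left turn", {
  # ccw ellipse = left turn; right envelope gain must exceed left
  s <- simulate_session(generator_config(seed = 12, n_paths = 1,
                                         flights_per_path = 2,
                                         envelope_cycle_sd = 0))
  gt <- s$ground_truth
  fl <- gt$flights[1, ]
  mid <- s$trajectory$t > fl$start + 0.5 & s$trajectory$t < fl$end - 0.5
  expect_true(all(gt$env_r[mid] > gt$env_l[mid]))
  # read the asymmetry directly from generated body-frame keypoints:
  # right wrist oscillation envelope exceeds the left one
  amp <- function(kp) max(kp) - min(kp)
  expect_gt(amp(gt$kp_body[mid, "wrist_r", "z"]),
            amp(gt$kp_body[mid, "wrist_l", "z"]))
})

test_that("spike generation honors unit class statistics", {
  # unmodulated unit: empirical rate within 3 s.e. of nominal
  r0 <- 6
  units <- list(unit_spec("unmodulated", baseline_rate = r0),
                unit_spec("tonic_phase_locked", baseline_rate = 8,
                          kappa = 4, preferred_phase = 1),
                unit_spec("group_selective", baseline_rate = 0,
                          active_groups = 1L, jitter_sd_ms = 2))
  s <- simulate_session(generator_config(seed = 17, n_paths = 1,
                                         flights_per_path = 10,
                                         units = units))
  gt <- s$ground_truth
  dur <- max(s$trajectory$t)
  n_sp <- sum(s$spikes$unit_id == 1)
  expect_lt(abs(n_sp - r0 * dur), 3 * sqrt(r0 * dur))
  # tonic unit: RVL of true phases near the von Mises Bessel ratio
  # (nearest-sample phase lookup; floor indexing would bias the
  # preferred phase by half a sample)
  st <- s$spikes$t[s$spikes$unit_id == 2]
  fs <- s$meta$sample_rate_hz
  idx <- pmin(pmax(round(st * fs) + 1L, 1L), length(gt$theta))
  ph <- gt$theta[idx]
  r <- resultant_vector_length(ph[!is.na(ph)])
  expect_lt(abs(r$rvl - von_mises_rvl(4)), 0.05)
  expect_lt(abs(((r$pref_phase - 1 + pi) %% (2 * pi)) - pi), 0.15)
  # group-selective unit active in 1 group: silent fraction ~ 1 - 1/G
  sf <- silent_wingbeat_fraction(s$spikes$t[s$spikes$unit_id == 3],
                                 gt$wingbeats)
  G <- max(gt$wingbeats$group)
  expect_lt(abs(sf - (1 - 0.95 / G)), 0.03)
})

test_that("excessive rates are rejected", {
  units <- list(unit_spec("tonic_phase_locked", baseline_rate = 500,
                          kappa = 6))
  cfg <- generator_config(seed = 2, n_paths = 1, flights_per_path = 1,
                          units = units)
  expect_error(simulate_session(cfg), "rate overflow")
})

test_that("sessions round-trip through the directory format", {
  s <- simulate_session(generator_config(seed = 23, n_paths = 1,
                                         flights_per_path = 2))
  d1 <- file.path(tempdir(), "wb_sess_a")
  d2 <- file.path(tempdir(), "wb_sess_b")
  write_session(s, d1)
  s2 <- read_session(d1)
  write_session(s2, d2)
  for (f in c("trajectory.csv", "keypoints.csv", "accel.csv",
              "spikes.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e7),
                     readBin(file.path(d2, f), "raw", 2e7),
                     label = f)
  }
  # ground truth JSON carries every unit-spec field
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = FALSE)
  need <- c("class", "baseline_rate", "kappa", "preferred_phase",
            "active_groups", "jitter_sd_ms", "spike_phase", "p_active")
  expect_true(all(need %in% names(gt$units[[1]])))
  # spike times outside the recording are a hard error with a row number
  sp <- utils::read.csv(file.path(d1, "spikes.csv"))
  sp$t[3] <- 1e6
  utils::write.csv(sp, file.path(d1, "spikes.csv"), row.names = FALSE)
  expect_error(read_session(d1), "row 3")
  unlink(c(d1, d2), recursive = TRUE)
})
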