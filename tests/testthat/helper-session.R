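# Shared synthetic-session fixture, built once per test run and reused
# across test files. The "standard" session: 2 elliptical paths flown in
# opposite directions, 6 flights each, the default mixed unit population.

.wb_cache <- new.env(parent = emptyenv())

std_session <- function() {
  if (is.null(.wb_cache$session)) {
    cfg <- generator_config(seed = 42, n_paths = 2, flights_per_path = 6)
    .wb_cache$session <- simulate_session(cfg)
  }
  .wb_cache$session
}

# flights + path labels + wingbeat detection for the standard session
std_analysis <- function() {
  if (is.null(.wb_cache$analysis)) {
    s <- std_session()
    fs <- s$meta$sample_rate_hz
    flights <- segment_flights(s$trajectory, fs)
    flights$path <- as.integer(cluster_paths(s$trajectory, flights))
    det <- detect_wingbeats(s$accel$az, fs, flights, t = s$accel$t,
                            traj = s$trajectory)
    kin <- derive_kinematics(s$trajectory, fs)
    body <- body_frame_transform(s$keypoints)
    env <- list()
    for (nm in c("wrist_l", "wrist_r", "wingtip_l", "wingtip_r")) {
      env[[nm]] <- extract_envelopes(body[, nm, 3], s$accel$t,
                                     det$wingbeats)
    }
    .wb_cache$analysis <- list(
      flights = flights, det = det, wbt = det$wingbeats, kin = kin,
      body = body, env = env, adapt = adaptation_vectors(env),
      kin_cyc = cycle_kinematic_means(kin, det$wingbeats))
  }
  .wb_cache$analysis
}

# wingbeat table restricted to one path, with detected ordinals as groups
std_path_wingbeats <- function(path = 1) {
  a <- std_analysis()
  fids <- a$flights$flight_id[a$flights$path == path]
  sel <- which(a$wbt$flight_id %in% fids)
  w <- a$wbt[sel, ]
  w$group <- w$ordinal
  list(wbt = w, sel = sel,
       flights = a$flights[a$flights$path == path, ])
}
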