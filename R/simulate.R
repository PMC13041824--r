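# Synthetic flying-session generator with planted ground truth.
#
# A "session" is a set of synchronized streams (3D body trajectory, 20 pose
# keypoints, a 3-axis accelerometer in g, spike times per unit) emulating a
# bat flying repeated loops from a perch: ~4.5 m/s flight speed, ~8 Hz
# wingbeats with small per-cycle period jitter, stroke envelopes that couple
# to angular velocity with opposite left/right sign in turns, and four unit
# classes (phase-locked tonic, kinematically tuned, sparsely group-selective
# with millisecond jitter, unmodulated) plus optional shared low-rank latent
# drive. Every planted quantity is returned as ground truth so downstream
# stages can be scored against it.

GRAVITY <- 9.81

# ---------------------------------------------------------------------------
# Path templates

#' Built-in flight path templates
#'
#' Each template is a smooth closed loop starting and ending at a common
#' perch at `c(0, 0, z0)`, parameterized on `u` in `[0, 1]`:
#' * `"ellipse_ccw"` / `"ellipse_cw"`: level elliptical loops flown
#'   counterclockwise (left turn) or clockwise (right turn); the two are the
#'   same shape traversed in opposite directions.
#' * `"climb"` / `"descend"`: the counterclockwise ellipse with a smooth
#'   vertical excursion of height `climb_h` starting at fraction `split_u`
#'   of the loop; the pair shares an identical prefix up to `split_u`,
#'   which gives a known kinematic divergence point.
#'
#' @param shape template name.
#' @param a,b ellipse semi-axes (m).
#' @param z0 flight altitude (m).
#' @param climb_h vertical excursion (m) for climb/descend.
#' @param split_u loop fraction at which climb/descend diverge from the
#'   level ellipse.
#' @return a `wb_path_template`: list with `name`, `fun(u)` returning an
#'   `n x 3` matrix of positions, and `split_u` (`NA` for level loops).
#' @export
path_template <- function(shape = c("ellipse_ccw", "ellipse_cw", "climb",
                                    "descend"),
                          a = 2.5, b = 1.5, z0 = 1.5, climb_h = 0.8,
                          split_u = 0.4) {
  shape <- match.arg(shape)
  base_xy <- function(u, sign_y) {
    cbind(a * sin(2 * pi * u), sign_y * b * (1 - cos(2 * pi * u)))
  }
  zfun <- function(u, sign_h) {
    z <- rep(z0, length(u))
    past <- u > split_u
    if (any(past)) {
      s <- (u[past] - split_u) / (1 - split_u)
      z[past] <- z0 + sign_h * climb_h * sin(pi * s)^2
    }
    z
  }
  fun <- switch(shape,
    ellipse_ccw = function(u) cbind(base_xy(u, 1), rep(z0, length(u))),
    ellipse_cw  = function(u) cbind(base_xy(u, -1), rep(z0, length(u))),
    climb       = function(u) cbind(base_xy(u, 1), zfun(u, 1)),
    descend     = function(u) cbind(base_xy(u, 1), zfun(u, -1))
  )
  structure(list(name = shape,
                 fun = fun,
                 split_u = if (shape %in% c("climb", "descend")) split_u
                           else NA_real_),
            class = "wb_path_template")
}

# ---------------------------------------------------------------------------
# Unit specifications

#' Specify one synthetic unit
#'
#' @param class response class: `"tonic_phase_locked"` (rate follows
#'   `exp(kappa * cos(theta - preferred_phase))`, normalized so the mean
#'   flight rate stays at `baseline_rate`, giving an exactly von Mises phase
#'   distribution with population RVL `I1(kappa)/I0(kappa)`);
#'   `"kinematic_glm"` (per-cycle log rate = `log(baseline) +
#'   glm_weights %*% z-scored cycle features`); `"group_selective"` (one
#'   precisely timed spike per cycle at `spike_phase`, only in
#'   `active_groups`, with Gaussian timing jitter `jitter_sd_ms`);
#'   `"unmodulated"` (homogeneous Poisson).
#' @param baseline_rate mean rate in Hz (>= 0).
#' @param kappa von Mises concentration (>= 0; tonic class).
#' @param preferred_phase preferred wingbeat phase in radians (tonic class).
#' @param glm_weights named numeric vector over kinematic feature names
#'   (see [cycle_feature_names()]); kinematic class.
#' @param active_groups integer wingbeat-group ids (ordinal cycle positions)
#'   in which the unit participates; group-selective class.
#' @param jitter_sd_ms spike-time jitter sd in ms (> 0).
#' @param spike_phase wingbeat phase of the group-selective spike.
#' @param p_active per-cycle participation probability of a group-selective
#'   unit in its active groups.
#' @return a `wb_unit_spec` list.
#' @export
unit_spec <- function(class = c("tonic_phase_locked", "kinematic_glm",
                                "group_selective", "unmodulated"),
                      baseline_rate = 5, kappa = 4, preferred_phase = 0,
                      glm_weights = NULL, active_groups = integer(),
                      jitter_sd_ms = 2, spike_phase = pi / 2,
                      p_active = 0.95) {
  class <- match.arg(class)
  stopifnot(baseline_rate >= 0, kappa >= 0, jitter_sd_ms > 0)
  structure(list(class = class, baseline_rate = baseline_rate,
                 kappa = kappa, preferred_phase = preferred_phase,
                 glm_weights = glm_weights,
                 active_groups = as.integer(active_groups),
                 jitter_sd_ms = jitter_sd_ms, spike_phase = spike_phase,
                 p_active = p_active),
            class = "wb_unit_spec")
}

#' Names of the per-cycle kinematic feature registry
#'
#' The 17 default features summarizing each wingbeat cycle: position-derived
#' kinematics (speed, g-force, angular velocity, flight-path angle, velocity
#' and acceleration components, turn curvature), stroke upper envelopes of
#' the left/right wrist and wingtip, the wrist envelope asymmetry, and the
#' cycle period.
#'
#' @return character vector of length 17.
#' @export
cycle_feature_names <- function() {
  c("speed", "g_force", "ang_vel", "fpa", "vx", "vy", "vz",
    "ax", "ay", "az", "curvature",
    "env_wrist_l", "env_wrist_r", "env_wingtip_l", "env_wingtip_r",
    "asym_wrist", "period")
}

# Default mixed population; uses the current RNG stream.
default_unit_population <- function(n_tonic = 6, n_kin = 6, n_group = 8,
                                    n_unmod = 4, n_cycle_groups = 20) {
  units <- list()
  feats <- cycle_feature_names()
  for (i in seq_len(n_tonic)) {
    units <- c(units, list(unit_spec("tonic_phase_locked",
      baseline_rate = stats::runif(1, 4, 10),
      kappa = stats::runif(1, 2, 6),
      preferred_phase = stats::runif(1, 0, 2 * pi))))
  }
  for (i in seq_len(n_kin)) {
    w <- stats::setNames(numeric(length(feats)), feats)
    pick <- sample(length(feats), 3)
    w[pick] <- stats::runif(3, 0.4, 0.8) * sample(c(-1, 1), 3, replace = TRUE)
    units <- c(units, list(unit_spec("kinematic_glm",
      baseline_rate = stats::runif(1, 3, 8), glm_weights = w)))
  }
  for (i in seq_len(n_group)) {
    start <- sample(n_cycle_groups, 1)
    len <- sample(1:3, 1)
    units <- c(units, list(unit_spec("group_selective",
      baseline_rate = 0,
      active_groups = intersect(start:(start + len - 1), 1:n_cycle_groups),
      jitter_sd_ms = stats::runif(1, 1, 4),
      spike_phase = stats::runif(1, 0, 2 * pi))))
  }
  for (i in seq_len(n_unmod)) {
    units <- c(units, list(unit_spec("unmodulated",
      baseline_rate = stats::runif(1, 2, 6))))
  }
  units
}

# ---------------------------------------------------------------------------
# Generator configuration

#' Configuration for the synthetic session generator
#'
#' Defaults encode the nominal flight regime the pipeline targets: 120 Hz
#' sampling, ~8 Hz wingbeats (~125 ms cycles) with 3 ms period jitter,
#' 4.5 m/s flight speed, 2 s perch rests separating flights, and stroke
#' envelopes coupled to yaw rate with opposite sign on the two wings.
#'
#' @param seed integer; fully determines the generated session.
#' @param n_paths number of distinct path templates flown.
#' @param flights_per_path flights per template (interleaved over time).
#' @param sample_rate_hz stream sampling rate (must be >= 2x wingbeat rate).
#' @param wingbeat_hz nominal wingbeat frequency.
#' @param period_jitter_ms sd of i.i.d. Gaussian per-cycle period jitter,
#'   truncated at +/- 3 sd.
#' @param flight_speed cruise speed in m/s.
#' @param path_templates list of [path_template()] objects (length
#'   `n_paths`); default: ccw ellipse, cw ellipse, climb, descend.
#' @param path_jitter_sd sd (m) of the smooth per-flight trajectory
#'   perturbation; 0 makes all flights of a path identical.
#' @param rest_s perch rest duration between flights (s).
#' @param envelope_turn_gain coupling of stroke envelope to normalized yaw
#'   rate; the right wing gets `1 + gain * yaw`, the left `1 - gain * yaw`.
#' @param envelope_cycle_sd sd of the multiplicative per-cycle envelope
#'   variability (smoothly evolving cycle-to-cycle stroke adjustments,
#'   independent per wing).
#' @param envelope_cycle_rho AR(1) correlation of the per-cycle envelope
#'   variability across successive cycles; sets the planted decay
#'   timescale of adaptation-vector similarity.
#' @param keypoint_noise_sd measurement noise sd (m) added to keypoints.
#' @param accel_amp_g amplitude (g) of the dorsoventral wingbeat
#'   oscillation on the accelerometer.
#' @param accel_noise_sd accelerometer white-noise sd (g).
#' @param units list of [unit_spec()]; `NULL` draws a default mixed
#'   population from the seeded RNG.
#' @param latent_spec list(n_factors, timescale_ms, loading_sd): shared
#'   Gaussian-process latent factors added to the log rate of every
#'   Poisson-class unit.
#' @param ramp_s duration of the smooth speed ramp at takeoff and landing.
#' @return a validated `wb_generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_paths = 2L,
                             flights_per_path = 8L,
                             sample_rate_hz = 120,
                             wingbeat_hz = 8,
                             period_jitter_ms = 3,
                             flight_speed = 4.5,
                             path_templates = NULL,
                             path_jitter_sd = 0.05,
                             rest_s = 2,
                             envelope_turn_gain = 0.6,
                             envelope_cycle_sd = 0.08,
                             envelope_cycle_rho = 0.6,
                             keypoint_noise_sd = 0.001,
                             accel_amp_g = 0.8,
                             accel_noise_sd = 0.05,
                             units = NULL,
                             latent_spec = list(n_factors = 0L,
                                                timescale_ms = 150,
                                                loading_sd = 0),
                             ramp_s = 0.3) {
  stopifnot(n_paths >= 1, flights_per_path >= 1,
            sample_rate_hz >= 2 * wingbeat_hz,
            wingbeat_hz > 0, flight_speed > 0, rest_s >= 0)
  if (is.null(path_templates)) {
    all_shapes <- c("ellipse_ccw", "ellipse_cw", "climb", "descend")
    if (n_paths > length(all_shapes))
      stop("provide explicit path_templates for n_paths > 4")
    path_templates <- lapply(all_shapes[seq_len(n_paths)], path_template)
  }
  stopifnot(length(path_templates) == n_paths)
  structure(list(seed = as.integer(seed), n_paths = as.integer(n_paths),
                 flights_per_path = as.integer(flights_per_path),
                 sample_rate_hz = sample_rate_hz, wingbeat_hz = wingbeat_hz,
                 period_jitter_ms = period_jitter_ms,
                 flight_speed = flight_speed,
                 path_templates = path_templates,
                 path_jitter_sd = path_jitter_sd, rest_s = rest_s,
                 envelope_turn_gain = envelope_turn_gain,
                 envelope_cycle_sd = envelope_cycle_sd,
                 envelope_cycle_rho = envelope_cycle_rho,
                 keypoint_noise_sd = keypoint_noise_sd,
                 accel_amp_g = accel_amp_g, accel_noise_sd = accel_noise_sd,
                 units = units, latent_spec = latent_spec, ramp_s = ramp_s),
            class = "wb_generator_config")
}

# Body-frame keypoint skeleton: 20 keypoints; `amp` is the dorsoventral
# stroke amplitude (m) scaling the planted A(t) * sin(theta) oscillation.
keypoint_skeleton <- function() {
  body <- data.frame(
    name = c("snout", "head", "neck", "sternum", "tail_base", "tail_tip"),
    x = c(0.09, 0.07, 0.04, 0, -0.09, -0.13),
    y = 0, z = 0, amp = 0, side = "C", stringsAsFactors = FALSE)
  body$grp <- "body"
  wing <- function(side) {
    s <- if (side == "L") 1 else -1
    data.frame(
      name = paste0(c("shoulder", "elbow", "wrist", "thumb", "d3_joint",
                      "wingtip", "d5_tip"), "_", tolower(side)),
      x = c(0.01, 0.00, 0.02, 0.04, 0.03, 0.02, -0.03),
      y = s * c(0.05, 0.12, 0.20, 0.22, 0.28, 0.36, 0.30),
      z = 0,
      amp = c(0, 0.03, 0.08, 0.09, 0.10, 0.13, 0.11),
      side = side,
      grp = c("arm", "arm", "arm", "arm", "dist", "dist", "dist"),
      stringsAsFactors = FALSE)
  }
  rbind(body, wing("L"), wing("R"))
}

# Arc-length parameterization with cosine speed ramps at both ends.
# Returns positions sampled at `fs` plus flight duration.
sample_template_flight <- function(tpl, speed, fs, jitter_sd, ramp_s) {
  n_fine <- 4000L
  u <- seq(0, 1, length.out = n_fine + 1L)
  P <- tpl$fun(u)
  if (jitter_sd > 0) {
    for (c in 1:3) {
      a <- stats::rnorm(3, 0, jitter_sd / (1:3))
      P[, c] <- P[, c] + a[1] * sin(pi * u) + a[2] * sin(2 * pi * u) +
        a[3] * sin(3 * pi * u)
    }
  }
  seg <- sqrt(rowSums(diff(P)^2))
  s_cum <- c(0, cumsum(seg))
  L <- s_cum[n_fine + 1L]
  # distance-vs-time profile: cosine ease-in/out of duration ramp_s
  dur <- L / speed + ramp_s            # ramps each cover speed*ramp_s/2
  t <- seq(0, dur, by = 1 / fs)
  s_of_t <- function(tt) {
    r <- ramp_s
    s <- numeric(length(tt))
    a <- tt < r
    # integral of the cosine ease speed profile v(t) = speed*(1-cos(pi t/r))/2
    s[a] <- speed * (tt[a] / 2 - r / (2 * pi) * sin(pi * tt[a] / r))
    mid <- tt >= r & tt <= dur - r
    s[mid] <- speed * r / 2 + speed * (tt[mid] - r)
    e <- tt > dur - r
    te <- dur - tt[e]
    s[e] <- L - speed * (te / 2 - r / (2 * pi) * sin(pi * te / r))
    pmin(pmax(s, 0), L)
  }
  s_t <- s_of_t(t)
  # invert arc length to u, then to positions
  u_t <- stats::approx(s_cum, u, xout = s_t, rule = 2)$y
  pos <- cbind(stats::approx(u, P[, 1], xout = u_t)$y,
               stats::approx(u, P[, 2], xout = u_t)$y,
               stats::approx(u, P[, 3], xout = u_t)$y)
  split_t <- if (is.na(tpl$split_u)) NA_real_ else {
    s_split <- s_cum[which.min(abs(u - tpl$split_u))]
    ramp_dist <- speed * ramp_s / 2
    if (s_split <= ramp_dist) s_split / speed
    else ramp_s + (s_split - ramp_dist) / speed
  }
  list(pos = pos, dur = dur, split_t = split_t, length_m = L)
}

#' Generate flight trajectories for a session
#'
#' Lays out interleaved flights of each path template, separated by perch
#' rests, and returns the sampled body trajectory plus flight intervals and
#' path labels. Called by [simulate_session()]; exported for direct use.
#'
#' @param cfg a [generator_config()].
#' @return list with `t`, `pos` (n x 3), `flights` (data.frame: flight_id,
#'   start, end, path, split_t), `perch` position.
#' @export
generate_trajectories <- function(cfg) {
  fs <- cfg$sample_rate_hz
  min_dur <- 2 / cfg$wingbeat_hz
  order_paths <- rep(seq_len(cfg$n_paths), cfg$flights_per_path)
  perch <- cfg$path_templates[[1]]$fun(0)[1, ]
  segs <- list()
  flights <- list()
  t_cursor <- 0
  rest_n <- max(1L, round(cfg$rest_s * fs))
  add_rest <- function() {
    matrix(rep(perch, each = rest_n), ncol = 3)
  }
  segs[[length(segs) + 1L]] <- add_rest()
  t_cursor <- t_cursor + rest_n / fs
  for (i in seq_along(order_paths)) {
    p <- order_paths[i]
    fl <- sample_template_flight(cfg$path_templates[[p]], cfg$flight_speed,
                                 fs, cfg$path_jitter_sd, cfg$ramp_s)
    if (fl$dur < min_dur)
      stop("path template shorter than 2 wingbeat periods")
    segs[[length(segs) + 1L]] <- fl$pos
    flights[[length(flights) + 1L]] <- data.frame(
      flight_id = i, start = t_cursor,
      end = t_cursor + (nrow(fl$pos) - 1) / fs, path = p,
      split_t = if (is.na(fl$split_t)) NA_real_ else t_cursor + fl$split_t)
    t_cursor <- t_cursor + nrow(fl$pos) / fs
    segs[[length(segs) + 1L]] <- add_rest()
    t_cursor <- t_cursor + rest_n / fs
  }
  pos <- do.call(rbind, segs)
  n <- nrow(pos)
  list(t = (seq_len(n) - 1) / fs, pos = pos,
       flights = do.call(rbind, flights), perch = perch)
}

# True kinematics from the noiseless trajectory (used for envelopes and for
# the planted per-cycle feature matrix).
true_kinematics <- function(t, pos, fs) {
  v <- apply(pos, 2, num_deriv, dt = 1 / fs)
  a <- apply(v, 2, num_deriv, dt = 1 / fs)
  speed <- sqrt(rowSums(v^2))
  yaw_rate <- (v[, 1] * a[, 2] - v[, 2] * a[, 1]) / pmax(speed^2, 1e-6)
  cx <- v[, 2] * a[, 3] - v[, 3] * a[, 2]
  cy <- v[, 3] * a[, 1] - v[, 1] * a[, 3]
  cz <- v[, 1] * a[, 2] - v[, 2] * a[, 1]
  ang_vel <- sqrt(cx^2 + cy^2 + cz^2) / pmax(speed^2, 1e-6)
  fpa <- asin(pmin(pmax(v[, 3] / pmax(speed, 1e-6), -1), 1))
  list(v = v, a = a, speed = speed, yaw_rate = yaw_rate, ang_vel = ang_vel,
       g_force = sqrt(rowSums(a^2)) / GRAVITY, fpa = fpa)
}

#' Generate wingbeat phase, keypoint and accelerometer streams
#'
#' Plants a wingbeat phase advancing at `wingbeat_hz` with truncated
#' Gaussian per-cycle period jitter, stroke envelopes
#' `A_side(t) = 1 + gain * side * yaw_norm(t)` with opposite sign on the two
#' wings, body-frame keypoint oscillations `amp * A_side * sin(theta)`, and
#' a dorsoventral accelerometer `1 + accel_amp_g * sin(theta) + noise` (g).
#'
#' @param cfg a [generator_config()].
#' @param traj output of [generate_trajectories()].
#' @return list with per-sample `theta` (NA at rest), `wingbeats`
#'   data.frame, keypoint array (world frame), body-frame keypoint array,
#'   accelerometer data.frame, envelope gains, and body axes.
#' @export
generate_wingbeat_streams <- function(cfg, traj) {
  fs <- cfg$sample_rate_hz
  n <- length(traj$t)
  theta <- rep(NA_real_, n)
  wb <- list()
  jit <- cfg$period_jitter_ms / 1000
  f0 <- cfg$wingbeat_hz
  for (fi in seq_len(nrow(traj$flights))) {
    fl <- traj$flights[fi, ]
    dur <- fl$end - fl$start
    n_cand <- ceiling(dur * f0 * 1.5) + 3L
    dj <- stats::rnorm(n_cand, 0, jit)
    dj <- pmin(pmax(dj, -3 * jit), 3 * jit)
    periods <- 1 / f0 + dj
    bounds <- fl$start + c(0, cumsum(periods))
    full <- which(bounds[-1] <= fl$end + 1e-9)
    idx <- which(traj$t >= fl$start & traj$t <= fl$end)
    th_unwrap <- stats::approx(bounds, 2 * pi * (seq_along(bounds) - 1),
                               xout = traj$t[idx], rule = 2)$y
    theta[idx] <- th_unwrap %% (2 * pi)
    if (length(full)) {
      wb[[length(wb) + 1L]] <- data.frame(
        flight_id = fl$flight_id,
        onset = bounds[full], offset = bounds[full + 1L],
        period_ms = periods[full] * 1000,
        ordinal = seq_along(full), group = seq_along(full))
    }
  }
  wingbeats <- do.call(rbind, wb)
  wingbeats$wingbeat_id <- seq_len(nrow(wingbeats))
  kin <- true_kinematics(traj$t, traj$pos, fs)
  in_flight <- !is.na(theta)
  yaw_norm <- kin$yaw_rate / max(abs(kin$yaw_rate[in_flight]), 1e-9)
  yaw_norm[!in_flight] <- 0
  # smoothly evolving per-cycle stroke adjustments: AR(1) across cycles,
  # independent for each wing and for the proximal (arm: elbow/wrist/
  # thumb) vs distal (digits: d3/wingtip/d5) keypoint groups, mapped to
  # samples through the cycle id
  rho <- cfg$envelope_cycle_rho
  e_sd <- cfg$envelope_cycle_sd
  mult <- list(arm_L = rep(1, n), arm_R = rep(1, n),
               dist_L = rep(1, n), dist_R = rep(1, n))
  if (e_sd > 0) {
    for (fi in seq_len(nrow(traj$flights))) {
      fl <- traj$flights[fi, ]
      rows <- which(wingbeats$flight_id == fl$flight_id)
      if (!length(rows)) next
      nc <- length(rows)
      ar <- function() {
        e <- numeric(nc)
        e[1] <- stats::rnorm(1, 0, e_sd)
        for (i in seq_len(nc - 1))
          e[i + 1] <- rho * e[i] + stats::rnorm(1, 0,
                                                e_sd * sqrt(1 - rho^2))
        e
      }
      bnds <- c(wingbeats$onset[rows], fl$end)
      idx <- which(traj$t >= bnds[1] & traj$t <= fl$end)
      ci <- pmin(findInterval(traj$t[idx], bnds), nc)
      for (nm in names(mult)) mult[[nm]][idx] <- 1 + ar()[ci]
    }
  }
  turn_r <- 1 + cfg$envelope_turn_gain * yaw_norm
  turn_l <- 1 - cfg$envelope_turn_gain * yaw_norm
  env <- list(arm_L = turn_l * mult$arm_L, arm_R = turn_r * mult$arm_R,
              dist_L = turn_l * mult$dist_L,
              dist_R = turn_r * mult$dist_R)
  env_r <- env$arm_R
  env_l <- env$arm_L
  osc <- ifelse(is.na(theta), 0, sin(ifelse(is.na(theta), 0, theta)))
  # body axes from velocity direction; hold last heading at rest
  fwd <- kin$v
  spd <- kin$speed
  good <- spd > 0.5
  fwd[good, ] <- fwd[good, ] / spd[good]
  last <- c(1, 0, 0)
  for (i in seq_len(n)) {
    if (good[i]) last <- fwd[i, ] else fwd[i, ] <- last
  }
  up0 <- c(0, 0, 1)
  left <- cbind(up0[2] * fwd[, 3] - up0[3] * fwd[, 2],
                up0[3] * fwd[, 1] - up0[1] * fwd[, 3],
                up0[1] * fwd[, 2] - up0[2] * fwd[, 1])
  left <- left / pmax(sqrt(rowSums(left^2)), 1e-9)
  up <- cbind(fwd[, 2] * left[, 3] - fwd[, 3] * left[, 2],
              fwd[, 3] * left[, 1] - fwd[, 1] * left[, 3],
              fwd[, 1] * left[, 2] - fwd[, 2] * left[, 1])
  skel <- keypoint_skeleton()
  K <- nrow(skel)
  kp_body <- array(0, c(n, K, 3),
                   dimnames = list(NULL, skel$name, c("x", "y", "z")))
  for (k in seq_len(K)) {
    kp_body[, k, 1] <- skel$x[k]
    kp_body[, k, 2] <- skel$y[k]
    env_k <- if (skel$side[k] == "C" || skel$amp[k] == 0) 1 else
      env[[paste0(skel$grp[k], "_", skel$side[k])]]
    kp_body[, k, 3] <- skel$z[k] + skel$amp[k] * env_k * osc
  }
  kp_world <- array(0, c(n, K, 3),
                    dimnames = dimnames(kp_body))
  for (k in seq_len(K)) {
    for (c in 1:3) {
      kp_world[, k, c] <- traj$pos[, c] +
        fwd[, c] * kp_body[, k, 1] + left[, c] * kp_body[, k, 2] +
        up[, c] * kp_body[, k, 3]
    }
  }
  if (cfg$keypoint_noise_sd > 0) {
    kp_world <- kp_world +
      array(stats::rnorm(length(kp_world), 0, cfg$keypoint_noise_sd),
            dim(kp_world))
  }
  accel <- data.frame(
    t = traj$t,
    ax = stats::rnorm(n, 0, cfg$accel_noise_sd),
    ay = stats::rnorm(n, 0, cfg$accel_noise_sd),
    az = 1 + cfg$accel_amp_g * osc + stats::rnorm(n, 0, cfg$accel_noise_sd))
  list(theta = theta, wingbeats = wingbeats, kp_world = kp_world,
       kp_body = kp_body, accel = accel, env_l = env_l, env_r = env_r,
       env = env, kin = kin,
       axes = list(fwd = fwd, left = left, up = up), skeleton = skel)
}

# Planted per-cycle feature matrix (z-scored over all cycles), matching
# cycle_feature_names(); computed from the exact generator streams.
planted_cycle_features <- function(traj, streams) {
  wbt <- streams$wingbeats
  kin <- streams$kin
  skel <- streams$skeleton
  amp_wrist <- skel$amp[skel$name == "wrist_l"]
  amp_tip <- skel$amp[skel$name == "wingtip_l"]
  t <- traj$t
  n_wb <- nrow(wbt)
  X <- matrix(NA_real_, n_wb, 17,
              dimnames = list(NULL, cycle_feature_names()))
  curv <- kin$ang_vel / pmax(kin$speed, 1e-6)
  for (i in seq_len(n_wb)) {
    idx <- which(t >= wbt$onset[i] & t < wbt$offset[i])
    el <- mean(streams$env$arm_L[idx])
    er <- mean(streams$env$arm_R[idx])
    dl <- mean(streams$env$dist_L[idx])
    dr <- mean(streams$env$dist_R[idx])
    X[i, ] <- c(mean(kin$speed[idx]), mean(kin$g_force[idx]),
                mean(kin$ang_vel[idx]), mean(kin$fpa[idx]),
                mean(kin$v[idx, 1]), mean(kin$v[idx, 2]),
                mean(kin$v[idx, 3]),
                mean(kin$a[idx, 1]), mean(kin$a[idx, 2]),
                mean(kin$a[idx, 3]), mean(curv[idx]),
                amp_wrist * el, amp_wrist * er,
                amp_tip * dl, amp_tip * dr,
                amp_wrist * (er - el), wbt$period_ms[i])
  }
  zscore_cols(X)
}

# GP latent factors sampled per flight on a 25 ms grid with a squared-
# exponential kernel, linearly interpolated onto `t_fine`; zero at rest.
sample_latent_factors <- function(latent_spec, flights, t_fine) {
  k <- latent_spec$n_factors
  n <- length(t_fine)
  if (is.null(k) || k < 1) return(NULL)
  tau <- latent_spec$timescale_ms / 1000
  F <- matrix(0, n, k)
  for (fi in seq_len(nrow(flights))) {
    fl <- flights[fi, ]
    tg <- seq(fl$start, fl$end, by = 0.025)
    Km <- exp(-outer(tg, tg, "-")^2 / (2 * tau^2)) +
      diag(1e-6, length(tg))
    Lc <- chol(Km)
    idx <- which(t_fine >= fl$start & t_fine <= fl$end)
    for (j in seq_len(k)) {
      f <- as.numeric(t(Lc) %*% stats::rnorm(length(tg)))
      F[idx, j] <- stats::approx(tg, f, xout = t_fine[idx], rule = 2)$y
    }
  }
  F
}

#' Generate spike trains for all configured units
#'
#' Poisson-class units are sampled as an inhomogeneous Poisson process on a
#' 1 ms grid with `lambda(t) = baseline * exp(drive(t) + loadings . f(t))`;
#' group-selective units emit Gaussian-jittered spikes at a fixed phase only
#' in their active wingbeat groups. Rates above 1 kHz abort with an error.
#'
#' @param cfg a [generator_config()].
#' @param traj,streams outputs of the trajectory / stream generators.
#' @return list with `spikes` (data.frame unit_id, t), resolved `units`
#'   (specs incl. latent loadings), `cycle_features`, `latent` factors.
#' @export
generate_spikes <- function(cfg, traj, streams) {
  units <- cfg$units
  if (is.null(units)) {
    n_cyc <- round(stats::median(
      table(streams$wingbeats$flight_id)))
    units <- default_unit_population(n_cycle_groups = n_cyc)
  }
  n_units <- length(units)
  dt <- 0.001
  t_fine <- seq(0, max(traj$t), by = dt)
  wbt <- streams$wingbeats
  # per-fine-sample phase and cycle id (NA off-flight / partial cycles)
  theta_fine <- rep(NA_real_, length(t_fine))
  cyc_fine <- rep(NA_integer_, length(t_fine))
  for (fi in seq_len(nrow(traj$flights))) {
    fl <- traj$flights[fi, ]
    rows <- which(wbt$flight_id == fl$flight_id)
    if (!length(rows)) next
    bnds <- c(wbt$onset[rows], wbt$offset[rows[length(rows)]])
    idx <- which(t_fine >= bnds[1] & t_fine < bnds[length(bnds)])
    pos <- findInterval(t_fine[idx], bnds, rightmost.closed = TRUE)
    frac <- (t_fine[idx] - bnds[pos]) / (bnds[pos + 1] - bnds[pos])
    theta_fine[idx] <- 2 * pi * frac
    cyc_fine[idx] <- rows[pos]
  }
  X <- planted_cycle_features(traj, streams)
  latent <- sample_latent_factors(cfg$latent_spec, traj$flights, t_fine)
  loading_sd <- cfg$latent_spec$loading_sd %||% 0
  spikes <- list()
  for (ui in seq_len(n_units)) {
    u <- units[[ui]]
    if (!is.null(latent) && loading_sd > 0 && u$class != "group_selective") {
      u$latent_loading <- stats::rnorm(ncol(latent), 0, loading_sd)
    } else {
      u$latent_loading <- NULL
    }
    units[[ui]] <- u
    if (u$class == "group_selective") {
      st <- c()
      for (fi in unique(wbt$flight_id)) {
        rows <- which(wbt$flight_id == fi & wbt$group %in% u$active_groups)
        for (r in rows) {
          if (stats::runif(1) > u$p_active) next
          tt <- wbt$onset[r] +
            (u$spike_phase / (2 * pi)) * (wbt$offset[r] - wbt$onset[r]) +
            stats::rnorm(1, 0, u$jitter_sd_ms / 1000)
          tt <- min(max(tt, wbt$onset[r]), wbt$offset[r] - 1e-4)
          st <- c(st, tt)
        }
      }
      if (u$baseline_rate > 0) {
        nb <- stats::rpois(1, u$baseline_rate * max(traj$t))
        st <- c(st, stats::runif(nb, 0, max(traj$t)))
      }
      if (length(st))
        spikes[[length(spikes) + 1L]] <-
          data.frame(unit_id = ui, t = sort(st))
      next
    }
    drive <- numeric(length(t_fine))
    if (u$class == "tonic_phase_locked" && u$kappa > 0) {
      log_i0 <- log(besselI(u$kappa, 0, expon.scaled = TRUE)) + u$kappa
      ok <- !is.na(theta_fine)
      drive[ok] <- u$kappa * cos(theta_fine[ok] - u$preferred_phase) - log_i0
    } else if (u$class == "kinematic_glm") {
      w <- u$glm_weights[cycle_feature_names()]
      w[is.na(w)] <- 0
      # saturate the multiplicative drive at e^3: outlying z-scored
      # features (e.g. curvature at the slow takeoff ramps) must not
      # produce unphysical rates
      dv <- pmin(pmax(as.numeric(X %*% w), -3), 3)
      ok <- !is.na(cyc_fine)
      drive[ok] <- dv[cyc_fine[ok]]
    }
    if (!is.null(u$latent_loading))
      drive <- drive + as.numeric(latent %*% u$latent_loading)
    lam <- u$baseline_rate * exp(drive)
    if (any(lam > 1000))
      stop("rate overflow: unit ", ui, " exceeds 1 kHz")
    cnt <- stats::rpois(length(lam), lam * dt)
    pos <- which(cnt > 0)
    if (length(pos)) {
      st <- rep(t_fine[pos], cnt[pos]) +
        stats::runif(sum(cnt[pos]), 0, dt)
      spikes[[length(spikes) + 1L]] <- data.frame(unit_id = ui,
                                                  t = sort(st))
    }
  }
  spk <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(unit_id = integer(), t = numeric())
  spk <- spk[order(spk$unit_id, spk$t), , drop = FALSE]
  rownames(spk) <- NULL
  list(spikes = spk, units = units, cycle_features = X, latent = latent,
       latent_t = t_fine)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate spike-count trials from a planted latent-factor population
#'
#' Draws per-trial latent factor trajectories from independent
#' squared-exponential GPs and emits Poisson counts whose rate is driven
#' by the shared factors: with `link = "sqrt"` the rate is
#' `pmax(d + C x, floor)^2` (so the square-root counts are linear in the
#' factors, the factor-analysis observation scale); with `link = "log"`
#' the rate is `exp(d + C x)`. Used to score dimensionality estimators
#' against a known factor count.
#'
#' @param n_units,n_bins,n_trials population and trial geometry.
#' @param n_factors planted shared dimensionality.
#' @param tau_bins GP timescales in bins (recycled to `n_factors`).
#' @param loading_sd sd of the Gaussian loadings.
#' @param baseline baseline drive `d` (per unit, on the link scale).
#' @param link `"sqrt"` or `"log"`.
#' @return list of `n_trials` matrices (`n_units x n_bins` counts) with
#'   the planted `C`, `d`, factors per trial in attributes.
#' @export
simulate_factor_trials <- function(n_units = 15, n_bins = 40,
                                   n_trials = 12, n_factors = 3,
                                   tau_bins = c(5, 10, 20),
                                   loading_sd = 0.45, baseline = 1.6,
                                   link = c("sqrt", "log")) {
  link <- match.arg(link)
  tau_bins <- rep_len(tau_bins, n_factors)
  C <- matrix(stats::rnorm(n_units * n_factors, 0, loading_sd), n_units)
  d <- rep_len(baseline, n_units)
  chols <- lapply(tau_bins, function(tb) chol(gp_kernel(n_bins, tb)))
  factors <- list()
  trials <- lapply(seq_len(n_trials), function(m) {
    X <- vapply(seq_len(n_factors), function(i) {
      as.numeric(t(chols[[i]]) %*% stats::rnorm(n_bins))
    }, numeric(n_bins))
    factors[[m]] <<- t(X)
    eta <- sweep(C %*% t(X), 1, d, "+")
    lam <- if (link == "sqrt") pmax(eta, 0.05)^2 else exp(eta)
    matrix(stats::rpois(n_units * n_bins, lam), n_units, n_bins)
  })
  attr(trials, "C") <- C
  attr(trials, "d") <- d
  attr(trials, "factors") <- factors
  trials
}

#' Simulate a complete synthetic session
#'
#' Runs the trajectory, wingbeat-stream and spike generators under a single
#' seeded RNG stream, so the same configuration and seed always reproduce a
#' bit-identical session.
#'
#' @param cfg a [generator_config()].
#' @return a `wb_session` object: synchronized `trajectory`, `keypoints`
#'   (world frame, `n x 20 x 3`), `accel`, `spikes`, `meta`, and a
#'   `ground_truth` list holding all planted parameters (flight intervals
#'   and labels, per-sample phase, wingbeat table with group ids, unit
#'   specifications, planted cycle features, envelope gains, latent
#'   factors).
#' @export
simulate_session <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "wb_generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(cfg$seed)
  traj <- generate_trajectories(cfg)
  streams <- generate_wingbeat_streams(cfg, traj)
  spk <- generate_spikes(cfg, traj, streams)
  gt <- list(flights = traj$flights, theta = streams$theta,
             wingbeats = streams$wingbeats, units = spk$units,
             cycle_features = spk$cycle_features,
             env_l = streams$env_l, env_r = streams$env_r,
             kp_body = streams$kp_body,
             latent = spk$latent,
             perch = traj$perch)
  structure(list(
    trajectory = data.frame(t = traj$t, x = traj$pos[, 1],
                            y = traj$pos[, 2], z = traj$pos[, 3]),
    keypoints = spk_round(streams$kp_world),
    accel = streams$accel,
    spikes = spk$spikes,
    meta = list(sample_rate_hz = cfg$sample_rate_hz,
                wingbeat_hz = cfg$wingbeat_hz,
                n_units = length(spk$units),
                duration_s = max(traj$t),
                keypoint_frame = "world",
                keypoint_names = dimnames(streams$kp_world)[[2]]),
    ground_truth = gt,
    config = cfg), class = "wb_session")
}

# keep keypoint array as-is (hook for future rounding); identity today
spk_round <- function(a) a

#' @export
print.wb_session <- function(x, ...) {
  cat("<wb_session> ", round(x$meta$duration_s, 1), " s @ ",
      x$meta$sample_rate_hz, " Hz, ",
      nrow(x$ground_truth$flights), " flights, ",
      x$meta$n_units, " units, ",
      nrow(x$ground_truth$wingbeats), " wingbeats\n", sep = "")
  invisible(x)
}
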