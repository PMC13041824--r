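# Session directory readers / writers.
#
# Layout: trajectory.csv (t,x,y,z), keypoints.csv (t + <name>_x/_y/_z wide
# columns), accel.csv (t,ax,ay,az in g), spikes.csv (unit_id,t), meta.json,
# and optionally ground_truth.json for synthetic sessions. All tables are
# plain CSV written at full double precision so a write -> read -> write
# cycle is byte-identical.

#' Write a session to a directory
#'
#' @param session a `wb_session` (from [simulate_session()] or
#'   [read_session()]).
#' @param dir output directory; created if missing.
#' @param ground_truth write `ground_truth.json` when the session carries
#'   planted ground truth.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, ground_truth = TRUE) {
  stopifnot(inherits(session, "wb_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fw <- function(df, name) {
    data.table::fwrite(df, file.path(dir, name))
  }
  fw(session$trajectory, "trajectory.csv")
  if (!is.null(session$keypoints)) {
    kp <- session$keypoints
    nm <- dimnames(kp)[[2]]
    wide <- data.frame(t = session$trajectory$t)
    for (k in seq_along(nm)) {
      wide[[paste0(nm[k], "_x")]] <- kp[, k, 1]
      wide[[paste0(nm[k], "_y")]] <- kp[, k, 2]
      wide[[paste0(nm[k], "_z")]] <- kp[, k, 3]
    }
    fw(wide, "keypoints.csv")
  }
  fw(session$accel, "accel.csv")
  fw(session$spikes, "spikes.csv")
  jsonlite::write_json(session$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (ground_truth && !is.null(session$ground_truth)) {
    gt <- session$ground_truth
    gt_json <- list(
      flights = gt$flights,
      wingbeats = gt$wingbeats,
      theta = gt$theta,
      env_l = gt$env_l, env_r = gt$env_r,
      perch = gt$perch,
      cycle_features = gt$cycle_features,
      units = lapply(gt$units, unclass))
    jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Read a session directory
#'
#' Validates monotone time bases and that spike times fall inside the
#' recording; violations abort with the offending file and row. A missing
#' `keypoints.csv` sets `keypoints = NULL` and flags keypoint-based
#' analyses as unavailable in `meta$keypoints_available`.
#'
#' @param dir session directory written by [write_session()].
#' @return a `wb_session` object.
#' @export
read_session <- function(dir) {
  need <- c("trajectory.csv", "accel.csv", "spikes.csv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(dir, f)))
      stop("session directory missing ", f)
  }
  traj <- as.data.frame(data.table::fread(file.path(dir, "trajectory.csv")))
  accel <- as.data.frame(data.table::fread(file.path(dir, "accel.csv")))
  spikes <- as.data.frame(data.table::fread(file.path(dir, "spikes.csv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  check_monotone <- function(tv, file) {
    bad <- which(diff(tv) <= 0)
    if (length(bad))
      stop("non-monotone timestamps in ", file, " at row ", bad[1] + 1L)
  }
  check_monotone(traj$t, "trajectory.csv")
  check_monotone(accel$t, "accel.csv")
  t0 <- traj$t[1]; t1 <- traj$t[nrow(traj)]
  if (nrow(spikes)) {
    bad <- which(spikes$t < t0 | spikes$t > t1 + 1)
    if (length(bad))
      stop("spike time outside recording in spikes.csv at row ", bad[1])
  }
  fs_inferred <- 1 / stats::median(diff(traj$t))
  if (!is.null(meta$sample_rate_hz) &&
      abs(fs_inferred - meta$sample_rate_hz) > 0.05 * meta$sample_rate_hz)
    stop("trajectory sampling rate ", round(fs_inferred, 2),
         " Hz disagrees with meta.json (", meta$sample_rate_hz, " Hz)")
  kp <- NULL
  kp_file <- file.path(dir, "keypoints.csv")
  meta$keypoints_available <- file.exists(kp_file)
  if (meta$keypoints_available) {
    wide <- as.data.frame(data.table::fread(kp_file))
    nm <- unique(sub("_[xyz]$", "", setdiff(names(wide), "t")))
    kp <- array(NA_real_, c(nrow(wide), length(nm), 3),
                dimnames = list(NULL, nm, c("x", "y", "z")))
    for (k in seq_along(nm)) {
      kp[, k, 1] <- wide[[paste0(nm[k], "_x")]]
      kp[, k, 2] <- wide[[paste0(nm[k], "_y")]]
      kp[, k, 3] <- wide[[paste0(nm[k], "_z")]]
    }
  }
  gt <- NULL
  gt_file <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_file)) {
    gt <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    gt$cycle_features <- as.matrix(gt$cycle_features)
    colnames(gt$cycle_features) <- cycle_feature_names()
    raw <- jsonlite::read_json(gt_file, simplifyVector = FALSE)
    gt$units <- lapply(raw$units, function(u) {
      lapply(u, function(x) if (is.list(x)) unlist(x) else x)
    })
  }
  structure(list(trajectory = traj, keypoints = kp, accel = accel,
                 spikes = spikes, meta = meta, ground_truth = gt,
                 config = NULL),
            class = "wb_session")
}
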