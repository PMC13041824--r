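# End-to-end pipeline: session -> flights -> wingbeats -> unit statistics
# -> decoding -> encoding models -> population dimensionality, with every
# stage's outputs serialized to plain CSV / JSON reports.

#' Pipeline configuration
#'
#' All analysis thresholds in one validated object. Unknown arguments are
#' rejected (they would be silent typos); the configuration is echoed into
#' the output manifest for provenance.
#'
#' @param seed root seed; the generator and every stochastic stage derive
#'   from it, so a fixed seed reproduces byte-identical reports.
#' @param generator a [generator_config()] used when no `session_dir` is
#'   given.
#' @param session_dir optional existing session directory to analyze
#'   instead of simulating.
#' @param stages character vector of stages to run, in dependency order;
#'   stages whose prerequisites were skipped are skipped too.
#' @param n_shuffles permutation count for modulation / phase tests.
#' @param decode_null_iters label-shuffle iterations for the decoder null.
#' @param q_modulation,q_phase BH-FDR levels.
#' @param speed_threshold,min_duration flight segmentation parameters.
#' @param cluster_cutoff path clustering RMS cutoff (m).
#' @param gpfa_dims candidate GPFA dimensionalities.
#' @param gpfa_bin_s GPFA count bin width (s).
#' @return a `wb_pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = generator_config(seed = seed),
                            session_dir = NULL,
                            stages = c("kinematics", "wingbeats",
                                       "unitstats", "decode", "glm",
                                       "popdim"),
                            n_shuffles = 200,
                            decode_null_iters = 20,
                            q_modulation = 0.01,
                            q_phase = 0.05,
                            speed_threshold = 1,
                            min_duration = 1,
                            cluster_cutoff = 0.3,
                            gpfa_dims = 1:3,
                            gpfa_bin_s = 0.02) {
  known <- c("kinematics", "wingbeats", "unitstats", "decode", "glm",
             "popdim")
  if (!all(stages %in% known))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(seed = as.integer(seed), generator = generator,
                 session_dir = session_dir, stages = stages,
                 n_shuffles = n_shuffles,
                 decode_null_iters = decode_null_iters,
                 q_modulation = q_modulation, q_phase = q_phase,
                 speed_threshold = speed_threshold,
                 min_duration = min_duration,
                 cluster_cutoff = cluster_cutoff,
                 gpfa_dims = gpfa_dims, gpfa_bin_s = gpfa_bin_s),
            class = "wb_pipeline_config")
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

# serializable echo of the configuration (drop closures)
config_echo <- function(cfg) {
  gen <- cfg$generator
  gen$path_templates <- vapply(gen$path_templates, function(tp) tp$name,
                               character(1))
  gen$units <- if (is.null(gen$units)) "default" else
    paste0("explicit(", length(gen$units), ")")
  cfg$generator <- lapply(unclass(gen), unclass)
  lapply(unclass(cfg), function(x) if (is.list(x)) x else unclass(x))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a session, then runs flight segmentation and path
#' clustering, wingbeat detection and grouping, unit statistics, barcode
#' decoding, per-unit encoding models, and population dimensionality, in
#' dependency order. Every stage writes its outputs under `out_dir`;
#' failures are caught and recorded in `manifest.json` so a partial bundle
#' with a failure manifest is still produced. Given the same configuration
#' and seed, all numeric reports are byte-identical across runs.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) the manifest list, with per-stage status.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "wb_pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)
  manifest <- list(config = config_echo(cfg), stages = list())
  note <- function(stage, status, detail = NULL) {
    manifest$stages[[stage]] <<- list(status = status, detail = detail)
  }
  run_stage <- function(stage, deps, fun) {
    if (!(stage %in% cfg$stages)) {
      note(stage, "skipped", "disabled in config")
      return(NULL)
    }
    missing_dep <- deps[!vapply(deps, function(d) {
      !is.null(manifest$stages[[d]]) &&
        manifest$stages[[d]]$status == "ok"
    }, logical(1))]
    if (length(missing_dep)) {
      note(stage, "skipped",
           paste("dependency not satisfied:",
                 paste(missing_dep, collapse = ", ")))
      return(NULL)
    }
    tryCatch({
      out <- fun()
      note(stage, "ok")
      out
    }, error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
  }

  # --- session ------------------------------------------------------------
  session <- if (is.null(cfg$session_dir)) {
    s <- simulate_session(cfg$generator)
    write_session(s, file.path(out_dir, "session"))
    s
  } else read_session(cfg$session_dir)
  note("session", "ok")
  fs <- session$meta$sample_rate_hz
  spikes <- session$spikes
  units <- sort(unique(spikes$unit_id))

  # --- kinematics ---------------------------------------------------------
  kinres <- run_stage("kinematics", "session", function() {
    flights <- segment_flights(session$trajectory, fs,
                               cfg$speed_threshold, cfg$min_duration)
    if (!nrow(flights)) stop("no flights detected")
    lab <- cluster_paths(session$trajectory, flights, cfg$cluster_cutoff)
    flights$path <- as.integer(lab)
    data.table::fwrite(flights, file.path(out_dir, "flights.csv"))
    kin <- derive_kinematics(session$trajectory, fs)
    repro <- list()
    for (pa in setdiff(unique(flights$path), 0L)) {
      fl <- flights[flights$path == pa, ]
      if (nrow(fl) < 2) next
      feats <- lapply(seq_len(nrow(fl)), function(i) {
        sel <- kin$t >= fl$start[i] & kin$t <= fl$end[i]
        cbind(x = session$trajectory$x[sel],
              y = session$trajectory$y[sel],
              z = session$trajectory$z[sel],
              as.matrix(kin[sel, c("speed", "g_force", "ang_vel", "fpa",
                                   "vx", "vy", "vz", "ax", "ay", "az")]))
      })
      r <- path_reproducibility(feats)
      repro[[paste0("path_", pa)]] <- list(median = r$median,
                                           iqr = r$iqr,
                                           n = length(r$correlations))
    }
    write_report(repro, file.path(out_dir, "reproducibility.json"))
    list(flights = flights, kin = kin)
  })

  # --- wingbeats ----------------------------------------------------------
  wbres <- run_stage("wingbeats", "kinematics", function() {
    flights <- kinres$flights
    det <- detect_wingbeats(session$accel$az, fs, flights,
                            t = session$accel$t, traj = session$trajectory)
    wbt <- det$wingbeats
    if (!nrow(wbt)) stop("no wingbeats detected")
    kp_avail <- !is.null(session$keypoints)
    env <- NULL; adapt <- NULL
    wbt$group <- NA_integer_
    if (kp_avail) {
      body <- body_frame_transform(session$keypoints)
      env <- list()
      for (nm in c("wrist_l", "wrist_r", "wingtip_l", "wingtip_r")) {
        env[[nm]] <- extract_envelopes(body[, nm, 3], session$accel$t,
                                       wbt)
      }
      adapt <- adaptation_vectors(env)
    }
    kin_cyc <- cycle_kinematic_means(kinres$kin, wbt)
    path_of_flight <- stats::setNames(flights$path, flights$flight_id)
    for (pa in setdiff(unique(flights$path), 0L)) {
      sel <- which(path_of_flight[as.character(wbt$flight_id)] == pa)
      if (length(sel) < 4) next
      g <- group_wingbeats(wbt[sel, ],
                           if (!is.null(adapt))
                             adapt[sel, , drop = FALSE],
                           kin_cyc[sel, , drop = FALSE])
      wbt$group[sel] <- as.integer(g)
    }
    data.table::fwrite(wbt, file.path(out_dir, "wingbeats.csv"))
    ps <- period_statistics(wbt)
    write_report(ps, file.path(out_dir, "period_stats.json"))
    list(det = det, wbt = wbt, env = env, adapt = adapt,
         kin_cyc = kin_cyc)
  })

  # --- unit statistics ----------------------------------------------------
  usres <- run_stage("unitstats", c("kinematics", "wingbeats"), function() {
    flights <- kinres$flights
    main_path <- names(which.max(table(flights$path[flights$path != 0])))
    fl1 <- flights[flights$path == as.integer(main_path), ]
    mod <- modulation_test_population(spikes, fl1, units,
                                      q = cfg$q_modulation,
                                      n_shuffles = cfg$n_shuffles)
    sil <- vapply(units, function(u) {
      silent_wingbeat_fraction(spikes$t[spikes$unit_id == u], wbres$wbt)
    }, numeric(1))
    dur <- sum(flights$end - flights$start)
    rate <- vapply(units, function(u) {
      st <- spikes$t[spikes$unit_id == u]
      sum(vapply(seq_len(nrow(flights)), function(i) {
        sum(st >= flights$start[i] & st <= flights$end[i])
      }, numeric(1))) / dur
    }, numeric(1))
    stats_df <- data.frame(unit_id = units, flight_rate_hz = rate,
                           silent_fraction = sil,
                           mod_stat = mod$stat, mod_p = mod$p,
                           mod_sig = mod$sig)
    data.table::fwrite(stats_df, file.path(out_dir, "unit_stats.csv"))
    ph <- phase_locking_population(spikes, wbres$det, flights,
                                   q = cfg$q_phase,
                                   n_shuffles = cfg$n_shuffles)
    data.table::fwrite(ph, file.path(out_dir, "phase_pairs.csv"))
    list(stats = stats_df, phase = ph, main_path = as.integer(main_path))
  })

  # --- barcode decoding ---------------------------------------------------
  run_stage("decode", c("wingbeats", "unitstats"), function() {
    flights <- kinres$flights
    pa <- usres$main_path
    fids <- flights$flight_id[flights$path == pa]
    sel <- which(wbres$wbt$flight_id %in% fids &
                   !is.na(wbres$wbt$group))
    wsub <- wbres$wbt[sel, ]
    B <- build_barcodes(spikes, wsub, units)
    dec <- decode_wingbeat_group(B, wsub$group)
    bands <- 0:min(3, nrow(dec$confusion) - 1)
    acc <- vapply(bands, function(b) band_accuracy(dec$confusion, b),
                  numeric(1))
    null <- decoder_shuffle_null(B, wsub$group,
                                 n_iter = cfg$decode_null_iters,
                                 bands = bands)
    sim <- barcode_similarity_curve(B, wsub$flight_id)
    rep <- list(path = pa, n_wingbeats = nrow(B),
                n_groups = nrow(dec$confusion),
                confusion = unname(dec$confusion),
                accuracy = dec$accuracy,
                band = bands, band_accuracy = acc,
                null_mean = unname(colMeans(null)),
                null_sd = unname(apply(null, 2, stats::sd)),
                similarity = sim)
    write_report(rep, file.path(out_dir, "decode_report.json"))
    rep
  })

  # --- encoding models ----------------------------------------------------
  run_stage("glm", c("wingbeats", "unitstats"), function() {
    flights <- kinres$flights
    pa <- usres$main_path
    fids <- flights$flight_id[flights$path == pa]
    sel <- which(wbres$wbt$flight_id %in% fids)
    wsub <- wbres$wbt[sel, ]
    env_sub <- if (!is.null(wbres$env))
      lapply(wbres$env, function(e) e[sel, ]) else NULL
    X <- build_feature_matrix(kinres$kin, env_sub, wsub)
    counts <- vapply(units, function(u) {
      cycle_spike_counts(spikes$t[spikes$unit_id == u], wsub)
    }, integer(nrow(wsub)))
    colnames(counts) <- units
    fits <- fit_unit_glms(counts, X)
    data.table::fwrite(fits, file.path(out_dir, "glm_fits.csv"))
    fits
  })

  # --- population dimensionality ------------------------------------------
  run_stage("popdim", c("wingbeats", "unitstats"), function() {
    flights <- kinres$flights
    pa <- usres$main_path
    fids <- flights$flight_id[flights$path == pa]
    sel <- which(wbres$wbt$flight_id %in% fids &
                   !is.na(wbres$wbt$group))
    wsub <- wbres$wbt[sel, ]
    gm <- build_group_mean_matrix(spikes, wsub, units,
                                  reliability_min = -Inf)
    pca <- pca_dimensionality(gm$M)
    prs <- participation_ratio_split(pca$eigenvalues)
    # trial tensor for dPCA: balanced cycles per group
    tab <- table(wsub$group)
    R_tr <- min(tab)
    groups <- as.integer(names(tab))
    bpc <- gm$bins_per_cycle
    tens <- array(0, c(length(units), bpc, length(groups), R_tr))
    for (gi in seq_along(groups)) {
      rows <- which(wsub$group == groups[gi])[seq_len(R_tr)]
      for (r in seq_along(rows)) {
        w <- wsub[rows[r], ]
        for (j in seq_along(units)) {
          st <- spikes$t[spikes$unit_id == units[j]]
          st <- st[st >= w$onset & st < w$offset]
          if (length(st)) {
            b <- pmin(floor((st - w$onset) / (w$offset - w$onset) *
                              bpc) + 1L, bpc)
            tens[j, , gi, r] <- tabulate(b, bpc)
          }
        }
      }
    }
    dp <- if (length(groups) >= 2 && R_tr >= 2)
      dpca_decompose(tens) else NULL
    # GPFA on per-flight count matrices
    fl1 <- flights[flights$path == pa, ]
    Tmin <- floor(min(fl1$end - fl1$start) / cfg$gpfa_bin_s)
    trials <- lapply(seq_len(nrow(fl1)), function(i) {
      t(vapply(units, function(u) {
        bin_events(spikes$t[spikes$unit_id == u], fl1$start[i],
                   fl1$end[i], cfg$gpfa_bin_s)[seq_len(Tmin)]
      }, numeric(Tmin)))
    })
    gd <- gpfa_dimensionality(trials, cfg$gpfa_dims,
                              bin_s = cfg$gpfa_bin_s)
    rep <- list(path = pa, n_units = pca$n_units,
                eigenvalues = pca$eigenvalues, n90 = pca$n90,
                n90_frac = pca$n90_frac,
                pr_core_norm = prs$pr_core_norm,
                pr_extended_norm = prs$pr_extended_norm,
                dpca = if (!is.null(dp))
                  list(ev_group = dp$ev_group, ev_time = dp$ev_time,
                       ev_unexplained = dp$ev_unexplained,
                       ratio = dp$ratio) else NULL,
                gpfa = list(dims = gd$dims, errors = gd$errors,
                            selected = gd$selected, best = gd$best))
    write_report(rep, file.path(out_dir, "dim_report.json"))
    data.table::fwrite(
      data.frame(component = seq_along(pca$eigenvalues),
                 eigenvalue = pca$eigenvalues, cum_ev = pca$cum_ev),
      file.path(out_dir, "spectra.csv"))
    rep
  })

  write_report(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
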