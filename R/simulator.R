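# Synthetic ground-truth generator: an ellipsoidal head with a quasi-uniform
# electrode layout, rigid head motion, controller pose streams with a known
# endpoint offset, and a phenomenological tracking-noise model.  Every other
# module is testable against this simulator because the generating truth is
# known exactly.
#
# Noise model (per translation component, millimeters):
#   * jitter  -- band-limited (AR(1)) zero-mean noise with stationary
#     standard deviation jitter_sigma and correlation time jitter_tau.
#     Sensor-fused tracking noise is temporally correlated; white noise at
#     the full per-sample amplitude would trip the 1-mm stability gate at
#     jitter levels real systems tolerate.
#   * bias    -- a quasi-static, pose-dependent offset redrawn at each dwell
#     (sd bias_sigma for the controller, tracker_bias_sigma for trackers).
#     This emulates the static distortion of beacon-based optical tracking,
#     the error component that survives the 0.5-s averaging window and
#     dominates the final localization error.
#   * transient -- an exponentially decaying error burst after each transit
#     (post-movement settling), amplitude transient_mm, time constant
#     transient_decay_s, in a random direction.

#' Simulation scenario configuration
#'
#' Defaults describe the reference scenario: a 128-electrode radial cap on
#' an adult-sized ellipsoidal head (semi-axes 80 x 95 x 90 mm, giving a
#' median inter-electrode spacing of about 20 mm, inside the observed
#' 18-25 mm range), a 27-mm stylus stub endpoint, 90 Hz tracking, and a
#' static head; noise terms default to zero so that the base scenario is
#' exactly recoverable.
#'
#' @param n_electrodes electrode count (default 128, labeled A1..D32).
#' @param head_semiaxes ellipsoid semi-axes (x right, y anterior, z up), mm.
#' @param spacing_target admissible median nearest-neighbor spacing, mm.
#' @param z_cut cap coverage: electrodes lie above `z_cut` (fraction of the
#'   unit sphere; -0.2 extends just below the equator).
#' @param endpoint_truth true device-frame endpoint offset, mm.
#' @param jitter_sigma stationary sd of tracking jitter, mm.
#' @param jitter_tau jitter correlation time, s (default 1.0: sensor-fused
#'   tracking drift varies on the timescale of the stability window).
#' @param bias_sigma per-dwell quasi-static controller error sd, mm.
#' @param tracker_bias_sigma per-dwell quasi-static tracker error sd, mm.
#' @param transient_mm,transient_decay_s post-movement transient amplitude
#'   (mm) and decay time constant (s).
#' @param head_drift_mm total head translation over the session, mm
#'   (constant-velocity; 0 = static head).
#' @param head_rot_deg total head rotation about +z over the session, deg.
#' @param n_trackers number of head trackers (0-2).
#' @param dwell_s,transit_s dwell time at each target and transit time
#'   between targets, s; dwell must cover the stability window.
#' @param sample_rate tracking rate, Hz (default 90, typical of consumer VR).
#' @param fiducial_repeats measured repeats per fiducial.
#' @param slip optional tracker-slip event for mismatch testing:
#'   `list(tracker = 2, time_s = ..., offset_mm = c(x,y,z))`.
#' @param seed integer RNG seed; identical seed + config gives bit-identical
#'   streams.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_electrodes = 128L,
                            head_semiaxes = c(80, 95, 90),
                            spacing_target = c(18, 25),
                            z_cut = -0.2,
                            endpoint_truth = c(0, 0, -27),
                            jitter_sigma = 0,
                            jitter_tau = 1.0,
                            bias_sigma = 0,
                            tracker_bias_sigma = 0,
                            transient_mm = 0,
                            transient_decay_s = 0.4,
                            head_drift_mm = 0,
                            head_rot_deg = 0,
                            n_trackers = 2L,
                            dwell_s = 1.8,
                            transit_s = 0.4,
                            sample_rate = 90,
                            fiducial_repeats = 1L,
                            slip = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_electrodes >= 1, all(cfg$head_semiaxes > 0),
            cfg$sample_rate > 0, cfg$dwell_s > 0, cfg$transit_s >= 0,
            cfg$jitter_sigma >= 0, cfg$bias_sigma >= 0,
            cfg$n_trackers %in% 0:2)
  structure(cfg, class = "scenario_config")
}

#' Read a scenario configuration from YAML
#'
#' Recognized keys mirror the arguments of [scenario_config()]; unknown keys
#' are an error.
#' @param path YAML file path.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("unknown scenario key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  do.call(scenario_config, x)
}

# quasi-uniform unit directions from the Fibonacci spiral
fibonacci_sphere <- function(n_total) {
  i <- seq_len(n_total) - 0.5
  phi <- acos(1 - 2 * i / n_total)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a ground-truth head layout
#'
#' Places `n_electrodes` quasi-uniform points on the upper portion of the
#' head ellipsoid via a Fibonacci spiral, labels them in ring order
#' (top-down, by azimuth within rings) to mimic a radial montage, and adds
#' three anatomical fiducials (nasion, left/right preauricular) and the
#' configured head-tracker mounts on the forehead.
#'
#' @param cfg A `scenario_config`.
#' @return Object of class `ground_truth`: `electrodes` (n x 3, rownames =
#'   labels, head frame mm), `fiducials` (named list of length-3), `mounts`
#'   (list of `rigid_transform`, tracker-local -> head frame), `endpoint`
#'   (mm), `cfg`.
#' @export
generate_layout <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  ax <- cfg$head_semiaxes
  n <- cfg$n_electrodes
  # grow the spiral until exactly n directions clear the coverage cut
  ntot <- n
  for (iter in 1:200) {
    u <- fibonacci_sphere(ntot)
    k <- sum(u[, 3] > cfg$z_cut)
    if (k == n) break
    ntot <- ntot + max(1L, as.integer(round((ntot * n / max(k, 1) - ntot) / 2)))
    if (iter == 200)
      stop("generate_layout: could not hit requested electrode count",
           call. = FALSE)
  }
  u <- u[u[, 3] > cfg$z_cut, , drop = FALSE]
  pts <- sweep(u, 2, ax, "*")                     # exactly on the ellipsoid
  # ring-order labeling: top-down bands, azimuth within band
  n_rings <- max(1L, as.integer(round(sqrt(n / 2))))
  ring_of <- ceiling(rank(-pts[, 3], ties.method = "first") / (n / n_rings))
  ord <- order(ring_of, atan2(pts[, 2], pts[, 1]))
  pts <- pts[ord, , drop = FALSE]
  rownames(pts) <- if (n == 128L) biosemi_labels(128L) else
    sprintf("E%03d", seq_len(n))
  if (n >= 32) {
    d <- as.matrix(stats::dist(pts)); diag(d) <- Inf
    med_nn <- stats::median(apply(d, 1, min))
    # the spacing target describes the 128-channel cap density; for other
    # counts the admissible band scales with sqrt(128/n)
    target <- cfg$spacing_target * sqrt(128 / n)
    if (med_nn < target[1] || med_nn > target[2])
      stop(sprintf(
        "generate_layout: infeasible spacing %.1f mm for head size (target %.1f-%.1f mm at n=%d)",
        med_nn, target[1], target[2], n), call. = FALSE)
  }
  on_ell <- function(dir) { dir <- dir / sqrt(sum(dir^2)); dir * ax }
  fiducials <- list(nasion = on_ell(c(0, 0.966, -0.259)),
                    lpa = on_ell(c(-0.966, 0, -0.259)),
                    rpa = on_ell(c(0.966, 0, -0.259)))
  mount_dirs <- list(c(-0.4, 0.82, 0.41), c(0.4, 0.82, 0.41))
  mounts <- lapply(seq_len(cfg$n_trackers), function(j) {
    rigid_transform(rotation_axis_angle(c(1, 0, 0), pi / 6 * j),
                    on_ell(mount_dirs[[j]]))
  })
  names(mounts) <- paste0("tracker", seq_len(cfg$n_trackers))
  structure(list(electrodes = pts, fiducials = fiducials, mounts = mounts,
                 endpoint = cfg$endpoint_truth, cfg = cfg),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d electrodes, %d fiducials, %d tracker mounts\n",
              nrow(x$electrodes), length(x$fiducials), length(x$mounts)))
  invisible(x)
}

#' Build a reference session directly from ground truth
#'
#' Converts a `ground_truth` layout into a `digitization_session` holding
#' the exact electrode and fiducial positions (head frame), for use as the
#' reference in evaluation.
#'
#' @param truth A `ground_truth`.
#' @return A `digitization_session`.
#' @export
truth_session <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  s <- digitization_session(montage(rownames(truth$electrodes)),
                            fiducial_names = names(truth$fiducials),
                            provenance = list(system = "ground-truth"))
  for (nm in names(truth$fiducials))
    s$fiducial_repeats[[nm]] <- matrix(truth$fiducials[[nm]], 1, 3)
  for (lab in rownames(truth$electrodes))
    s$electrodes[[lab]] <- list(position = truth$electrodes[lab, ],
                                frame = "head", valid = TRUE,
                                stability_mm = 0, t = NA_real_)
  s$complete <- TRUE
  s
}

# head trajectory at time t: constant-velocity translation along a fixed
# direction plus linear rotation about +z, reaching the configured totals at
# t_end
head_pose_fun <- function(cfg, t_end, drift_dir) {
  force(drift_dir)
  function(t) {
    fr <- if (t_end > 0) t / t_end else 0
    rigid_transform(rotation_axis_angle(c(0, 0, 1),
                                        fr * cfg$head_rot_deg * pi / 180),
                    fr * cfg$head_drift_mm * drift_dir)
  }
}

# AR(1) noise matrix (n x 3) with stationary sd sigma and correlation rho
ar1_noise <- function(n, sigma, rho) {
  if (sigma == 0 || n == 0) return(matrix(0, n, 3))
  x <- matrix(0, n, 3)
  x[1, ] <- stats::rnorm(3, 0, sigma)
  if (n > 1) {
    innov <- matrix(stats::rnorm((n - 1) * 3, 0, sigma * sqrt(1 - rho^2)),
                    n - 1, 3)
    for (i in 2:n) x[i, ] <- rho * x[i - 1, ] + innov[i - 1, ]
  }
  x
}

# random rotation with angle up to max_angle about a random axis
random_rotation <- function(max_angle) {
  ax <- stats::rnorm(3)
  rotation_axis_angle(ax / sqrt(sum(ax^2)), stats::runif(1, 0.2, 1) * max_angle)
}

#' Simulate a full digitization session
#'
#' Emits a pose stream for the controller and the configured head trackers:
#' for each target (fiducials first, then electrodes in montage order) the
#' controller transits to the target, dwells with its calibrated endpoint on
#' the target point in the moving head frame, and fires a trigger at dwell
#' end.  Translation noise follows the module's jitter/bias/transient model;
#' trackers ride the head trajectory exactly plus their own noise.
#'
#' @param truth A `ground_truth` from [generate_layout()].
#' @param cfg A `scenario_config` (defaults to `truth$cfg`).
#' @return list with `stream` (a `pose_stream` with embedded triggers),
#'   `plan` (data.frame of target label/role per trigger) and `truth`.
#' @export
simulate_session <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  dt <- 1 / cfg$sample_rate
  rho <- exp(-dt / cfg$jitter_tau)
  xc <- cfg$endpoint_truth
  plan <- data.frame(
    label = c(rep(names(truth$fiducials), each = cfg$fiducial_repeats),
              rownames(truth$electrodes)),
    role = c(rep("fiducial", length(truth$fiducials) * cfg$fiducial_repeats),
             rep("electrode", nrow(truth$electrodes))),
    stringsAsFactors = FALSE)
  targets <- rbind(
    do.call(rbind, rep(lapply(names(truth$fiducials),
                              function(nm) truth$fiducials[[nm]]),
                       each = cfg$fiducial_repeats)),
    unname(truth$electrodes))
  n_tgt <- nrow(targets)
  n_dwell <- as.integer(round(cfg$dwell_s / dt))
  n_transit <- as.integer(round(cfg$transit_s / dt))
  n_per <- n_transit + n_dwell
  n_samp <- n_tgt * n_per
  times <- (seq_len(n_samp) - 1) * dt
  t_end <- times[n_samp]
  drift_dir <- { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }
  head_at <- head_pose_fun(cfg, t_end, drift_dir)

  # controller pose in the head frame, sample by sample
  ctrl_R <- array(0, dim = c(3, 3, n_samp))
  ctrl_t <- matrix(0, n_samp, 3)
  trigger_t <- numeric(n_tgt)
  prev_tip <- targets[1, ]
  transient_dir <- matrix(0, n_tgt, 3)
  for (k in seq_len(n_tgt)) {
    Rk <- random_rotation(pi / 3)
    tip <- targets[k, ]
    base_t <- tip - as.numeric(Rk %*% xc)
    idx0 <- (k - 1) * n_per
    if (n_transit > 0) {
      frac <- seq_len(n_transit) / (n_transit + 1)
      start_t <- prev_tip - as.numeric(Rk %*% xc)
      for (j in seq_len(n_transit)) {
        ctrl_R[, , idx0 + j] <- Rk
        ctrl_t[idx0 + j, ] <- (1 - frac[j]) * start_t + frac[j] * base_t
      }
    }
    for (j in seq_len(n_dwell)) {
      ctrl_R[, , idx0 + n_transit + j] <- Rk
      ctrl_t[idx0 + n_transit + j, ] <- base_t
    }
    trigger_t[k] <- times[idx0 + n_per]
    dir <- stats::rnorm(3)
    transient_dir[k, ] <- dir / sqrt(sum(dir^2))
    prev_tip <- tip
  }

  # translation noise in the head frame: AR(1) jitter + per-dwell bias +
  # post-movement transient
  noise <- ar1_noise(n_samp, cfg$jitter_sigma, rho)
  if (cfg$bias_sigma > 0) {
    bias <- matrix(stats::rnorm(n_tgt * 3, 0, cfg$bias_sigma), n_tgt, 3)
    noise <- noise + bias[rep(seq_len(n_tgt), each = n_per), , drop = FALSE]
  }
  if (cfg$transient_mm > 0) {
    arrive <- (seq_len(n_tgt) - 1) * n_per * dt + cfg$transit_s
    k_of <- rep(seq_len(n_tgt), each = n_per)
    dtm <- times - arrive[k_of]
    amp <- ifelse(dtm >= 0, cfg$transient_mm * exp(-dtm / cfg$transient_decay_s), 0)
    noise <- noise + amp * transient_dir[k_of, , drop = FALSE]
  }

  # assemble global-frame streams
  devices <- c("controller", names(truth$mounts))
  all_t <- rep(times, length(devices))
  all_dev <- rep(devices, each = n_samp)
  Tarr <- array(0, dim = c(4, 4, n_samp * length(devices)))
  slip_offset <- function(dev_id, tt) {
    if (is.null(cfg$slip)) return(c(0, 0, 0))
    if (dev_id == paste0("tracker", cfg$slip$tracker) && tt >= cfg$slip$time_s)
      return(as.numeric(cfg$slip$offset_mm))
    c(0, 0, 0)
  }
  head_static <- cfg$head_drift_mm == 0 && cfg$head_rot_deg == 0
  H0 <- head_at(0)
  for (i in seq_len(n_samp)) {
    H <- if (head_static) H0 else head_at(times[i])
    Tarr[1:3, 1:3, i] <- H$R %*% ctrl_R[, , i]
    Tarr[1:3, 4, i] <- H$R %*% (ctrl_t[i, ] + noise[i, ]) + H$t
    Tarr[4, 4, i] <- 1
  }
  tr_noise <- lapply(names(truth$mounts), function(id) {
    nz <- ar1_noise(n_samp, cfg$jitter_sigma, rho)
    if (cfg$tracker_bias_sigma > 0) {
      b <- matrix(stats::rnorm(n_tgt * 3, 0, cfg$tracker_bias_sigma), n_tgt, 3)
      nz <- nz + b[rep(seq_len(n_tgt), each = n_per), , drop = FALSE]
    }
    nz
  })
  names(tr_noise) <- names(truth$mounts)
  for (j in seq_along(truth$mounts)) {
    id <- names(truth$mounts)[j]
    M <- truth$mounts[[j]]
    for (i in seq_len(n_samp)) {
      H <- if (head_static) H0 else head_at(times[i])
      k <- j * n_samp + i
      Tarr[1:3, 1:3, k] <- H$R %*% M$R
      Tarr[1:3, 4, k] <- H$R %*% (M$t + slip_offset(id, times[i])) + H$t +
        tr_noise[[id]][i, ]
      Tarr[4, 4, k] <- 1
    }
  }
  stream <- pose_stream(all_t, all_dev, Tarr,
                        data.frame(t = trigger_t,
                                   device = rep("controller", n_tgt),
                                   stringsAsFactors = FALSE))
  list(stream = stream, plan = plan, truth = truth)
}

#' Simulate a calibration pose set
#'
#' Generates `n_poses` controller poses whose transformed endpoint coincides
#' at one fixed global point, with rotations about random axes spanning the
#' given angular spread; optional translation jitter.  `rotation_spread_deg
#' = 0` deliberately emits a degenerate (all-identical-rotation) set for
#' negative testing.
#'
#' @param endpoint_truth true device-frame offset (mm); a `ground_truth`
#'   may be passed instead.
#' @param n_poses number of poses (>= 3; the reference protocol uses ~10).
#' @param rotation_spread_deg angular spread of the rotations, degrees.
#' @param jitter_sigma translation noise sd, mm (iid here: each pose is an
#'   already-averaged measurement).
#' @param fixed_point global tip location (default (400, 300, 900) mm, an
#'   arbitrary in-room point).
#' @param seed RNG seed.
#' @return A `calibration_set` (flagged degenerate when spread is 0).
#' @export
simulate_calibration <- function(endpoint_truth, n_poses = 10L,
                                 rotation_spread_deg = 90,
                                 jitter_sigma = 0,
                                 fixed_point = c(400, 300, 900),
                                 seed = 1L) {
  if (inherits(endpoint_truth, "ground_truth"))
    endpoint_truth <- endpoint_truth$endpoint
  xc <- as.numeric(endpoint_truth)
  stopifnot(n_poses >= 3L)
  set.seed(seed)
  transforms <- lapply(seq_len(n_poses), function(i) {
    R <- if (rotation_spread_deg == 0) diag(3) else {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1, -0.5, 0.5) * rotation_spread_deg * pi / 180
      rotation_axis_angle(ax, ang)
    }
    tt <- fixed_point - as.numeric(R %*% xc)
    if (jitter_sigma > 0) tt <- tt + stats::rnorm(3, 0, jitter_sigma)
    rigid_transform(R, tt)
  })
  calibration_set(transforms)
}
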