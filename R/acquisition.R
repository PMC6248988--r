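# Acquisition: turn raw pose streams into validated measurements.
# A triggered sample is the mean endpoint position over a trailing averaging
# window (default 0.5 s, suppressing high-frequency jitter) and is accepted
# only if the endpoint stayed within a stability threshold (default 1 mm) of
# the windowed mean over a longer trailing stability window (default 1.0 s,
# rejecting post-movement transients).  With head trackers enabled, all
# windowing is done in head-relative coordinates, the frame in which a point
# on the head is stationary.

DEFAULT_AVG_WINDOW <- 0.5    # seconds
DEFAULT_STAB_WINDOW <- 1.0   # seconds
DEFAULT_STAB_THRESH <- 1.0   # mm
TIME_MATCH_TOL <- 0.050      # s; nearest-sample matching across devices

#' Endpoint trajectory of a device
#'
#' Applies each pose transform of one device to the device origin plus the
#' calibrated endpoint offset, yielding the global stylus-tip trajectory.
#'
#' @param stream A `pose_stream`.
#' @param device device id of the controller.
#' @param endpoint `endpoint_offset` or length-3 vector (mm).
#' @return Object of class `endpoint_series`: fields `t` (seconds) and `pos`
#'   (n x 3 matrix, mm), in stream order.
#' @export
endpoint_timeseries <- function(stream, device, endpoint) {
  sub <- stream_subset(stream, device)
  xc <- as_offset_vec(endpoint)
  n <- length(sub$t)
  pos <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    M <- sub$T[, , i]
    pos[i, ] <- M[1:3, 1:3] %*% xc + M[1:3, 4]
  }
  structure(list(t = sub$t, pos = pos), class = "endpoint_series")
}

#' Sample a measurement from an endpoint time series
#'
#' Both windows trail the trigger (they end at the trigger time): the
#' reported position is the mean over the trailing `avg_window`, and
#' stability is the maximum deviation from the `stab_window` mean over that
#' window.  The sample is valid iff stability does not exceed `stab_thresh`.
#'
#' @param series An `endpoint_series` (global or head-relative coordinates).
#' @param trig_time trigger time (seconds); the series must cover
#'   `[trig_time - stab_window, trig_time]`.
#' @param avg_window averaging window, seconds (default 0.5).
#' @param stab_window stability window, seconds (default 1.0); must be >=
#'   `avg_window`.
#' @param stab_thresh stability threshold, mm (default 1).
#' @param label,role optional label and role (`"fiducial"`, `"electrode"`,
#'   `"headshape"`) recorded on the sample.
#' @param frame frame-of-reference tag recorded on the sample.
#' @return Object of class `measurement_sample`: `label`, `role`, `position`
#'   (mm), `frame`, `valid`, `stability_mm`, `window_n`, `t`.
#' @export
sample_measurement <- function(series, trig_time,
                               avg_window = DEFAULT_AVG_WINDOW,
                               stab_window = DEFAULT_STAB_WINDOW,
                               stab_thresh = DEFAULT_STAB_THRESH,
                               label = NA_character_, role = "electrode",
                               frame = "global") {
  stopifnot(inherits(series, "endpoint_series"))
  if (avg_window > stab_window)
    stop("sample_measurement: avg_window must not exceed stab_window",
         call. = FALSE)
  in_stab <- series$t >= trig_time - stab_window - 1e-12 &
             series$t <= trig_time + 1e-12
  in_avg <- series$t >= trig_time - avg_window - 1e-12 &
            series$t <= trig_time + 1e-12
  if (sum(in_stab) < 3L || sum(in_avg) < 3L)
    stop(sprintf(
      "insufficient data: %d samples in stability window, %d in averaging window (need >= 3)",
      sum(in_stab), sum(in_avg)), call. = FALSE)
  if (min(series$t) > trig_time - stab_window + 1e-9)
    stop("insufficient data: series does not cover the stability window",
         call. = FALSE)
  stab_pos <- series$pos[in_stab, , drop = FALSE]
  stab_mean <- colMeans(stab_pos)
  stability <- max(sqrt(rowSums(sweep(stab_pos, 2, stab_mean)^2)))
  position <- colMeans(series$pos[in_avg, , drop = FALSE])
  structure(list(label = label, role = role, position = position,
                 frame = frame, valid = stability <= stab_thresh,
                 stability_mm = stability, window_n = sum(in_avg),
                 t = trig_time),
            class = "measurement_sample")
}

#' @export
print.measurement_sample <- function(x, ...) {
  cat(sprintf("measurement '%s' (%s): (%.2f, %.2f, %.2f) mm [%s], stability %.3f mm, %s\n",
              x$label, x$role, x$position[1], x$position[2], x$position[3],
              x$frame, x$stability_mm, if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

# nearest-sample indices of sorted reference times for each query time
nearest_indices <- function(ref_t, query_t, device, tol = TIME_MATCH_TOL) {
  lo <- findInterval(query_t, ref_t)
  lo <- pmin(pmax(lo, 1L), length(ref_t))
  hi <- pmin(lo + 1L, length(ref_t))
  idx <- ifelse(abs(ref_t[hi] - query_t) < abs(ref_t[lo] - query_t), hi, lo)
  gap <- abs(ref_t[idx] - query_t)
  if (any(gap > tol))
    stop(sprintf("missing tracker pose: no '%s' sample within %.0f ms of t=%.3f",
                 device, tol * 1000, query_t[which(gap > tol)[1]]),
         call. = FALSE)
  idx
}

# nearest-sample pose of a device at a given time (no interpolation)
pose_at_time <- function(stream, device, time, tol = TIME_MATCH_TOL) {
  keep <- which(stream$device == device)
  if (!length(keep)) stop(sprintf("unknown device id '%s'", device), call. = FALSE)
  ord <- keep[order(stream$t[keep])]
  i <- ord[nearest_indices(stream$t[ord], time, device, tol)]
  from_matrix4(stream$T[, , i])
}

#' Express a global point in head-tracker coordinates
#'
#' Each tracker's coordinate of the point is `invert(pose) applied to the
#' global point`.  With more than one tracker the per-tracker coordinates
#' are re-expressed in a common session frame -- the first tracker's pose at
#' session start -- and averaged.
#'
#' @param point_global length-3 global point (mm).
#' @param tracker_poses named list of `rigid_transform` tracker poses at the
#'   sample time (1 or 2 trackers).
#' @param reference_poses named list of the same trackers' poses at session
#'   start; defaults to `tracker_poses` (single-time-point use).
#' @return list with `per_tracker` (named list of length-3 head-frame
#'   coordinates) and `combined` (length-3, session head frame anchored at
#'   tracker 1's start pose).
#' @export
compensate_head <- function(point_global, tracker_poses,
                            reference_poses = tracker_poses) {
  stopifnot(length(tracker_poses) >= 1L,
            all(names(tracker_poses) %in% names(reference_poses)))
  ids <- names(tracker_poses)
  per <- lapply(tracker_poses, function(P)
    apply_transform(invert(P), point_global))
  anchor <- invert(reference_poses[[ids[1]]])
  mapped <- lapply(ids, function(id)
    apply_transform(compose(anchor, reference_poses[[id]]), per[[id]]))
  list(per_tracker = per,
       combined = Reduce(`+`, mapped) / length(mapped))
}

# head-relative endpoint series: for each controller sample, map the global
# endpoint through the trackers' nearest-in-time poses into the session head
# frame (tracker 1 at session start)
compensated_timeseries <- function(stream, device, endpoint, tracker_ids,
                                   reference_time = NULL) {
  series <- endpoint_timeseries(stream, device, endpoint)
  if (is.null(reference_time)) reference_time <- min(stream$t)
  refs <- stats::setNames(
    lapply(tracker_ids, function(id) pose_at_time(stream, id, reference_time)),
    tracker_ids)
  anchor <- invert(refs[[tracker_ids[1]]])
  n <- length(series$t)
  out <- matrix(0, n, 3)
  for (id in tracker_ids) {
    keep <- which(stream$device == id)
    ord <- keep[order(stream$t[keep])]
    idx <- ord[nearest_indices(stream$t[ord], series$t, id)]
    A <- compose(anchor, refs[[id]])  # tracker-k frame -> session head frame
    for (i in seq_len(n)) {
      M <- stream$T[, , idx[i]]
      h <- crossprod(M[1:3, 1:3], series$pos[i, ] - M[1:3, 4])
      out[i, ] <- out[i, ] + A$R %*% h + A$t
    }
  }
  structure(list(t = series$t, pos = out / length(tracker_ids)),
            class = "endpoint_series")
}

#' Detect head-tracker mismatch (slip)
#'
#' With two trackers rigidly attached to the head, their relative transform
#' `invert(pose1) o pose2` is constant; if one tracker slips, it changes.
#' The mismatch magnitude at each time is the largest displacement of a
#' probe set (the tracker-2 origin and three 100-mm axis points) under the
#' current relative transform versus the session-initial one.
#'
#' @param stream A `pose_stream` containing both trackers.
#' @param tracker_ids character vector of 2 tracker device ids.
#' @param threshold_mm mismatch threshold (default 3 mm at the 100-mm lever
#'   arm, comparable to the system's overall error scale).
#' @param lever_mm probe lever arm (default 100 mm).
#' @return Object of class `mismatch_report`: `applicable`, `times`,
#'   `mismatch_mm` (per-time magnitude), `flagged`, `first_time`,
#'   `magnitude` (at first exceedance), `threshold_mm`.  With a single
#'   tracker, `applicable = FALSE` (no error).
#' @export
detect_tracker_mismatch <- function(stream, tracker_ids,
                                    threshold_mm = 3, lever_mm = 100) {
  if (length(tracker_ids) < 2L)
    return(structure(list(applicable = FALSE, flagged = FALSE,
                          times = numeric(0), mismatch_mm = numeric(0),
                          first_time = NA_real_, magnitude = NA_real_,
                          threshold_mm = threshold_mm),
                     class = "mismatch_report"))
  id1 <- tracker_ids[1]; id2 <- tracker_ids[2]
  k1 <- which(stream$device == id1); k1 <- k1[order(stream$t[k1])]
  k2 <- which(stream$device == id2); k2 <- k2[order(stream$t[k2])]
  t1 <- stream$t[k1]
  i2 <- k2[nearest_indices(stream$t[k2], t1, id2)]
  probes <- rbind(c(0, 0, 0), diag(3) * lever_mm)
  rel_probe <- function(j1, j2) {
    # probes under invert(pose1) o pose2, without S3 overhead
    M1 <- stream$T[, , j1]; M2 <- stream$T[, , j2]
    g <- sweep(probes %*% t(M2[1:3, 1:3]), 2, M2[1:3, 4], "+")
    sweep(g, 2, M1[1:3, 4]) %*% M1[1:3, 1:3]
  }
  p0 <- rel_probe(k1[1], i2[1])
  mm <- vapply(seq_along(t1), function(i) {
    max(sqrt(rowSums((rel_probe(k1[i], i2[i]) - p0)^2)))
  }, numeric(1))
  exceed <- which(mm > threshold_mm)
  structure(list(applicable = TRUE, times = t1, mismatch_mm = mm,
                 flagged = length(exceed) > 0,
                 first_time = if (length(exceed)) t1[exceed[1]] else NA_real_,
                 magnitude = if (length(exceed)) mm[exceed[1]] else NA_real_,
                 threshold_mm = threshold_mm),
            class = "mismatch_report")
}

#' @export
print.mismatch_report <- function(x, ...) {
  if (!x$applicable) {
    cat("mismatch_report: single-tracker session, not applicable\n")
  } else if (x$flagged) {
    cat(sprintf("mismatch_report: FLAGGED at t=%.3f s, magnitude %.2f mm (threshold %.1f mm)\n",
                x$first_time, x$magnitude, x$threshold_mm))
  } else {
    cat(sprintf("mismatch_report: no mismatch (max %.3f mm, threshold %.1f mm)\n",
                if (length(x$mismatch_mm)) max(x$mismatch_mm) else 0,
                x$threshold_mm))
  }
  invisible(x)
}

#' Replay a recorded pose stream into a digitization session
#'
#' Consumes the stream's trigger events in time order, binding the i-th
#' trigger to the i-th planned target (fiducials first, then electrodes in
#' montage order, then any headshape re-measurements of the fiducials).
#' Samples failing the stability gate are recorded but flagged invalid
#' (electrodes) or dropped (fiducial repeats and headshape points); invalid
#' electrodes are excluded from evaluation and exports like rejected ones.
#'
#' @param stream A `pose_stream` with embedded triggers.
#' @param montage A `montage`.
#' @param endpoint `endpoint_offset` or length-3 vector (mm).
#' @param controller controller device id (default `"controller"`).
#' @param tracker_ids optional character vector of 1-2 head-tracker ids;
#'   when given, sampling is done in head-relative coordinates.
#' @param fiducial_names fiducial names in measurement order.
#' @param fiducial_repeats number of repeated measurements per fiducial.
#' @param headshape_refiducials number of post-session headshape
#'   re-measurements per fiducial (0 to disable).
#' @param avg_window,stab_window,stab_thresh gate parameters, see
#'   [sample_measurement()].
#' @return A `digitization_session`.
#' @export
replay_digitize <- function(stream, montage, endpoint,
                            controller = "controller", tracker_ids = NULL,
                            fiducial_names = c("nasion", "lpa", "rpa"),
                            fiducial_repeats = 1L,
                            headshape_refiducials = 0L,
                            avg_window = DEFAULT_AVG_WINDOW,
                            stab_window = DEFAULT_STAB_WINDOW,
                            stab_thresh = DEFAULT_STAB_THRESH) {
  stopifnot(inherits(stream, "pose_stream"), inherits(montage, "montage"))
  series <- if (length(tracker_ids))
    compensated_timeseries(stream, controller, endpoint, tracker_ids)
  else
    endpoint_timeseries(stream, controller, endpoint)
  frame <- if (length(tracker_ids))
    paste0("tracker-relative(", paste(tracker_ids, collapse = ","), ")")
  else "global"
  session <- digitization_session(
    montage, fiducial_names = fiducial_names, tracker_ids = tracker_ids,
    provenance = list(system = "digikit-replay",
                      endpoint_mm = as_offset_vec(endpoint),
                      avg_window_s = avg_window, stab_window_s = stab_window,
                      stab_thresh_mm = stab_thresh))
  # full target plan: repeated fiducials, electrodes, headshape re-fiducials
  plan <- c(rep(fiducial_names, each = fiducial_repeats),
            montage$labels,
            rep(fiducial_names, each = headshape_refiducials))
  roles <- c(rep("fiducial", length(fiducial_names) * fiducial_repeats),
             rep("electrode", length(montage$labels)),
             rep("headshape", length(fiducial_names) * headshape_refiducials))
  trig <- stream$triggers[stream$triggers$device == controller, , drop = FALSE]
  trig <- trig[order(trig$t), , drop = FALSE]
  n_assign <- min(nrow(trig), length(plan))
  for (k in seq_len(n_assign)) {
    m <- sample_measurement(series, trig$t[k], avg_window, stab_window,
                            stab_thresh, label = plan[k], role = roles[k],
                            frame = frame)
    if (!m$valid && roles[k] != "electrode") next
    session <- session_add_measurement(session, m)
  }
  session$complete <- n_assign >= length(plan)
  session
}
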