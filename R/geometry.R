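# Rigid-body algebra: transforms, points, composition, inversion, and the
# JSON-lines pose-stream format shared by all acquisition and simulation code.
# All lengths are millimeters throughout the package; any meter-native input
# must be converted (factor 1000) at stream ingestion.

RIGID_TOL <- 1e-9       # construction tolerance on orthonormality / det
RIGID_REPAIR_TOL <- 1e-6 # inputs worse than RIGID_TOL but within this are
                         # projected to the nearest rotation (and flagged)

#' Construct a rigid transform
#'
#' A rigid transform maps device-local coordinates to global coordinates as
#' `rotation %*% p + translation`.  The rotation must be orthonormal with
#' determinant +1 to within `1e-9`; matrices that fail by at most `1e-6`
#' (e.g. accumulated round-off from composing many transforms) are projected
#' to the nearest rotation via SVD and a message is emitted; worse inputs are
#' rejected with a rigidity error.
#'
#' @param rotation 3x3 orthonormal matrix, determinant +1.
#' @param translation numeric length-3 vector, millimeters.
#' @return An object of class `rigid_transform` with fields `R` and `t`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(10, 0, 0))
#' apply_transform(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform: rotation must be 3x3 and translation length 3",
         call. = FALSE)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite components", call. = FALSE)
  err <- rigidity_error(rotation)
  if (err > RIGID_TOL) {
    if (err <= RIGID_REPAIR_TOL) {
      rotation <- nearest_rotation(rotation)
      message(sprintf(
        "rigid_transform: re-orthonormalized near-rigid rotation (error %.3g)",
        err))
    } else {
      stop(sprintf(
        "rigid_transform: matrix is not rigid (orthonormality/det error %.3g > %.0e)",
        err, RIGID_REPAIR_TOL), call. = FALSE)
    }
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

# max deviation from orthonormality and from det +1
rigidity_error <- function(R) {
  max(max(abs(crossprod(R) - diag(3))), abs(det(R) - 1))
}

# nearest rotation in Frobenius norm (polar decomposition via SVD)
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$R, 6))
  cat("  translation (mm):", format(x$t, digits = 6), "\n")
  invisible(x)
}

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to one or more points
#'
#' @param t A `rigid_transform`.
#' @param p Numeric length-3 vector, or an n x 3 matrix of row points (mm).
#' @return Transformed point(s), same shape as `p`.
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(sweep(p %*% t(t$R), 2L, t$t, "+"))
  }
  p <- as.numeric(p)
  stopifnot(length(p) == 3L)
  as.numeric(t$R %*% p + t$t)
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`:
#' `apply_transform(compose(a, b), p) == apply_transform(a, apply_transform(b, p))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t + a$t))
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse transform: rotation transposed, translation `-R't`.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$R)
  rigid_transform(Rt, as.numeric(-Rt %*% t$t))
}

#' Convert a rigid transform to / from a 4x4 homogeneous matrix
#'
#' @param t A `rigid_transform`.
#' @return `as_matrix4`: a 4x4 matrix with bottom row (0,0,0,1).
#' @export
as_matrix4 <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  M <- rbind(cbind(t$R, t$t), c(0, 0, 0, 1))
  dimnames(M) <- NULL
  M
}

#' @param M 4x4 homogeneous matrix; bottom row must be (0,0,0,1).
#' @rdname as_matrix4
#' @export
from_matrix4 <- function(M) {
  M <- as.matrix(M)
  stopifnot(all(dim(M) == c(4L, 4L)))
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > RIGID_TOL)
    stop("from_matrix4: bottom row must be (0,0,0,1)", call. = FALSE)
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}

#' Construct an endpoint offset
#'
#' The calibrated vector from the controller origin to the stylus tip,
#' expressed in the controller-local (device) frame.
#'
#' @param offset numeric length-3 vector (mm).
#' @param bound_mm maximum allowed magnitude (default 200 mm; physical stylus
#'   stubs are a few centimeters).
#' @return Object of class `endpoint_offset`.
#' @export
endpoint_offset <- function(offset, bound_mm = 200) {
  offset <- as.numeric(offset)
  stopifnot(length(offset) == 3L, all(is.finite(offset)))
  if (sqrt(sum(offset^2)) > bound_mm)
    stop(sprintf("endpoint_offset: |offset| = %.1f mm exceeds bound %.1f mm",
                 sqrt(sum(offset^2)), bound_mm), call. = FALSE)
  structure(list(offset = offset), class = "endpoint_offset")
}

# coerce endpoint argument (vector or endpoint_offset) to a plain 3-vector
as_offset_vec <- function(endpoint) {
  if (inherits(endpoint, "endpoint_offset")) return(endpoint$offset)
  v <- as.numeric(endpoint)
  stopifnot(length(v) == 3L, all(is.finite(v)))
  v
}

# rotation about a unit axis by angle (radians), Rodrigues formula
rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## ---- pose streams ---------------------------------------------------------

#' Construct a pose stream
#'
#' A timestamped sequence of (device, 4x4 rigid transform) samples with
#' optional trigger events, the raw input to acquisition.  Stored internally
#' as a parallel structure: times, device ids and a 4 x 4 x n array.
#'
#' @param t numeric vector of sample times (seconds).
#' @param device character vector of device ids, same length as `t`.
#' @param T 4 x 4 x n array of homogeneous transforms, or a list of
#'   `rigid_transform` objects.
#' @param triggers data.frame with columns `t` (seconds) and `device`, or NULL.
#' @return Object of class `pose_stream`.
#' @export
pose_stream <- function(t, device, T, triggers = NULL) {
  t <- as.numeric(t)
  device <- as.character(device)
  if (is.list(T)) {
    arr <- array(0, dim = c(4, 4, length(T)))
    for (i in seq_along(T)) arr[, , i] <- as_matrix4(T[[i]])
    T <- arr
  }
  stopifnot(length(t) == length(device), dim(T)[3] == length(t))
  if (is.null(triggers))
    triggers <- data.frame(t = numeric(0), device = character(0))
  if (nrow(triggers) > 0 && length(t) > 0) {
    bad <- triggers$t < min(t) - 1e-9 | triggers$t > max(t) + 1e-9
    if (any(bad))
      stop("pose_stream: trigger time outside the stream's span", call. = FALSE)
  }
  structure(list(t = t, device = device, T = T, triggers = triggers),
            class = "pose_stream")
}

#' @export
print.pose_stream <- function(x, ...) {
  cat(sprintf("pose_stream: %d samples, devices {%s}, %d triggers, span %.2f s\n",
              length(x$t), paste(unique(x$device), collapse = ", "),
              nrow(x$triggers),
              if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}

#' Device ids present in a stream
#' @param stream A `pose_stream`.
#' @export
stream_devices <- function(stream) unique(stream$device)

#' Subset a pose stream to a single device
#' @param stream A `pose_stream`.
#' @param device device id to keep.
#' @return A `pose_stream` holding only that device's samples (triggers for
#'   the device are kept too).
#' @export
stream_subset <- function(stream, device) {
  stopifnot(inherits(stream, "pose_stream"))
  keep <- stream$device == device
  if (!any(keep)) stop(sprintf("unknown device id '%s'", device), call. = FALSE)
  pose_stream(stream$t[keep], stream$device[keep],
              stream$T[, , keep, drop = FALSE],
              stream$triggers[stream$triggers$device == device, , drop = FALSE])
}

#' Read / write pose streams as JSON-lines
#'
#' One record per line.  Pose samples are
#' `{"t": <sec>, "device": "<id>", "T": [16 floats, row-major 4x4]}` with the
#' bottom row required to be (0,0,0,1); trigger events are
#' `{"t": <sec>, "device": "<id>", "event": "trigger"}`.  Numbers are written
#' with 17 significant digits so that write-then-read round-trips bit-exactly.
#'
#' @param path file path.
#' @return `read_pose_stream`: a `pose_stream`.
#' @export
read_pose_stream <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  t <- numeric(n); device <- character(n)
  Tarr <- array(0, dim = c(4, 4, n))
  is_pose <- logical(n)
  trig_t <- numeric(0); trig_dev <- character(0)
  for (i in seq_len(n)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("malformed JSONL at line %d: %s",
                                   i, conditionMessage(e)), call. = FALSE))
    if (is.null(rec$t) || is.null(rec$device))
      stop(sprintf("malformed pose record at line %d: missing t/device", i),
           call. = FALSE)
    if (!is.null(rec$event)) {
      if (!identical(rec$event, "trigger"))
        stop(sprintf("unknown event type at line %d: %s", i, rec$event),
             call. = FALSE)
      trig_t <- c(trig_t, rec$t); trig_dev <- c(trig_dev, rec$device)
      next
    }
    if (is.null(rec$T) || length(rec$T) != 16L)
      stop(sprintf("malformed pose record at line %d: T must have 16 floats", i),
           call. = FALSE)
    M <- matrix(rec$T, 4, 4, byrow = TRUE)
    if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 0)
      stop(sprintf("bad bottom row in transform at line %d", i), call. = FALSE)
    is_pose[i] <- TRUE
    t[i] <- rec$t; device[i] <- rec$device; Tarr[, , i] <- M
  }
  keep <- which(is_pose)
  pose_stream(t[keep], device[keep], Tarr[, , keep, drop = FALSE],
              data.frame(t = trig_t, device = trig_dev,
                         stringsAsFactors = FALSE))
}

#' @param stream A `pose_stream` to write.
#' @rdname read_pose_stream
#' @export
write_pose_stream <- function(stream, path) {
  stopifnot(inherits(stream, "pose_stream"))
  n <- length(stream$t)
  fmt_num <- function(x) sprintf("%.17g", x)
  pose_lines <- vapply(seq_len(n), function(i) {
    Tv <- as.vector(t(stream$T[, , i]))  # row-major
    sprintf('{"t": %s, "device": %s, "T": [%s]}',
            fmt_num(stream$t[i]),
            jsonlite::toJSON(stream$device[i], auto_unbox = TRUE),
            paste(fmt_num(Tv), collapse = ", "))
  }, character(1))
  trig_lines <- if (nrow(stream$triggers) > 0) {
    vapply(seq_len(nrow(stream$triggers)), function(i) {
      sprintf('{"t": %s, "device": %s, "event": "trigger"}',
              fmt_num(stream$triggers$t[i]),
              jsonlite::toJSON(stream$triggers$device[i], auto_unbox = TRUE))
    }, character(1))
  } else character(0)
  # interleave in time order so replay order is the file order
  all_t <- c(stream$t, stream$triggers$t)
  all_lines <- c(pose_lines, trig_lines)
  writeLines(all_lines[order(all_t)], path)
  invisible(path)
}
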