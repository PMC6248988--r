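# Endpoint (pivot) calibration.  The stylus tip is held at one fixed physical
# point while the controller is rotated into N different orientations; the
# device-frame tip offset x_c is the vector that minimizes the spread of the
# implied global tip positions
#
#   sum_i | R_i x_c + t_i  -  mean_j (R_j x_c + t_j) |^2 .
#
# Writing D_i = R_i - Rbar and d_i = t_i - tbar, the objective is the convex
# quadratic sum_i |D_i x_c + d_i|^2, whose unconstrained minimizer coincides
# with the classical linear pivot solve (stack R_i x_c - p = -t_i over the
# unknown offset x_c and fixed point p).  The public solver still runs a
# bounded nonlinear refinement from the linear initialization, mirroring the
# constrained-optimization formulation; the linear solve is retained as an
# independent oracle.

DEGENERACY_SV_TOL <- 1e-3  # smallest singular value of stacked (R_i - Rbar)

#' Build a calibration set from rigid poses
#'
#' @param transforms list of `rigid_transform` pose samples, all taken with
#'   the stylus tip at one fixed physical location.
#' @param min_n minimum number of poses (default 3).
#' @return Object of class `calibration_set`: fields `transforms`, `n`,
#'   `diversity` (smallest singular value of the stacked rotation-difference
#'   system) and `degenerate` flag.
#' @export
calibration_set <- function(transforms, min_n = 3L) {
  stopifnot(is.list(transforms),
            all(vapply(transforms, inherits, logical(1), "rigid_transform")))
  n <- length(transforms)
  if (n < min_n)
    stop(sprintf("calibration_set: need at least %d poses, got %d", min_n, n),
         call. = FALSE)
  sv <- rotation_diversity(transforms)
  structure(list(transforms = transforms, n = n,
                 diversity = sv, degenerate = sv < DEGENERACY_SV_TOL),
            class = "calibration_set")
}

# smallest singular value of the 3N x 3 stack of (R_i - Rbar); zero when all
# rotations are equal (offset unidentifiable) and small when rotations share
# a single axis through the tip
rotation_diversity <- function(transforms) {
  Rs <- lapply(transforms, function(tr) tr$R)
  Rbar <- Reduce(`+`, Rs) / length(Rs)
  D <- do.call(rbind, lapply(Rs, function(R) R - Rbar))
  min(svd(D, nu = 0, nv = 0)$d)
}

# objective/gradient pieces shared by solver and quality metrics
calib_system <- function(cal) {
  Rs <- lapply(cal$transforms, function(tr) tr$R)
  ts <- do.call(rbind, lapply(cal$transforms, function(tr) tr$t))
  Rbar <- Reduce(`+`, Rs) / cal$n
  tbar <- colMeans(ts)
  D <- do.call(rbind, lapply(Rs, function(R) R - Rbar))      # 3N x 3
  d <- as.vector(t(sweep(ts, 2, tbar)))                      # stacked d_i
  list(Rs = Rs, ts = ts, D = D, d = d)
}

# spread objective sum_i |x_gi - mean(x_g)|^2 for a given offset
calib_objective <- function(cal, xc) {
  sys <- calib_system(cal)
  r <- sys$D %*% xc + sys$d
  sum(r^2)
}

# implied global tip positions x_gi = R_i x_c + t_i  (n x 3)
implied_tips <- function(cal, xc) {
  do.call(rbind, lapply(cal$transforms,
                        function(tr) as.numeric(tr$R %*% xc + tr$t)))
}

#' Linear pivot-calibration oracle
#'
#' Solves the stacked linear least-squares system `R_i x_c - p = -t_i` for
#' the device-frame offset `x_c` and the fixed global tip position `p`.  On
#' noiseless input this equals the spread-minimizing solution exactly; it is
#' kept as an independent closed-form oracle and as the initialization for
#' [calibrate_endpoint()].
#'
#' @param cal A `calibration_set`.
#' @return list with `endpoint` (`endpoint_offset`) and `fixed_point`
#'   (length-3, mm).
#' @export
linear_pivot_oracle <- function(cal) {
  stopifnot(inherits(cal, "calibration_set"))
  if (cal$degenerate)
    stop(degenerate_message(cal), call. = FALSE)
  A <- do.call(rbind, lapply(cal$transforms,
                             function(tr) cbind(tr$R, -diag(3))))
  b <- -as.vector(t(do.call(rbind, lapply(cal$transforms,
                                          function(tr) tr$t))))
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-8 * sv[1])
    stop("linear_pivot_oracle: rank-deficient system (degenerate calibration)",
         call. = FALSE)
  sol <- qr.solve(A, b)
  list(endpoint = endpoint_offset(sol[1:3], bound_mm = Inf),
       fixed_point = sol[4:6])
}

degenerate_message <- function(cal) {
  sys <- calib_system(cal)
  s <- svd(sys$D)
  dir <- s$v[, which.min(s$d)]
  sprintf(paste0("degenerate calibration: rotation set has no diversity ",
                 "along device direction (%.3f, %.3f, %.3f) ",
                 "(smallest singular value %.2e < %.0e); rotate the ",
                 "controller about at least two distinct axes"),
          dir[1], dir[2], dir[3], min(s$d), DEGENERACY_SV_TOL)
}

#' Calibrate the stylus endpoint from a set of poses
#'
#' Estimates the device-frame tip offset that minimizes the spread of the
#' implied global tip positions across the calibration poses, subject to a
#' norm bound on the offset.  The solver initializes at the
#' [linear_pivot_oracle()] solution and refines with a bounded quasi-Newton
#' iteration; by construction the returned objective is never worse than the
#' initialization's.
#'
#' @param cal A `calibration_set`.
#' @param bound_mm norm bound on the offset magnitude (default 200 mm).
#' @param tol convergence tolerance on objective change (default 1e-9).
#' @param max_iter iteration cap (default 500).
#' @param allow_degenerate if TRUE, proceed on a degenerate set with a
#'   warning instead of an error.
#' @return Object of class `calibration_result`: `endpoint`
#'   (`endpoint_offset`), `fixed_point` (mean implied tip, mm),
#'   `max_deviation` (mm), `residuals` (per-sample deviation from the mean
#'   tip, mm), `objective`, `n`, `converged`.
#' @export
calibrate_endpoint <- function(cal, bound_mm = 200, tol = 1e-9,
                               max_iter = 500L, allow_degenerate = FALSE) {
  stopifnot(inherits(cal, "calibration_set"))
  if (cal$degenerate) {
    if (!allow_degenerate) stop(degenerate_message(cal), call. = FALSE)
    warning(degenerate_message(cal), call. = FALSE)
  }
  init <- linear_pivot_oracle(cal)$endpoint$offset
  if (sqrt(sum(init^2)) > bound_mm)
    init <- init * (bound_mm / sqrt(sum(init^2))) * 0.999
  sys <- calib_system(cal)
  fn <- function(x) sum((sys$D %*% x + sys$d)^2)
  gr <- function(x) as.numeric(2 * crossprod(sys$D, sys$D %*% x + sys$d))
  opt <- stats::optim(init, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  xc <- opt$par
  if (sqrt(sum(xc^2)) > bound_mm) {
    # active norm constraint: solve the trust-region style subproblem
    # (M + lambda I) x = -g with |x| = bound_mm by bisection on lambda >= 0
    M <- crossprod(sys$D)
    g <- as.numeric(crossprod(sys$D, sys$d))
    norm_at <- function(lam) sqrt(sum(solve(M + lam * diag(3), -g)^2))
    lo <- 0; hi <- 1
    while (norm_at(hi) > bound_mm) hi <- hi * 2
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (norm_at(mid) > bound_mm) lo <- mid else hi <- mid
    }
    xc <- solve(M + hi * diag(3), -g)
  }
  obj <- fn(xc)
  obj_init <- fn(init)
  if (obj > obj_init + 1e-12 * max(1, obj_init)) {
    xc <- init          # refinement may not regress below the oracle
    obj <- obj_init
  }
  if (!is.finite(obj))
    stop(sprintf("calibration failed to converge (objective %g)", obj),
         call. = FALSE)
  tips <- implied_tips(cal, xc)
  ctr <- colMeans(tips)
  dev <- sqrt(rowSums(sweep(tips, 2, ctr)^2))
  structure(list(endpoint = endpoint_offset(xc, bound_mm = bound_mm),
                 fixed_point = ctr,
                 max_deviation = max(dev),
                 residuals = dev,
                 objective = obj,
                 n = cal$n,
                 converged = opt$convergence == 0),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("calibration_result: endpoint (%.3f, %.3f, %.3f) mm, ",
                     "max deviation %.4f mm over %d poses\n"),
              x$endpoint$offset[1], x$endpoint$offset[2], x$endpoint$offset[3],
              x$max_deviation, x$n))
  invisible(x)
}

#' Calibration quality: maximum deviation from the mean tip position
#'
#' Given a calibration set and an endpoint offset, computes the implied
#' global tip position for each pose and returns the maximum Euclidean
#' distance from their mean, in millimeters.  (The quality metric is
#' reported as an unsquared distance so that it reads directly in mm.)
#'
#' @param cal A `calibration_set`.
#' @param endpoint An `endpoint_offset` or length-3 vector (mm).
#' @return Maximum deviation from the mean implied tip, mm.
#' @export
calibration_quality <- function(cal, endpoint) {
  stopifnot(inherits(cal, "calibration_set"))
  xc <- as_offset_vec(endpoint)
  tips <- implied_tips(cal, xc)
  ctr <- colMeans(tips)
  max(sqrt(rowSums(sweep(tips, 2, ctr)^2)))
}

#' Write / read a calibration result as JSON
#'
#' The on-disk form is `{"endpoint_mm": [x,y,z], "max_deviation_mm": d,
#' "n_samples": N}`.
#'
#' @param result A `calibration_result`.
#' @param path file path.
#' @export
write_calibration <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(endpoint_mm = result$endpoint$offset,
         max_deviation_mm = result$max_deviation,
         n_samples = result$n),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_calibration
#' @return `read_calibration`: list with `endpoint` (`endpoint_offset`),
#'   `max_deviation`, `n`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- jsonlite::fromJSON(path)
  if (is.null(x$endpoint_mm) || length(x$endpoint_mm) != 3L)
    stop("read_calibration: missing/invalid endpoint_mm", call. = FALSE)
  list(endpoint = endpoint_offset(as.numeric(x$endpoint_mm), bound_mm = Inf),
       max_deviation = x$max_deviation_mm, n = x$n_samples)
}
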