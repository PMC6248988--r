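# Shared fixtures and independent oracles.  Oracles here are deliberately
# naive (direct formulas, grids, forward simulation) and never call the code
# paths they check.

# random rigid transform with translation scale `trans_mm`
random_rigid <- function(trans_mm = 100) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- rotation_aa(ax, stats::runif(1, 0, pi))
  rigid_transform(R, stats::rnorm(3, 0, trans_mm))
}

# Rodrigues rotation, written out independently of the package internals
rotation_aa <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# direct 4x4 homogeneous product oracle for compose()
matmul4_oracle <- function(a, b) as_matrix4(a) %*% as_matrix4(b)

# forward-simulated calibration poses: rotations about the given axes
# (cycled), tip fixed at `fixed_point`, true device-frame offset `xc`
make_calibration_poses <- function(xc, fixed_point = c(100, 50, 200),
                                   axes = list(c(1, 0, 0), c(0, 1, 0)),
                                   angles_deg = c(-45, 45, 30, -30),
                                   jitter = 0) {
  lapply(seq_along(angles_deg), function(i) {
    R <- rotation_aa(axes[[(i - 1) %% length(axes) + 1]],
                     angles_deg[i] * pi / 180)
    tt <- fixed_point - as.numeric(R %*% xc)
    if (jitter > 0) tt <- tt + stats::rnorm(3, 0, jitter)
    rigid_transform(R, tt)
  })
}

# spread objective computed from first principles (for optimality checks)
spread_objective_oracle <- function(transforms, xc) {
  tips <- t(vapply(transforms, function(tr) as.numeric(tr$R %*% xc + tr$t),
                   numeric(3)))
  ctr <- colMeans(tips)
  sum(rowSums(sweep(tips, 2, ctr)^2))
}

# Brute-force rigid-alignment oracle: exhaustive Euler-angle grid with the
# closed-form optimal translation per rotation, then Nelder-Mead refinement.
# SVD-free by construction.
brutforce_align_residual <- function(test, ref, coarse_deg = 20) {
  euler_R <- function(a, b, c)
    rotation_aa(c(0, 0, 1), c) %*% rotation_aa(c(0, 1, 0), b) %*%
      rotation_aa(c(1, 0, 0), a)
  resid <- function(ang) {
    R <- euler_R(ang[1], ang[2], ang[3])
    tr <- colMeans(ref) - as.numeric(R %*% colMeans(test))
    sum((sweep(test %*% t(R), 2, tr, "+") - ref)^2)
  }
  g <- seq(-pi, pi, by = coarse_deg * pi / 180)
  gb <- seq(-pi / 2, pi / 2, by = coarse_deg * pi / 180)
  best <- c(0, 0, 0); best_v <- resid(best)
  for (a in g) for (b in gb) for (c in g) {
    v <- resid(c(a, b, c))
    if (v < best_v) { best_v <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, resid, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# synthetic endpoint series: constant position plus optional injected parts
make_series <- function(times, base = c(10, 20, 30), add = NULL) {
  pos <- matrix(rep(base, each = length(times)), ncol = 3)
  if (!is.null(add)) pos <- pos + add
  structure(list(t = times, pos = pos), class = "endpoint_series")
}

# minimal three-electrode session at given positions
make_session <- function(pos, labels = rownames(pos),
                         fiducials = NULL) {
  s <- digitization_session(montage(labels))
  for (i in seq_along(labels))
    s$electrodes[[labels[i]]] <- list(position = pos[i, ], frame = "global",
                                      valid = TRUE, stability_mm = 0,
                                      t = NA_real_)
  if (!is.null(fiducials))
    for (nm in names(fiducials))
      s$fiducial_repeats[[nm]] <- matrix(fiducials[[nm]], 1, 3)
  s
}
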