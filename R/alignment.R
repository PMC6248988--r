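# Alignment and error evaluation: rigid (Kabsch) point-set registration with
# determinant correction, per-electrode Euclidean error maps, RMSE
# aggregation, Welch's t-test, electrode rejection, and reference-dataset
# selection.

#' Rigid point-set alignment (Kabsch)
#'
#' Finds the rigid transform (rotation with determinant +1 plus translation,
#' no scaling) minimizing the sum of squared distances
#' `sum_i |T test_i - ref_i|^2` over label-matched pairs, via the
#' cross-covariance SVD with determinant correction (reflection optima are
#' folded back to proper rotations).
#'
#' @param test,ref n x 3 matrices of paired points (mm), n >= 3,
#'   non-collinear.
#' @return A `rigid_transform` mapping test coordinates onto the reference.
#' @export
rigid_align <- function(test, ref) {
  test <- as.matrix(test); ref <- as.matrix(ref)
  stopifnot(ncol(test) == 3L, ncol(ref) == 3L, nrow(test) == nrow(ref))
  if (nrow(test) < 3L)
    stop("rigid_align: need at least 3 point pairs", call. = FALSE)
  ct <- colMeans(test); cr <- colMeans(ref)
  X <- sweep(test, 2, ct); Y <- sweep(ref, 2, cr)
  # collinearity: centered points must span at least 2 dimensions
  if (svd(X, nu = 0, nv = 0)$d[2] < 1e-9 * max(1, svd(X, nu = 0, nv = 0)$d[1]))
    stop("rigid_align: degenerate (collinear) point configuration",
         call. = FALSE)
  H <- crossprod(X, Y)                 # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, as.numeric(cr - R %*% ct))
}

rmse <- function(errors) sqrt(mean(errors^2))

#' Align one session to a reference and compute localization errors
#'
#' Estimates a single rigid transform from the chosen correspondence mode --
#' aggregated anatomical fiducials, or shared electrodes -- applies it to
#' the test session, then reports the Euclidean distance between each shared
#' non-rejected electrode and its reference location.  Errors are always
#' computed over electrodes, whichever mode drove the alignment.
#'
#' @param test,ref `digitization_session` objects.
#' @param mode `"electrodes"` or `"fiducials"`.
#' @return Object of class `alignment_result`: `transform`, `per_label_error`
#'   (named, mm), `rmse`, `max_error`, `n_used`, `mode`.
#' @export
evaluate_dataset <- function(test, ref, mode = c("electrodes", "fiducials")) {
  mode <- match.arg(mode)
  stopifnot(inherits(test, "digitization_session"),
            inherits(ref, "digitization_session"))
  test_all <- electrode_positions(test)   # excludes rejected + gate-invalid
  ref_all <- electrode_positions(ref)
  shared <- intersect(rownames(test_all), rownames(ref_all))
  if (length(shared) < 1L)
    stop("no shared non-rejected electrodes to evaluate", call. = FALSE)
  test_el <- test_all[shared, , drop = FALSE]
  ref_el <- ref_all[shared, , drop = FALSE]
  if (mode == "electrodes") {
    if (length(shared) < 3L)
      stop("need >= 3 shared electrodes to align by electrodes", call. = FALSE)
    tr <- rigid_align(test_el, ref_el)
  } else {
    tf <- session_fiducials(test); rf <- session_fiducials(ref)
    common <- intersect(names(tf), names(rf))
    if (length(common) < 3L)
      stop(sprintf("need >= 3 shared fiducials to align by fiducials (have %d)",
                   length(common)), call. = FALSE)
    tr <- rigid_align(
      do.call(rbind, lapply(tf[common], function(f) f$aggregate)),
      do.call(rbind, lapply(rf[common], function(f) f$aggregate)))
  }
  aligned <- apply_transform(tr, test_el)
  err <- sqrt(rowSums((aligned - ref_el)^2))
  names(err) <- shared
  structure(list(transform = tr, per_label_error = err, rmse = rmse(err),
                 max_error = max(err), n_used = length(shared), mode = mode),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result (%s): RMSE %.3f mm, max %.3f mm over %d electrodes\n",
              x$mode, x$rmse, x$max_error, x$n_used))
  invisible(x)
}

#' Reject electrodes from a session
#'
#' Flagged electrodes (e.g. operator errors spotted on inspection) are
#' excluded from all subsequent correspondence and error computations; the
#' count is retained for reporting and reference selection.
#'
#' @param session A `digitization_session`.
#' @param labels electrode labels to reject; must be measured electrodes
#'   (fiducial names are not electrodes).
#' @return The updated session.
#' @export
reject_electrodes <- function(session, labels) {
  stopifnot(inherits(session, "digitization_session"))
  labels <- as.character(labels)
  unknown <- setdiff(labels, names(session$electrodes))
  if (length(unknown))
    stop(sprintf("unknown electrode label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  session$rejected <- union(session$rejected, labels)
  session
}

#' Welch's two-sample t-test
#'
#' Unequal-variance two-tailed t-test with Welch-Satterthwaite degrees of
#' freedom, as used for comparing per-dataset RMSE distributions between
#' digitization conditions; no multiplicity correction.  When both groups
#' have zero variance and equal means the comparison is vacuous: t = 0,
#' p = 1, flagged `degenerate`.
#'
#' @param a,b numeric vectors (length >= 2, finite), e.g. RMSE per dataset.
#' @return Object of class `welch_test`: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
welch_ttest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(structure(list(t = 0, df = na + nb - 2, p = 1,
                            mean_a = mean(a), mean_b = mean(b),
                            degenerate = TRUE), class = "welch_test"))
    stop("welch_ttest: zero variance in both groups with unequal means",
         call. = FALSE)
  }
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(t = tstat, df = df, p = p, mean_a = mean(a),
                 mean_b = mean(b), degenerate = FALSE),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, two-tailed p = %.4g (means %.3f vs %.3f)\n",
              x$t, x$df, x$p, x$mean_a, x$mean_b))
  invisible(x)
}

#' Choose the reference dataset among repeated candidates
#'
#' The first candidate is the reference by default; if a later candidate has
#' strictly fewer rejected electrodes than the first, the later candidate
#' with the fewest rejections (earliest on ties) is used instead.
#'
#' @param rejection_counts integer vector of rejected-electrode counts, one
#'   per candidate in acquisition order; or a list of
#'   `digitization_session` objects.
#' @return The 1-based index of the chosen reference.
#' @export
reference_selection <- function(rejection_counts) {
  if (is.list(rejection_counts))
    rejection_counts <- vapply(rejection_counts,
                               function(s) length(s$rejected), numeric(1))
  n <- length(rejection_counts)
  if (n < 1L) stop("reference_selection: empty candidate list", call. = FALSE)
  if (n == 1L) return(1L)
  later <- rejection_counts[-1]
  if (any(later < rejection_counts[1]))
    return(1L + which.min(later))
  1L
}
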