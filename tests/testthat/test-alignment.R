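test_that("rigid_align recovers exact transforms and refuses degeneracy", {
  set.seed(61)
  pts <- matrix(stats::rnorm(30, 0, 60), 10, 3)
  expect_equal(as_matrix4(rigid_align(pts, pts)), diag(4), tolerance = 1e-9)
  # 30 deg about z plus translation (5,5,0): recovered to 1e-9
  R <- rotation_aa(c(0, 0, 1), 30 * pi / 180)
  moved <- sweep(pts %*% t(R), 2, c(5, 5, 0), "+")
  tr <- rigid_align(pts, moved)
  expect_equal(tr$R, R, tolerance = 1e-9)
  expect_equal(tr$t, c(5, 5, 0), tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(tr, pts) - moved)), 1e-9)
  # residual at the solution never exceeds the identity's residual
  set.seed(62)
  noisy <- moved + matrix(stats::rnorm(30, 0, 2), 10, 3)
  fit <- rigid_align(pts, noisy)
  expect_lte(sum((apply_transform(fit, pts) - noisy)^2),
             sum((pts - noisy)^2))
  # degenerate configurations
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(rigid_align(line, line), "collinear")
  expect_error(rigid_align(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("rigid_align matches the brute-force rotation-grid oracle", {
  set.seed(63)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    test <- matrix(stats::rnorm(3 * n, 0, 50), n, 3)
    tr_true <- random_rigid(30)
    ref <- apply_transform(tr_true, test) + matrix(stats::rnorm(3 * n, 0, 1.5),
                                                   n, 3)
    fit <- rigid_align(test, ref)
    resid_fit <- sum((apply_transform(fit, test) - ref)^2)
    resid_oracle <- brutforce_align_residual(test, ref)
    expect_lt(abs(sqrt(resid_fit / n) - sqrt(resid_oracle / n)), 1e-4)
    expect_lte(resid_fit, resid_oracle + 1e-6)
  }
})

test_that("evaluate_dataset computes errors over shared electrodes", {
  set.seed(64)
  cfg <- scenario_config(n_electrodes = 12, seed = 64)
  truth <- generate_layout(cfg)
  ref <- truth_session(truth)
  # identical sessions: all errors zero
  ev0 <- evaluate_dataset(ref, ref, mode = "electrodes")
  expect_equal(ev0$rmse, 0, tolerance = 1e-12)
  expect_equal(ev0$max_error, 0, tolerance = 1e-12)
  expect_equal(ev0$n_used, 12)
  # known 2-mm perturbations: rmse <= 2, per-label errors bounded
  pert <- electrode_positions(ref)
  dirs <- matrix(stats::rnorm(nrow(pert) * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  test <- make_session(pert + 2 * dirs, labels = rownames(pert),
                       fiducials = truth$fiducials)
  ev2 <- evaluate_dataset(test, ref, mode = "electrodes")
  expect_lte(ev2$rmse, 2 + 1e-9)
  expect_lte(ev2$max_error, 4)
  # transform invariance: rigidly moving the test session changes nothing
  tr <- random_rigid(80)
  moved <- make_session(apply_transform(tr, pert + 2 * dirs),
                        labels = rownames(pert))
  evm <- evaluate_dataset(moved, ref, mode = "electrodes")
  expect_equal(evm$rmse, ev2$rmse, tolerance = 1e-9)
  expect_equal(unname(evm$per_label_error), unname(ev2$per_label_error),
               tolerance = 1e-9)
})

test_that("electrode-mode RMSE never exceeds fiducial-mode RMSE", {
  set.seed(65)
  cfg <- scenario_config(n_electrodes = 10, seed = 65)
  truth <- generate_layout(cfg)
  ref <- truth_session(truth)
  pos <- electrode_positions(ref)
  for (i in 1:50) {
    noisy_el <- pos + matrix(stats::rnorm(length(pos), 0, 1.5),
                             nrow(pos), 3)
    noisy_fid <- lapply(truth$fiducials,
                        function(f) f + stats::rnorm(3, 0, 1.5))
    test <- make_session(noisy_el, labels = rownames(pos),
                         fiducials = noisy_fid)
    ev_el <- evaluate_dataset(test, ref, mode = "electrodes")
    ev_fid <- evaluate_dataset(test, ref, mode = "fiducials")
    expect_lte(ev_el$rmse, ev_fid$rmse + 1e-9)
  }
  # fiducial mode requires 3 shared fiducials
  no_fid <- make_session(pos, labels = rownames(pos))
  expect_error(evaluate_dataset(no_fid, ref, mode = "fiducials"))
})

test_that("electrode rejection excludes labels from evaluation", {
  cfg <- scenario_config(n_electrodes = 128, seed = 66)
  ref <- truth_session(generate_layout(cfg))
  expect_equal(nrow(electrode_positions(ref)), 128)
  r2 <- reject_electrodes(ref, c("A5", "C17"))
  expect_equal(nrow(electrode_positions(r2)), 126)
  expect_identical(reject_electrodes(ref, character(0))$rejected, character(0))
  expect_error(reject_electrodes(ref, "nasion"), "unknown electrode")
  ev <- evaluate_dataset(r2, ref, mode = "electrodes")
  expect_equal(ev$n_used, 126)
  expect_false("A5" %in% names(ev$per_label_error))
})

test_that("welch_ttest matches frozen textbook values", {
  # identical groups: vacuous comparison
  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  zero <- welch_ttest(c(2, 2), c(2, 2))
  expect_true(zero$degenerate)
  expect_equal(zero$p, 1)
  # frozen hand computation: a = 1:3, b = 2:4
  w <- welch_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.22474487139159, tolerance = 1e-10)
  expect_equal(w$df, 4, tolerance = 1e-10)
  expect_equal(w$p, 0.287864134726691, tolerance = 1e-10)
  # moment-matched phantom-scale groups: strongly significant
  base <- scale(1:5)[, 1]
  w2 <- welch_ttest(1.12 + 0.15 * base, 2.30 + 0.16 * base)
  expect_lt(w2$p, 0.001)
  expect_equal(w2$t, -12.0308, tolerance = 1e-4)
  expect_equal(w2$df, 7.9669, tolerance = 1e-4)
  expect_error(welch_ttest(1, c(1, 2)))
  expect_error(welch_ttest(c(1, 1), c(2, 2)), "zero variance")
})

test_that("reference selection prefers fewer rejections, else the first", {
  expect_equal(reference_selection(c(0, 0)), 1)
  expect_equal(reference_selection(c(2, 0)), 2)
  expect_equal(reference_selection(c(1)), 1)
  expect_equal(reference_selection(c(2, 1, 0)), 3)
  expect_equal(reference_selection(c(0, 1, 2)), 1)
  expect_error(reference_selection(numeric(0)), "empty")
  # list-of-sessions form
  cfg <- scenario_config(n_electrodes = 6, seed = 67)
  s1 <- truth_session(generate_layout(cfg))
  s2 <- s1
  s1 <- reject_electrodes(s1, c("E001", "E002"))
  expect_equal(reference_selection(list(s1, s2)), 2)
})
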