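test_that("endpoint timeseries applies the offset through each pose", {
  set.seed(31)
  # static stream: zero offset traces the controller origin
  trs <- replicate(10, rigid_transform(rotation_aa(c(0, 0, 1), 0.3),
                                       c(5, 6, 7)), simplify = FALSE)
  st <- pose_stream(seq(0, 0.9, by = 0.1), rep("controller", 10), trs)
  es0 <- endpoint_timeseries(st, "controller", c(0, 0, 0))
  expect_equal(max(abs(sweep(es0$pos, 2, c(5, 6, 7)))), 0)
  # 27-mm stub offset: constant point 27 mm from the origin trace
  es27 <- endpoint_timeseries(st, "controller", c(27, 0, 0))
  d <- sqrt(rowSums((es27$pos - es0$pos)^2))
  expect_equal(d, rep(27, 10), tolerance = 1e-12)
  # rotating about the tip: endpoint pinned while the origin moves
  xc <- c(27, 0, 0); tip <- c(80, -40, 120)
  rot <- lapply(seq(-60, 60, length.out = 9), function(a) {
    R <- rotation_aa(c(0, 1, 0), a * pi / 180)
    rigid_transform(R, tip - as.numeric(R %*% xc))
  })
  str <- pose_stream(seq_len(9) / 10, rep("controller", 9), rot)
  tipser <- endpoint_timeseries(str, "controller", xc)
  expect_lt(max(sqrt(rowSums(sweep(tipser$pos, 2, tip)^2))), 1e-9)
  origser <- endpoint_timeseries(str, "controller", c(0, 0, 0))
  expect_gt(max(dist(origser$pos)), 10)
  expect_error(endpoint_timeseries(st, "nope", xc), "unknown device")
})

test_that("stability gate accepts constant series and rejects steps", {
  tm <- seq(0, 2, by = 1 / 90)
  const <- make_series(tm)
  m <- sample_measurement(const, trig_time = 2)
  expect_true(m$valid)
  expect_equal(m$position, c(10, 20, 30))
  expect_equal(m$stability_mm, 0)
  expect_gte(m$window_n, 1)

  # 5-mm step 0.3 s before the trigger: deviation from the windowed mean is
  # max(1.5, 3.5) = 3.5 mm (0.3 of the 1-s window sits after the step)
  step <- make_series(tm, add = cbind(ifelse(tm >= 1.7, 5, 0), 0, 0))
  ms <- sample_measurement(step, trig_time = 2)
  expect_false(ms$valid)
  expect_gte(ms$stability_mm, 2.5)
  expect_equal(ms$stability_mm, 3.5, tolerance = 0.1)

  # bounded jitter of max amplitude 0.4 mm stays valid
  set.seed(32)
  jit <- matrix(runif(length(tm) * 3, -0.4, 0.4) / sqrt(3), ncol = 3)
  mj <- sample_measurement(make_series(tm, add = jit), trig_time = 2)
  expect_true(mj$valid)

  # window preconditions
  expect_error(sample_measurement(const, trig_time = 0.5), "insufficient")
  expect_error(sample_measurement(const, trig_time = 2, avg_window = 2,
                                  stab_window = 1), "avg_window")
  sparse <- make_series(c(0, 1.9, 2))
  expect_error(sample_measurement(sparse, trig_time = 2), "insufficient")
})

test_that("head compensation cancels rigid head motion", {
  set.seed(33)
  mount1 <- random_rigid(50); mount2 <- random_rigid(50)
  point_head <- c(0, 90, 60)   # fixed point on the head
  ref_poses <- list(t1 = mount1, t2 = mount2)
  # tracker at identity: tracker-relative equals global
  cid <- compensate_head(c(1, 2, 3), list(t1 = rt_identity()))
  expect_equal(cid$per_tracker$t1, c(1, 2, 3))
  expect_equal(cid$combined, c(1, 2, 3))
  # arbitrary head motion: head-frame coordinates invariant
  per_pose <- lapply(1:10, function(i) {
    H <- random_rigid(100)
    poses <- list(t1 = compose(H, mount1), t2 = compose(H, mount2))
    compensate_head(apply_transform(H, point_head), poses, ref_poses)
  })
  combined <- t(vapply(per_pose, `[[`, numeric(3), "combined"))
  expect_lt(max(dist(combined)), 1e-9)
  # the two trackers reconstruct the same physical point
  for (cp in per_pose) {
    p1 <- apply_transform(mount1, cp$per_tracker$t1)
    p2 <- apply_transform(mount2, cp$per_tracker$t2)
    expect_equal(p1, p2, tolerance = 1e-9)
  }
  # 10-mm head translation between two samples of a head-fixed point
  H2 <- rigid_transform(diag(3), c(10, 0, 0))
  g1 <- point_head
  g2 <- apply_transform(H2, point_head)
  c1 <- compensate_head(g1, list(t1 = mount1, t2 = mount2), ref_poses)
  c2 <- compensate_head(g2, list(t1 = compose(H2, mount1),
                                 t2 = compose(H2, mount2)), ref_poses)
  expect_equal(sqrt(sum((g2 - g1)^2)), 10, tolerance = 1e-12)
  expect_lt(max(abs(c1$combined - c2$combined)), 1e-9)
})

test_that("tracker mismatch detection flags slips above threshold", {
  cfg <- scenario_config(n_electrodes = 6, head_drift_mm = 12,
                         head_rot_deg = 5, seed = 41,
                         slip = list(tracker = 2, time_s = 8,
                                     offset_mm = c(5, 0, 0)))
  truth <- generate_layout(cfg)
  sim <- simulate_session(truth, cfg)
  rep5 <- detect_tracker_mismatch(sim$stream, c("tracker1", "tracker2"),
                                  threshold_mm = 3)
  expect_true(rep5$applicable)
  expect_true(rep5$flagged)
  expect_equal(rep5$first_time, 8, tolerance = 0.1)
  expect_equal(rep5$magnitude, 5, tolerance = 1)
  # co-moving trackers through the same head motion: no mismatch
  cfg0 <- scenario_config(n_electrodes = 6, head_drift_mm = 12,
                          head_rot_deg = 5, seed = 41)
  rep0 <- detect_tracker_mismatch(simulate_session(generate_layout(cfg0),
                                                   cfg0)$stream,
                                  c("tracker1", "tracker2"), threshold_mm = 3)
  expect_false(rep0$flagged)
  expect_lt(max(rep0$mismatch_mm), 1e-9)
  # 1-mm slip stays under the 3-mm threshold
  cfg1 <- scenario_config(n_electrodes = 6, seed = 41,
                          slip = list(tracker = 2, time_s = 8,
                                      offset_mm = c(1, 0, 0)))
  rep1 <- detect_tracker_mismatch(simulate_session(generate_layout(cfg1),
                                                   cfg1)$stream,
                                  c("tracker1", "tracker2"), threshold_mm = 3)
  expect_false(rep1$flagged)
  # single-tracker session: not applicable, no error
  expect_false(detect_tracker_mismatch(sim$stream, "tracker1")$applicable)
})

test_that("gate-invalid electrodes are excluded from use but recorded", {
  cfg <- scenario_config(n_electrodes = 6, transient_mm = 8,
                         transient_decay_s = 0.8, dwell_s = 1.2, seed = 42)
  truth <- generate_layout(cfg)
  sim <- simulate_session(truth, cfg)
  ses <- replay_digitize(sim$stream, montage(rownames(truth$electrodes)),
                         cfg$endpoint_truth)
  # strong slow transient breaks the 1-mm gate for every dwell
  expect_equal(nrow(electrode_positions(ses)), 0)
  expect_equal(length(ses$electrodes), 6)
  expect_true(all(!vapply(ses$electrodes, `[[`, logical(1), "valid")))
  expect_equal(nrow(electrode_positions(ses, include_rejected = TRUE)), 6)
})
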