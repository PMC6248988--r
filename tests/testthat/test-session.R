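test_that("montage files parse across sfp/elc/csv dialects", {
  dir <- withr::local_tempdir()
  # sfp with 3 fiducials + 2 electrodes
  sfp <- file.path(dir, "cap.sfp")
  writeLines(c("fidnz\t0.0\t95.0\t-20.0",
               "fidt9\t-80.0\t0.0\t-20.0",
               "fidt10\t80.0\t0.0\t-20.0",
               "E1\t10.0\t20.0\t80.0",
               "E2\t-10.0\t20.0\t80.0"), sfp)
  m <- read_montage(sfp)
  expect_equal(m$montage$labels, c("E1", "E2"))
  expect_equal(sort(names(m$fiducials)), c("lpa", "nasion", "rpa"))
  expect_equal(m$fiducials$nasion, c(0, 95, -20))
  expect_equal(m$montage$template["E1", ], c(x = 10, y = 20, z = 80),
               ignore_attr = TRUE)

  # 128-label BioSemi csv in order, label-only rows (no template)
  csvp <- file.path(dir, "biosemi.csv")
  writeLines(c("label", biosemi_labels(128)), csvp)
  mb <- read_montage(csvp)
  expect_equal(length(mb$montage$labels), 128)
  expect_equal(mb$montage$labels[c(1, 2, 128)], c("A1", "A2", "D32"))
  expect_null(mb$montage$template)

  # elc with cm units is converted to mm
  elc <- file.path(dir, "cap.elc")
  writeLines(c("NumberPositions= 2", "UnitPosition cm", "Positions",
               "1.0 2.0 8.0", "-1.0 2.0 8.0", "Labels", "E1 E2"), elc)
  me <- read_montage(elc)
  expect_equal(me$montage$template["E1", ], c(x = 10, y = 20, z = 80),
               ignore_attr = TRUE)

  # failure modes: empty file, duplicate labels, malformed line numbers
  empty <- file.path(dir, "empty.sfp"); file.create(empty)
  expect_error(read_montage(empty), "empty")
  dup <- file.path(dir, "dup.csv")
  writeLines(c("E1,0,0,1", "E1,0,0,2"), dup)
  expect_error(read_montage(dup), "duplicate")
  bad <- file.path(dir, "bad.sfp")
  writeLines(c("E1 0 0 1", "E2 zero 0 1"), bad)
  expect_error(read_montage(bad), "line 2")
})

test_that("fiducial aggregation averages repeats and reports spread", {
  one <- aggregate_fiducials(list(nasion = c(1, 2, 3)))
  expect_equal(one$nasion$aggregate, c(1, 2, 3))
  expect_equal(one$nasion$spread_mm, 0)
  two <- aggregate_fiducials(list(nasion = rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(two$nasion$aggregate, c(1, 0, 0))
  expect_equal(two$nasion$spread_mm, 2)
  expect_false(two$nasion$flagged)
  tri <- aggregate_fiducials(list(lpa = rbind(c(0, 0, 0), c(1, 0, 0),
                                              c(2, 0, 0))))
  expect_equal(tri$lpa$spread_mm, 2)
  wide <- aggregate_fiducials(list(rpa = rbind(c(0, 0, 0), c(4, 0, 0))))
  expect_true(wide$rpa$flagged)
})

test_that("next_target walks fiducials then montage order", {
  s <- digitization_session(montage(c("A1", "A2", "A3")))
  expect_equal(next_target(s), "nasion")
  for (nm in c("nasion", "lpa", "rpa"))
    s$fiducial_repeats[[nm]] <- matrix(0, 1, 3)
  expect_equal(next_target(s), "A1")
  s$electrodes[["A1"]] <- list(position = c(0, 0, 0), valid = TRUE)
  expect_equal(next_target(s), "A2")
  s$electrodes[["A2"]] <- list(position = c(0, 0, 0), valid = TRUE)
  s$electrodes[["A3"]] <- list(position = c(0, 0, 0), valid = TRUE)
  expect_equal(next_target(s), "done")
  # repeated-fiducial protocol: nasion pending until enough repeats
  expect_equal(next_target(s, fiducial_repeats = 2), "nasion")
})

test_that("headshape re-fiducials append without altering aggregates", {
  s <- digitization_session(montage(c("A1")))
  s$fiducial_repeats$nasion <- rbind(c(0, 0, 0), c(2, 0, 0))
  s$fiducial_repeats$lpa <- matrix(c(-80, 0, 0), 1)
  s$fiducial_repeats$rpa <- matrix(c(80, 0, 0), 1)
  agg_before <- session_fiducials(s)$nasion$aggregate
  s2 <- add_headshape_refiducials(s, list(nasion = rbind(c(1, 0.5, 0),
                                                         c(1, -0.5, 0))))
  expect_length(s2$headshape, 2)
  expect_equal(vapply(s2$headshape, `[[`, character(1), "tag"),
               c("nasion", "nasion"))
  expect_equal(session_fiducials(s2)$nasion$aggregate, agg_before)
  expect_identical(add_headshape_refiducials(s, list())$headshape, list())
  # displaced re-measurement raises a consistency warning
  expect_warning(add_headshape_refiducials(s, list(nasion = c(5, 0, 0))),
                 "from its aggregate")
  expect_error(add_headshape_refiducials(s, list(inion = c(0, -90, 0))),
               "never measured")
})

test_that("sessions round-trip through JSON exactly", {
  set.seed(51)
  cfg <- scenario_config(n_electrodes = 8, fiducial_repeats = 2, seed = 51)
  truth <- generate_layout(cfg)
  sim <- simulate_session(truth, cfg)
  s <- replay_digitize(sim$stream, montage(rownames(truth$electrodes)),
                       cfg$endpoint_truth, tracker_ids = names(truth$mounts),
                       fiducial_repeats = 2)
  s <- reject_electrodes(s, "E003")
  path <- withr::local_tempfile(fileext = ".json")
  save_session(s, path)
  b <- load_session(path)
  expect_identical(b$montage$labels, s$montage$labels)
  expect_identical(b$rejected, s$rejected)
  expect_identical(b$complete, s$complete)
  for (lab in names(s$electrodes)) {
    expect_lt(max(abs(b$electrodes[[lab]]$position -
                        s$electrodes[[lab]]$position)), 1e-12)
    expect_identical(b$electrodes[[lab]]$valid, s$electrodes[[lab]]$valid)
  }
  for (nm in names(s$fiducial_repeats))
    expect_lt(max(abs(b$fiducial_repeats[[nm]] - s$fiducial_repeats[[nm]])),
              1e-12)
  # montage order survives an sfp export/import cycle
  sfp <- withr::local_tempfile(fileext = ".sfp")
  export_sfp(s, sfp)
  m2 <- read_montage(sfp)
  expect_identical(m2$montage$labels,
                   setdiff(rownames(electrode_positions(s)), character(0)))
  csvp <- withr::local_tempfile(fileext = ".csv")
  export_electrodes_csv(s, csvp)
  expect_false("E003" %in% read.csv(csvp)$label)
})

test_that("mesh readers parse OFF and STL and validate bounding boxes", {
  dir <- withr::local_tempdir()
  off <- file.path(dir, "tet.off")
  writeLines(c("OFF", "4 4 0",
               "0 0 0", "100 0 0", "0 100 0", "0 0 100",
               "3 0 1 2", "3 0 1 3", "3 0 2 3", "3 1 2 3"), off)
  m <- read_mesh(off)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 4)
  expect_equal(m$bbox["max", ], c(100, 100, 100), ignore_attr = TRUE)
  stl <- file.path(dir, "tri.stl")
  writeLines(c("solid tri", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 50 0 5", "vertex 0 50 5",
               "endloop", "endfacet", "endsolid tri"), stl)
  ms <- read_mesh(stl)
  expect_equal(nrow(ms$vertices), 3)
  expect_error(read_mesh(file.path(dir, "missing.off")), "not found")
  flat <- file.path(dir, "flat.off")
  writeLines(c("OFF", "3 1 0", "0 0 0", "1 0 0", "2 0 0", "3 0 1 2"), flat)
  expect_error(read_mesh(flat), "bounding box")
})
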