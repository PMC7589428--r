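test_that("translation registration recovers known integer shifts", {
  set.seed(3)
  a <- array(stats::runif(15^3), rep(15, 3))
  ref <- ImageVolume(a, 1, "counts")
  expect_identical(as.integer(registerTranslation(ref, ref, 2)),
                   c(0L, 0L, 0L))
  for (applied in list(c(2L, -1L, 3L), c(-2L, 0L, 1L))) {
    moving <- ImageVolume(shiftArray(a, applied), 1, "counts")
    sh <- registerTranslation(moving, ref, 3)
    expect_identical(as.integer(sh), as.integer(-applied))
    # applying the returned shift aligns moving to the reference
    aligned <- applyShift(moving, sh)
    inner <- voxelData(aligned)[4:12, 4:12, 4:12]
    expect_equal(inner, a[4:12, 4:12, 4:12], tolerance = 1e-15)
  }
})

test_that("degenerate constant volumes register to zero with a warning", {
  flat <- ImageVolume(array(5, rep(8, 3)), 1, "counts")
  expect_warning(sh <- registerTranslation(flat, flat, 2), "degenerate")
  expect_identical(as.integer(sh), c(0L, 0L, 0L))
  expect_true(attr(sh, "degenerate"))
})

test_that("VOI activity matches hand arithmetic and is additive", {
  # 500-voxel VOI with 100 counts per voxel at 38.3e-6 MBq/count
  lab <- array(0L, c(10, 10, 10)); lab[1:5, , ] <- 1L
  cnt <- array(0, c(10, 10, 10)); cnt[1:5, , ] <- 100
  labels <- LabelMap(lab, 4.42, data.frame(label = 1L, organ = "voi",
                                           density_gcc = 1.0))
  acq <- patientProtocol()
  cf <- CalibrationFactor(38.3e-6, "MBq_per_count", acq)
  s <- voiActivity(ImageVolume(cnt, 4.42, "counts", 24), labels, cf, acq)
  expect_equal(s$activity_MBq, 50000 * 38.3e-6, tolerance = 1e-12)
  expect_identical(s$voxels, 500L)

  # split VOI halves sum to the whole
  lab2 <- lab; lab2[1:2, , ] <- 2L
  labels2 <- LabelMap(lab2, 4.42,
                      data.frame(label = c(1L, 2L), organ = c("a", "b"),
                                 density_gcc = 1.0))
  s2 <- voiActivity(ImageVolume(cnt, 4.42, "counts", 24), labels2, cf, acq)
  expect_equal(sum(s2$activity_MBq), s$activity_MBq, tolerance = 1e-15)

  # all-zero counts give zero activity
  s0 <- voiActivity(ImageVolume(array(0, dim(lab)), 4.42, "counts", 4),
                    labels, cf, acq)
  expect_identical(s0$activity_MBq, 0)
})

test_that("activity is invariant to the calibration factor's unit kind", {
  spec <- smallPhantom()
  sim <- simulateTimepoints(spec)
  acq <- spec@acq
  base <- CalibrationFactor(spec@sensitivity, "cps_per_MBq", acq)
  acts <- sapply(c("cps_per_MBq", "MBq_per_count", "Bq_per_count",
                   "Bq_per_intensity"), function(kind) {
    cf <- convertCalibration(base, kind)
    voiActivity(sim$volumes[[1]], sim$labels, cf, acq)$activity_MBq
  })
  for (j in 2:ncol(acts))
    expect_lt(max(relErr(acts[, j], acts[, 1])), 1e-12)
})

test_that("quantification round-trips the noiseless phantom to 1e-12", {
  spec <- smallPhantom()
  sim <- simulateTimepoints(spec)
  cf <- CalibrationFactor(spec@sensitivity, "cps_per_MBq", spec@acq)
  for (i in seq_along(spec@times)) {
    s <- voiActivity(sim$volumes[[i]], sim$labels, cf, spec@acq)
    expect_lt(max(relErr(s$activity_MBq,
                         sim$truth@activities[s$organ, i])), 1e-12)
  }
})

test_that("organ mass follows voxel count x volume x density", {
  lab <- array(0L, c(12, 12, 12)); lab[2:11, 2:11, 2:11] <- 1L
  mk <- function(rho) LabelMap(lab, 4.42, data.frame(
    label = 1L, organ = "o", density_gcc = rho))
  expect_equal(organMass(mk(1.05), 1L), 1000 * 4.42^3 / 1e3 * 1.05,
               tolerance = 1e-12)
  expect_equal(organMass(mk(1.06), "o") / organMass(mk(1.05), "o"),
               1.06 / 1.05, tolerance = 1e-12)
  empty <- LabelMap(array(0L, c(4, 4, 4)), 4.42, data.frame(
    label = 1L, organ = "o", density_gcc = 1.05))
  expect_identical(organMass(empty, 1L), 0)
  expect_error(organMass(mk(1.05), 7L), "unknown")
})

test_that("masses stay constant across rigidly propagated time points", {
  sh <- matrix(c(0L, 0L, 0L, 2L, -1L, 1L, -1L, 2L, 0L, 1L, 1L, -2L),
               4, 3, byrow = TRUE)
  spec <- smallPhantom(shifts = sh)
  sim <- simulateTimepoints(spec)
  cf <- CalibrationFactor(spec@sensitivity, "cps_per_MBq", spec@acq)
  ref <- sim$volumes[[1]]
  masses <- sapply(seq_along(sim$volumes), function(i) {
    v <- applyShift(sim$volumes[[i]],
                    registerTranslation(sim$volumes[[i]], ref, 3))
    voiActivity(v, sim$labels, cf, spec@acq)$mass_g
  })
  for (j in 2:ncol(masses)) expect_identical(masses[, j], masses[, 1])
})

test_that("TAC assembly sorts, validates and carries A0", {
  s <- data.frame(organ = "k", time_h = c(72, 4, 192, 24),
                  activity_MBq = c(40, 90, 10, 70))
  tac <- buildTac(s, 7200)$k
  expect_identical(tac@times, c(4, 24, 72, 192))
  expect_identical(tac@activities, c(90, 70, 40, 10))
  expect_identical(tac@A0, 7200)
  expect_length(buildTac(data.frame(organ = "k", time_h = 4,
                                    activity_MBq = 1), 7200)$k@times, 1L)
  dup <- data.frame(organ = "k", time_h = c(4, 4), activity_MBq = c(1, 2))
  expect_error(buildTac(dup, 7200), "duplicate")
})

test_that("volumes survive a NIfTI round trip", {
  v <- ImageVolume(array(stats::rpois(6 * 5 * 4, 20), c(6, 5, 4)), 4.42,
                   "counts", 24)
  p <- tempfile(fileext = ".nii.gz")
  writeVolume(v, p)
  back <- readVolume(p, "counts", 24)
  expect_equal(voxelData(back), voxelData(v) + 0, tolerance = 0)
  expect_equal(voxelSpacing(back), voxelSpacing(v), tolerance = 1e-6)
  unlink(p)
})
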