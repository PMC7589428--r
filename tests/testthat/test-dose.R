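test_that("S-value dose follows the MIRD sum with self-dose mass adjustment", {
  tbl <- SValueTable("toy", data.frame(source = "kidney", target = "kidney",
                                       S_Gy_per_MBqh = 1e-5),
                     refMass = c(kidney = 150))
  # toy worked example: TIAC 2 h, A0 7000 MBq, matched masses -> 0.14 Gy
  r <- svalueDose(c(kidney = 2), 7000, tbl, c(kidney = 150))
  expect_equal(reportTable(r)$mean_dose_Gy, 0.14, tolerance = 1e-12)
  # doubling the patient mass halves the self-dose
  r2 <- svalueDose(c(kidney = 2), 7000, tbl, c(kidney = 300))
  expect_equal(reportTable(r2)$mean_dose_Gy, 0.07, tolerance = 1e-12)
  # zero TIACs give zero dose
  r0 <- svalueDose(c(kidney = 0), 7000, tbl, c(kidney = 150))
  expect_identical(reportTable(r0)$mean_dose_Gy, 0)
  # linearity in TIAC and A0
  set.seed(2)
  for (i in 1:5) {
    k <- stats::runif(1, 0.5, 4); a <- stats::runif(1, 1000, 9000)
    base <- reportTable(svalueDose(c(kidney = 1), 1000, tbl,
                                   c(kidney = 150)))$mean_dose_Gy
    expect_lt(relErr(reportTable(svalueDose(c(kidney = k), a, tbl,
                                            c(kidney = 150)))$mean_dose_Gy,
                     base * k * a / 1000), 1e-12)
  }
  # missing pair is an explicit lookup error naming the organs
  tbl2 <- SValueTable("toy", data.frame(source = "kidney", target = "kidney",
                                        S_Gy_per_MBqh = 1e-5),
                      refMass = c(kidney = 150, liver = 1800))
  expect_error(svalueDose(c(liver = 1, kidney = 1), 7000, tbl2,
                          c(kidney = 150)),
               "source 'liver'")
})

test_that("cross-organ terms accumulate and respect the scaling option", {
  ent <- expand.grid(source = c("a", "b"), target = c("a", "b"),
                     stringsAsFactors = FALSE)
  ent$S_Gy_per_MBqh <- c(1e-5, 2e-6, 2e-6, 1e-5)
  tbl <- SValueTable("toy", ent, refMass = c(a = 100, b = 100))
  r <- reportTable(svalueDose(c(a = 1, b = 1), 1000, tbl,
                              c(a = 200, b = 100)))
  # target a: self 1000*1e-5*(100/200) + cross from b 1000*2e-6
  expect_equal(r$mean_dose_Gy[r$organ == "a"], 5e-3 + 2e-3,
               tolerance = 1e-12)
  rInv <- reportTable(svalueDose(c(a = 1, b = 1), 1000, tbl,
                                 c(a = 200, b = 100),
                                 crossMassScaling = "inverse"))
  expect_equal(rInv$mean_dose_Gy[rInv$organ == "a"], 5e-3 + 1e-3,
               tolerance = 1e-12)
})

test_that("local energy deposition matches hand arithmetic", {
  arr <- array(0, c(5, 5, 5)); arr[3, 3, 3] <- 1  # 1 MBq h
  tiaMap <- ImageVolume(arr, 4.42, "tia")
  dens <- ImageVolume(array(1, c(5, 5, 5)), 4.42, "density")
  d <- ledDose(tiaMap, dens, toyNuclide(1e-12))
  # 3.6e9 decays * 1e-12 J / (4.42 mm)^3 of water
  expect_equal(max(voxelData(d)), 3.6e-3 / (4.42^3 / 1e3 * 1e-3),
               tolerance = 1e-12)
  expect_equal(max(voxelData(d)), 41.69, tolerance = 1e-4)
  # zero TIA gives zero dose; doubling density halves dose
  z <- ledDose(ImageVolume(array(0, c(5, 5, 5)), 4.42, "tia"), dens,
               toyNuclide(1e-12))
  expect_true(all(voxelData(z) == 0))
  dens2 <- ImageVolume(array(2, c(5, 5, 5)), 4.42, "density")
  d2 <- ledDose(tiaMap, dens2, toyNuclide(1e-12))
  expect_equal(voxelData(d2), voxelData(d) / 2, tolerance = 1e-15)
  # zero density under activity is an error naming the voxel
  dens0 <- dens; dens0@voxels[3, 3, 3] <- 0
  expect_error(ledDose(tiaMap, dens0, toyNuclide(1e-12)), "density")
})

test_that("radius-0 kernel is the pure LED kernel and symmetric kernels
           are symmetric", {
  nuc <- toyNuclide(5e-13)
  k0 <- buildWaterKernel(nuc, 4.42, radius = 0)
  expect_identical(dim(k0@values), c(1L, 1L, 1L))
  expect_equal(k0@values[1], 3.6e9 * 5e-13 / (4.42^3 / 1e3 * 1e-3),
               tolerance = 1e-12)
  k <- buildWaterKernel(nuc, 4.42, radius = 3)
  v <- k@values
  expect_equal(v, aperm(v, c(2, 1, 3)), tolerance = 1e-12)
  expect_equal(v, aperm(v, c(3, 2, 1)), tolerance = 1e-12)
  expect_equal(v, v[7:1, , ], tolerance = 1e-12)
  # central voxel dominates
  expect_identical(which.max(v), which(array(seq_along(v), dim(v)) ==
                                         ((length(v) + 1) / 2)))
})

test_that("kernel energy accounting: coverage guard and exact total", {
  nuc <- toyNuclide(1e-12)
  k <- buildWaterKernel(nuc, 4.42, radius = 5)
  # raw coverage of the truncated grid within 0.5% of all space
  expect_gt(k@energyFraction, 0.995)
  expect_lte(k@energyFraction, 1 + 1e-6)
  # after renormalisation the kernel deposits exactly E_local per MBq h:
  # direct summation oracle of kernel x voxel water mass
  voxmass <- 4.42^3 / 1e3 * 1e-3
  expect_lt(relErr(sum(k@values) * voxmass, 3.6e9 * 1e-12), 1e-12)
  # a profile too wide for the radius fails the truncation guard
  expect_error(buildWaterKernel(nuc, 4.42, radius = 1, scale_mm = 3),
               "radius")
})

test_that("DVK convolution translates a point source by the kernel", {
  nuc <- toyNuclide(1e-12)
  k <- buildWaterKernel(nuc, 4.42, radius = 2)
  arr <- array(0, c(15, 15, 15)); arr[8, 6, 9] <- 3.5
  d <- dvkDose(ImageVolume(arr, 4.42, "tia"), k)
  expect_equal(voxelData(d)[6:10, 4:8, 7:11], 3.5 * k@values,
               tolerance = 1e-9)
})

test_that("DVK conserves energy over the padded field to 1e-6", {
  nuc <- toyNuclide(1e-12)
  k <- buildWaterKernel(nuc, 4.42, radius = 3)
  set.seed(9)
  arr <- array(0, c(24, 24, 24))
  arr[9:16, 9:16, 9:16] <- stats::runif(512, 0, 5)  # interior sources
  d <- dvkDose(ImageVolume(arr, 4.42, "tia"), k)
  voxmass <- 4.42^3 / 1e3 * 1e-3
  lhs <- sum(voxelData(d)) * voxmass
  rhs <- sum(arr) * sum(k@values) * voxmass
  expect_lt(relErr(lhs, rhs), 1e-6)
})

test_that("radius-0 DVK equals LED bit-for-bit in water", {
  nuc <- toyNuclide(2e-13)
  set.seed(4)
  arr <- array(stats::runif(10^3, 0, 2), rep(10, 3))
  tiaMap <- ImageVolume(arr, 4.42, "tia")
  dens <- ImageVolume(array(1.0, rep(10, 3)), 4.42, "density")
  a <- dvkDose(tiaMap, buildWaterKernel(nuc, 4.42, radius = 0))
  b <- ledDose(tiaMap, dens, nuc)
  expect_identical(voxelData(a), voxelData(b))
})

test_that("DVK density correction and spacing guard behave", {
  nuc <- toyNuclide(1e-12)
  k <- buildWaterKernel(nuc, 4.42, radius = 2)
  arr <- array(1, rep(9, 3))
  tiaMap <- ImageVolume(arr, 4.42, "tia")
  dens <- ImageVolume(array(2, rep(9, 3)), 4.42, "density")
  plain <- dvkDose(tiaMap, k)
  corr <- dvkDose(tiaMap, k, density = dens)
  expect_equal(voxelData(corr), voxelData(plain) / 2, tolerance = 1e-15)
  wrong <- ImageVolume(arr, 4.0, "tia")
  expect_error(dvkDose(wrong, k), "spacing")
})

test_that("DVK and LED mean doses agree within 2% on a large uniform organ", {
  nuc <- defaultLu177()
  spec <- blobPhantom(n = 48L, semiVox = 11)   # 22 voxels across
  sim <- simulateTimepoints(spec)
  tiaMap <- tiaMapFromFits(list(fixedTiaFit("blob",
                                            sim$truth@organs$tia_MBqh)),
                           sim$labels)
  led <- ledDose(tiaMap, sim$density, nuc)
  k <- buildWaterKernel(nuc, 4.42, radius = 3)
  dv <- dvkDose(tiaMap, k, density = sim$density)
  mled <- dvh(led, sim$labels, "blob")$mean_Gy
  mdvk <- dvh(dv, sim$labels, "blob")$mean_Gy
  expect_lt(relErr(mdvk, mled), 0.02)
})

test_that("DVH is a monotone cumulative histogram with the map mean", {
  lab <- array(0L, c(4, 4, 4)); lab[1:2, 1, 1] <- 1L
  labels <- LabelMap(lab, 4.42, data.frame(label = 1L, organ = "o",
                                           density_gcc = 1))
  dmap <- array(0, c(4, 4, 4)); dmap[1, 1, 1] <- 1; dmap[2, 1, 1] <- 3
  h <- dvh(ImageVolume(dmap, 4.42, "dose"), labels, "o")
  expect_equal(h$mean_Gy, 2, tolerance = 1e-15)
  expect_equal(h$fraction[1], 1)  # everything gets at least 0 Gy
  expect_equal(h$fraction[which(h$dose_Gy >= 1 & h$dose_Gy < 1.01)][1], 1)
  expect_equal(h$fraction[which.min(abs(h$dose_Gy - 3))], 0.5,
               tolerance = 1e-12)
  expect_true(all(diff(h$fraction) <= 0))
  # uniform VOI: step at the uniform dose
  dmap2 <- array(2, c(4, 4, 4))
  h2 <- dvh(ImageVolume(dmap2, 4.42, "dose"), labels, "o")
  expect_equal(h2$mean_Gy, 2, tolerance = 1e-15)
  expect_true(all(h2$fraction[h2$dose_Gy <= 2] == 1))
  expect_true(all(h2$fraction[h2$dose_Gy > 2] == 0))
  # random maps stay monotone
  set.seed(12)
  for (i in 1:5) {
    dm <- ImageVolume(array(stats::rexp(64, 1), c(4, 4, 4)), 4.42, "dose")
    expect_true(all(diff(dvh(dm, labels, "o")$fraction) <= 1e-15))
  }
  empty <- LabelMap(array(0L, c(4, 4, 4)), 4.42,
                    data.frame(label = 2L, organ = "x", density_gcc = 1))
  expect_error(dvh(ImageVolume(dmap, 4.42, "dose"), empty, "x"), "empty")
})

test_that("voxel-wise trapezoid TIA map matches the per-voxel closed form", {
  t <- c(4, 24, 72, 192)
  lam <- log(2) / 159.53
  set.seed(21)
  base <- array(stats::runif(4^3, 1, 5), rep(4, 3))
  maps <- lapply(seq_along(t), function(i)
    ImageVolume(base * exp(-0.02 * t[i]), 4.42, "activity", time = t[i]))
  tm <- tiaMapVoxelTrapezoid(maps, "zero_line", lam)
  # oracle: integrateTrapezoidTail voxel by voxel on a sample of voxels
  idx <- cbind(c(1, 3, 4), c(2, 2, 4), c(1, 4, 2))
  for (r in seq_len(nrow(idx))) {
    a <- vapply(maps, function(m) voxelData(m)[idx[r, 1], idx[r, 2],
                                               idx[r, 3]], 0)
    f <- integrateTrapezoidTail(TimeActivityCurve("v", t, a, 1), "zero_line",
                                lam)
    expect_lt(relErr(voxelData(tm)[idx[r, 1], idx[r, 2], idx[r, 3]], tia(f)),
              1e-12)
  }
})
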