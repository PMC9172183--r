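test_that("noise-free vial phantom realizes exact relative signal levels", {
  ph <- generateVialPhantom(noiseSD = 0, s0 = 100)
  dat <- volData(ph$volume)
  lay <- ph$layout
  sr <- lungwater:::.vialSliceRange(lay)
  central <- (sr[1] + sr[2]) %/% 2
  rv <- lay@radiusMM / spacing(ph$volume)[2]
  v40 <- which(lay@concentration == 40)
  disc <- outer((seq_len(80) - lay@centers[v40, 1])^2,
                (seq_len(80) - lay@centers[v40, 2])^2, "+") <= (rv * 0.8)^2
  expect_equal(mean(dat[central, , ][disc]), 0.4 * 100)
})

test_that("vial phantom is seed-reproducible with seed-independent geometry", {
  a <- generateVialPhantom(noiseSD = 0.02, seed = 1)
  a2 <- generateVialPhantom(noiseSD = 0.02, seed = 1)
  b <- generateVialPhantom(noiseSD = 0.02, seed = 2)
  expect_identical(volData(a$volume), volData(a2$volume))
  expect_false(identical(volData(a$volume), volData(b$volume)))
  expect_identical(a$layout, b$layout)
  expect_error(generateVialPhantom(noiseSD = -0.1), "nonnegative")
})

test_that("coil shading field honors offset, monotonicity and symmetry", {
  d <- c(10L, 12L, 14L)
  expect_equal(coilShadingField(d, 3.5, list(offset = 2)),
               array(2, dim = d))
  expect_error(coilShadingField(d, 3.5, list(offset = 0)), "positive")
  # single posterior Gaussian: decreasing toward anterior along the axis
  f <- coilShadingField(c(20L, 8L, 8L), 3.5,
                        list(offset = 1, gaussians = list(list(
                          center = c(70, 12, 12), sigma = c(20, 50, 50),
                          amplitude = 0.5))))
  prof <- f[, 4, 4]
  expect_true(all(diff(prof) > 0))   # rises anterior -> posterior
  # symmetric parameters give mirror-symmetric values
  g <- coilShadingField(c(9L, 9L, 9L), 1,
                        list(offset = 1, gaussians = list(list(
                          center = c(4, 4, 4), sigma = c(2, 2, 2),
                          amplitude = 1))))
  expect_equal(g[2, 5, 5], g[8, 5, 5])
  expect_equal(g[5, 1, 5], g[5, 9, 5])
  # dynamic range cap
  h <- coilShadingField(c(16L, 16L, 16L), 3.5,
                        list(offset = 0.2, cap = 3,
                             gaussians = list(list(center = c(0, 0, 0),
                                                   sigma = c(10, 10, 10),
                                                   amplitude = 50))))
  expect_lte(max(h) / min(h), 3 + 1e-8)
  expect_gt(min(h), 0)
})

test_that("thorax phantom realizes the regional gradient and label geometry", {
  ph <- smallThorax(noiseSD = 0)
  a <- ph$truth@achieved
  # anterior third of the noise-free field matches the target within the
  # piecewise-linear discretization error
  expect_lt(abs(a$anterior - 21.2), 0.5)
  expect_true(a$posterior > a$mid && a$mid > a$anterior)
  # prone flag reverses the gravity gradient
  pr <- smallThorax(noiseSD = 0, posture = "prone")
  expect_true(pr$truth@achieved$anterior > pr$truth@achieved$posterior)
  # liver sits directly under the right lung: above every liver column top
  # voxel is a right-lung voxel
  lab <- volData(ph$labels)
  ok <- TRUE
  for (s in seq_len(dim(lab)[1])) for (cc in seq_len(dim(lab)[3])) {
    rows <- which(lab[s, , cc] == 4L)
    if (length(rows)) ok <- ok && lab[s, min(rows) - 1L, cc] == 2L
  }
  expect_true(ok)
  # noise-free homogeneous region: mean signal = C * WD/100 * s0
  tru <- ph$truth
  C <- coilShadingField(tru@dim, tru@spacing, tru@coil)
  liver <- lab == 4L
  expect_equal(mean(volData(ph$volume)[liver]),
               mean(C[liver]) * tru@liverWD / 100 * tru@s0, tolerance = 1e-9)
})

test_that("multiplicative shading acts voxel-wise on the noise-free phantom", {
  base <- generateThoraxPhantom(thoraxTruth(dim = c(32L, 48L, 48L),
                                            noiseSD = 0, coil = NULL))
  coil <- list(offset = 1, gaussians = list(list(center = c(60, 60, 60),
                                                 sigma = c(80, 80, 80),
                                                 amplitude = 0.5)))
  shaded <- generateThoraxPhantom(thoraxTruth(dim = c(32L, 48L, 48L),
                                              noiseSD = 0, coil = coil))
  C <- coilShadingField(c(32L, 48L, 48L), 3.5, coil)
  nz <- volData(base$volume) > 0
  expect_equal(volData(shaded$volume)[nz] / volData(base$volume)[nz],
               C[nz], tolerance = 1e-12)
})

test_that("segmentation training set is reproducible and contains both kinds of slices", {
  a <- generateSegmentationTrainingSet(20, seed = 5)
  b <- generateSegmentationTrainingSet(20, seed = 5)
  expect_identical(a$images, b$images)
  nLung <- apply(a$masks, 3, sum)
  expect_true(any(nLung == 0) && any(nLung > 0))
  expect_true(all(a$masks %in% c(0, 1)))
})
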