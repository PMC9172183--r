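test_that("body mask covers body and liver and excludes lungs", {
  ph <- smallThorax(noiseSD = 0)
  tru <- truthSegmentation(ph$labels)
  body <- computeBodyMask(ph$volume, tru)
  lab <- volData(ph$labels)
  soft <- lab == 1L | lab == 4L
  expect_gte(sum(body & soft) / sum(soft), 0.99)
  expect_equal(sum(body & lungMask(tru)), 0)
  expect_error(computeBodyMask(MRIVolume(array(1, dim(lab))),
                               tru), "empty body mask")
  # enlarging the lung mask can only shrink the body mask
  grown <- array(lungwater:::cppDilate3D(rightLung(tru)), dim(lab))
  grown[leftLung(tru)] <- FALSE
  seg2 <- LungSegmentation(grown, leftLung(tru), spacing = spacing(ph$volume))
  body2 <- computeBodyMask(ph$volume, seg2)
  expect_true(all(body[body2]))
})

test_that("normalization fit reproduces constants and flattens at large lambda", {
  # constant body signal: the constant lies in the Laplacian null space,
  # so the fit is exact for any lambda
  d <- c(4L, 24L, 24L)
  vol <- MRIVolume(array(7, dim = d), spacing = 3.5)
  body <- array(FALSE, dim = d); body[, 5:20, 5:20] <- TRUE
  for (lam in c(0.1, 10, 1000)) {
    map <- fitNormalizationMap(vol, body, lam, downsample = 2)
    expect_equal(max(abs(volData(map) - 7)), 0, tolerance = 1e-8)
  }
  # huge lambda drives the Laplacian seminorm toward zero
  set.seed(1)
  vol2 <- MRIVolume(array(7 + runif(prod(d)), dim = d), spacing = 3.5)
  mBig <- fitNormalizationMap(vol2, body, 1e6, downsample = 2)
  mSmall <- fitNormalizationMap(vol2, body, 1, downsample = 2)
  expect_lt(mBig@seminorm, 1e-6 * mSmall@seminorm + 1e-12)
  expect_error(fitNormalizationMap(vol2, body, -1), "positive")
})

test_that("coarse-grid solve matches the full-resolution solve for smooth maps", {
  ph <- smallThorax(noiseSD = 0)
  tru <- truthSegmentation(ph$labels)
  body <- computeBodyMask(ph$volume, tru)
  sub <- 20:28   # a few central slices keep the full-res solve fast
  volS <- MRIVolume(volData(ph$volume)[sub, , ], spacing = spacing(ph$volume))
  bodyS <- body[sub, , ]
  lam <- 50
  coarse <- fitNormalizationMap(volS, bodyS, lam, downsample = 4)
  # the coarse seminorm lives on a 4x coarser Laplacian; compare the maps,
  # not the norms
  full <- fitNormalizationMap(volS, bodyS, lam * 4, downsample = 1)
  rel <- abs(volData(coarse)[bodyS] - volData(full)[bodyS]) /
         mean(volData(full)[bodyS])
  expect_lt(median(rel), 0.05)
})

test_that("lambda selection needs a usable grid and is scale-invariant", {
  ph <- smallThorax(noiseSD = 0.02)
  tru <- truthSegmentation(ph$labels)
  body <- computeBodyMask(ph$volume, tru)
  expect_error(selectLambdaLcurve(ph$volume, body, grid = c(1, 10)),
               "at least 3")
  sel <- selectLambdaLcurve(ph$volume, body)
  volK <- MRIVolume(volData(ph$volume) * 37, spacing = spacing(ph$volume))
  selK <- selectLambdaLcurve(volK, body)
  expect_equal(sel$index, selK$index)
})

test_that("normalization division behaves homogeneously", {
  ph <- smallThorax(noiseSD = 0)
  tru <- truthSegmentation(ph$labels)
  body <- computeBodyMask(ph$volume, tru)
  map <- fitNormalizationMap(ph$volume, body, 50)
  nv <- normalizeVolume(ph$volume, map)
  map2 <- map; map2@field <- map@field * 2; map2@bodyMedian <- map@bodyMedian * 2
  nv2 <- normalizeVolume(ph$volume, map2)
  expect_equal(volData(nv2), volData(nv) / 2, tolerance = 1e-12)
  one <- new("NormalizationMap", field = array(1, dim(volData(ph$volume))),
             lambda = 1, sliceResiduals = 0, seminorm = 0, bodyMedian = 1,
             floorFrac = 1e-3)
  expect_equal(volData(normalizeVolume(ph$volume, one)),
               volData(ph$volume))
})

test_that("liver ROI geometry is exact", {
  ph <- smallThorax(noiseSD = 0)
  tru <- truthSegmentation(ph$labels)
  roi <- placeLiverROI(tru, spacing = spacing(ph$volume))
  sp <- spacing(ph$volume)
  bottom <- max(which(rightLung(tru)[roi@slice, , round(roi@centerCol)]))
  expect_equal((roi@centerRow - bottom) * sp[2], 8.75)
  expect_equal(roi@radiusMM, sqrt(12.5 / pi) * 10)
  # all members inside the disc, none on lung
  dr <- (roi@members[, 1] - roi@centerRow) * sp[2]
  dc <- (roi@members[, 2] - roi@centerCol) * sp[3]
  expect_true(all(dr^2 + dc^2 <= roi@radiusMM^2))
  lungPlane <- lungMask(tru)[roi@slice, , ]
  expect_false(any(lungPlane[roi@members]))
  # members fall on liver tissue in the phantom
  lab <- volData(ph$labels)[roi@slice, , ]
  expect_gte(mean(lab[roi@members] == 4L), 0.95)
  expect_error(placeLiverROI(LungSegmentation(array(FALSE, c(4, 4, 4)),
                                              array(FALSE, c(4, 4, 4)),
                                              spacing = 3.5)),
               "right lung is empty")
  # a lung flush against the volume bottom leaves no room for the disc
  r <- array(FALSE, c(8, 20, 20)); r[4, 14:20, 8:12] <- TRUE
  expect_error(placeLiverROI(LungSegmentation(r, r & FALSE, spacing = 3.5)),
               "exceeds volume bounds")
})

test_that("LWD mapping anchors the liver reference at exactly 70%", {
  ph <- smallThorax(noiseSD = 0)
  tru <- truthSegmentation(ph$labels)
  roi <- placeLiverROI(tru, spacing = spacing(ph$volume))
  nv <- ph$volume   # any positive volume serves: the anchor is structural
  lm <- roiMean(nv, roi)
  dat <- volData(nv)
  pick <- which(rightLung(tru), arr.ind = TRUE)[1, , drop = FALSE]
  dat[pick] <- lm
  nv2 <- MRIVolume(dat, spacing = spacing(nv))
  roi@meanSignal <- NA_real_
  lwd <- computeLwdMap(nv2, tru, roi, hepaticWD = 70)
  expect_identical(lwdValues(lwd)[pick], 70)
  dat[pick] <- 0
  lwd0 <- computeLwdMap(MRIVolume(dat, spacing = spacing(nv)), tru, roi)
  expect_identical(lwdValues(lwd0)[pick], 0)
  # scaling the normalized volume leaves the map unchanged
  lwdK <- computeLwdMap(MRIVolume(dat * 3.7, spacing = spacing(nv)), tru,
                        roi)
  expect_equal(lwdValues(lwdK), lwdValues(lwd0), tolerance = 1e-12)
  expect_true(all(is.na(lwdValues(lwd)[!lungMask(tru)])))
})

test_that("slice partition follows the remainder rule", {
  expect_equal(vapply(lungwater:::.splitThirds(1:9), length, 1L),
               c(anterior = 3L, mid = 3L, posterior = 3L))
  expect_equal(vapply(lungwater:::.splitThirds(1:10), length, 1L),
               c(anterior = 3L, mid = 4L, posterior = 3L))
  expect_equal(vapply(lungwater:::.splitThirds(1:11), length, 1L),
               c(anterior = 3L, mid = 4L, posterior = 4L))
  th <- lungwater:::.splitThirds(5:15)
  expect_identical(unlist(th, use.names = FALSE), 5:15)  # contiguous cover
  expect_error(lungwater:::.splitThirds(1:2), "fewer than 3")
})

test_that("summaries of a uniform LWD field are uniform", {
  ph <- smallThorax(noiseSD = 0)
  tru <- truthSegmentation(ph$labels)
  vals <- array(NA_real_, dim(volData(ph$volume)))
  vals[lungMask(tru)] <- 25
  lwd <- new("LWDMap", values = vals, liverMean = 1, hepaticWD = 70,
             spacing = spacing(ph$volume))
  s <- summarizeLwd(lwd, tru)
  expect_equal(c(s@global, s@anterior, s@mid, s@posterior, s@left, s@right),
               rep(25, 6))
  counts <- vapply(s@sliceRanges, length, 1L)
  expect_lte(max(counts) - min(counts), 1L)
})

test_that("the full pipeline is deterministic and scale-invariant", {
  ph <- smallThorax(noiseSD = 0.02)
  r1 <- runPipeline(ph$volume)
  r2 <- runPipeline(ph$volume)
  expect_identical(r1$report, r2$report)
  volK <- MRIVolume(volData(ph$volume) * 5.5, spacing = spacing(ph$volume))
  rK <- runPipeline(volK)
  expect_equal(rK$regional@global, r1$regional@global, tolerance = 1e-8)
  expect_equal(rK$regional@posterior, r1$regional@posterior,
               tolerance = 1e-8)
  expect_equal(rK$report$lambda, r1$report$lambda)
})

test_that("the pipeline recovers the phantom within a percentage point when noise-free", {
  ph <- smallThorax(noiseSD = 0)
  res <- runPipeline(ph$volume)
  expect_lt(abs(res$regional@global - ph$truth@achieved$global), 1)
})

test_that("supine and prone phantoms reverse the anterior-posterior difference", {
  sup <- runPipeline(smallThorax(noiseSD = 0.02)$volume)
  pro <- runPipeline(smallThorax(noiseSD = 0.02, posture = "prone")$volume)
  dSup <- sup$regional@anterior - sup$regional@posterior
  dPro <- pro$regional@anterior - pro$regional@posterior
  expect_lt(dSup, 0)
  expect_gt(dPro, 0)
})

test_that("pipeline errors carry their stage tag", {
  expect_error(runPipeline(MRIVolume(array(1, c(10, 10, 10)))),
               "\\[segmentation\\]")
  ph <- smallThorax(noiseSD = 0)
  expect_error(runPipeline(ph$volume, lambda = -2), "\\[lambda\\]")
})
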