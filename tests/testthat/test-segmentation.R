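test_that("Dice coefficient matches hand-computed overlaps", {
  a <- array(FALSE, c(4, 4, 1)); b <- a
  a[1:2, 1:2, 1] <- TRUE; b[1:2, 1:3, 1] <- TRUE
  # |A| = 4, |B| = 6, |A ∩ B| = 4 -> adjust to the 3-overlap case
  b[2, 2, 1] <- FALSE
  expect_equal(diceCoefficient(a, b), 2 * 3 / (4 + 5))
  a2 <- a; expect_equal(diceCoefficient(a, a2), 1)
  disj <- array(FALSE, c(4, 4, 1)); disj[4, 4, 1] <- TRUE
  expect_equal(diceCoefficient(a, disj), 0)
  expect_equal(diceCoefficient(a * 0 > 1, a * 0 > 1), 1)   # both empty
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
  expect_error(diceCoefficient(a, array(FALSE, c(3, 4, 1))), "shapes")
})

test_that("Dice matches the 4/6/3 hand count", {
  a <- c(rep(TRUE, 4), rep(FALSE, 4))
  b <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(diceCoefficient(a, b), 2 * 3 / (4 + 6))
})

test_that("Soft-Jaccard loss matches its formula", {
  g <- matrix(c(1, 0, 0, 0), 2, 2)
  p <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(softJaccardLoss(p, g, epsilon = 1), 1 - 2 / 3)
  expect_equal(softJaccardLoss(g, g, epsilon = 1), 0)
  expect_equal(softJaccardLoss(g * 0, g, epsilon = 1e-12), 1,
               tolerance = 1e-10)
  expect_error(softJaccardLoss(matrix(2, 2, 2), matrix(1, 2, 2)), "\\[0,1\\]")
  expect_error(softJaccardLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)),
               "shapes")
  # more overlap at fixed |p|, |g| lowers the loss
  pShift <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_lt(softJaccardLoss(p, g, 1), softJaccardLoss(pShift, g, 1))
})

test_that("augmentation is deterministic, shared, and keeps masks binary", {
  set.seed(9)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[10:20, 8:16] <- 1
  cfg <- augmentationConfig()
  a <- augmentPair(img, msk, cfg, seed = 4)
  b <- augmentPair(img, msk, cfg, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$mask %in% c(0, 1)))
  off <- augmentationConfig(flip = FALSE, blur = FALSE, scale = FALSE,
                            rotate = FALSE, noise = FALSE)
  ident <- augmentPair(img, msk, off, seed = 4)
  expect_equal(ident$image, img)
  expect_equal(ident$mask, msk)
})

test_that("flips move a marked pixel to its mirrored location", {
  img <- matrix(0, 16, 16); img[3, 5] <- 1
  msk <- img
  cfg <- augmentationConfig(blur = FALSE, scale = FALSE, rotate = FALSE,
                            noise = FALSE)
  # scan a few seeds for one where exactly the row flip triggered
  for (s in 1:50) {
    out <- augmentPair(img, msk, cfg, seed = s)
    hit <- which(out$mask == 1, arr.ind = TRUE)
    expect_equal(nrow(hit), 1)
    expect_true(all(out$image == out$mask))  # same geometric transform
    expect_true(hit[1] %in% c(3, 14) && hit[2] %in% c(5, 12))
  }
})

test_that("classical segmentation recovers the phantom lungs", {
  ph <- smallThorax(noiseSD = 0)
  tru <- truthSegmentation(ph$labels)
  seg <- segmentLungsClassical(ph$volume)
  expect_gte(diceCoefficient(rightLung(seg), rightLung(tru)), 0.95)
  expect_gte(diceCoefficient(leftLung(seg), leftLung(tru)), 0.95)
  # left-right mirroring swaps the lung labels
  mir <- MRIVolume(volData(ph$volume)[, , rev(seq_len(dim(volData(ph$volume))[3]))],
                   spacing = spacing(ph$volume))
  segM <- segmentLungsClassical(mir)
  flip <- function(m) m[, , rev(seq_len(dim(m)[3]))]
  expect_gte(diceCoefficient(rightLung(segM), flip(leftLung(seg))), 0.99)
  expect_gte(diceCoefficient(leftLung(segM), flip(rightLung(seg))), 0.99)
  expect_error(segmentLungsClassical(MRIVolume(array(1, c(10, 10, 10)))),
               "lungs not found")
})

test_that("lung volume accessor converts voxel counts to liters", {
  r <- array(FALSE, c(4, 4, 4)); l <- r
  r[1:2, 1, 1] <- TRUE; l[1, 1, 3:4] <- TRUE
  seg <- LungSegmentation(r, l, spacing = 10)   # 1 mL voxels
  expect_equal(lungVolume(seg), 4 * 1000 / 1e6)
})
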