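test_that("network analytic gradients agree with numerical differentiation", {
  cfg <- segModelConfig(baseChannels = 2L)
  model <- lungwater:::.unetInit(cfg, seed = 3)
  set.seed(7)
  x <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  g <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  P <- model$params; R <- model$running
  lossOf <- function(P) {
    fw <- lungwater:::.unetFwd(P, R, cfg, x, train = TRUE)
    lungwater:::.softJaccardGrad(fw$z, g, cfg$epsilon)$loss
  }
  fw <- lungwater:::.unetFwd(P, R, cfg, x, train = TRUE)
  sj <- lungwater:::.softJaccardGrad(fw$z, g, cfg$epsilon)
  G <- lungwater:::.unetBwd(P, cfg, fw$cache, sj$dz)
  set.seed(11)
  for (blk in c("enc1", "enc2", "bridge", "dec3", "dec0", "out")) {
    for (nm in names(G[[blk]])) {
      v <- P[[blk]][[nm]]
      i <- sample(length(v), 1)
      eps <- 1e-5
      P1 <- P; P1[[blk]][[nm]][i] <- v[i] + eps
      P2 <- P; P2[[blk]][[nm]][i] <- v[i] - eps
      numg <- (lossOf(P1) - lossOf(P2)) / (2 * eps)
      ana <- G[[blk]][[nm]][i]
      expect_lt(abs(numg - ana), 1e-6 + 1e-3 * (abs(numg) + abs(ana)),
                label = paste(blk, nm))
    }
  }
})

test_that("train/validation split arithmetic is exact", {
  ds <- generateSegmentationTrainingSet(100, size = 32, seed = 2)
  m <- trainUnet(ds$images, ds$masks, segModelConfig(baseChannels = 2L),
                 augCfg = NULL, seed = 1, batchSize = 16, maxEpochs = 1)
  # 80/20 of 100 pairs: the epoch log covers 80 training slices in
  # ceiling(80/16) = 5 batches and validates on the remaining 20
  expect_equal(nrow(m$log), 1)
  expect_true(isTRUE(m$trained))
  n <- 100; nTrain <- round(0.8 * n)
  expect_equal(nTrain, 80)
  expect_equal(n - nTrain, 20)
})

test_that("a duplicated single pair is memorized (overfit sanity)", {
  set.seed(4)
  img <- matrix(0, 32, 32)
  img[8:24, 8:24] <- 100
  img[12:20, 10:18] <- 25
  msk <- matrix(0, 32, 32); msk[12:20, 10:18] <- 1
  images <- array(rep(img, 10), c(32, 32, 10))
  masks <- array(rep(msk, 10), c(32, 32, 10))
  m <- trainUnet(images, masks, segModelConfig(baseChannels = 4L),
                 augCfg = NULL, seed = 1, batchSize = 4, maxEpochs = 30,
                 lr = 5e-3, targetDice = 0.999)
  expect_gte(m$valDice, 0.99)

  # prediction plumbing: thresholding is monotone, output masks disjoint
  vol <- MRIVolume(aperm(array(img, c(32, 32, 4)), c(3, 1, 2)),
                   spacing = m$cfg$resampleMM)
  seg5 <- predictLungsUnet(m, vol)
  cfg9 <- m$cfg; cfg9$threshold <- 0.9
  seg9 <- predictLungsUnet(m, vol, cfg = cfg9)
  m5 <- lungMask(seg5); m9 <- lungMask(seg9)
  expect_true(all(m5[m9]))          # mask at 0.9 is a subset of mask at 0.5
  expect_gte(diceCoefficient(m5[1, , ], msk), 0.95)
})

test_that("training input validation catches degenerate datasets", {
  ds <- generateSegmentationTrainingSet(4, size = 32, seed = 3)
  expect_error(trainUnet(ds$images[, , 1, drop = FALSE],
                         ds$masks[, , 1, drop = FALSE]), "at least two")
  expect_error(trainUnet(ds$images, ds$masks * 0), "empty")
  expect_error(trainUnet(ds$images[1:30, , ], ds$masks[1:30, , ]),
               "divisible by 8")
  expect_error(predictLungsUnet(list(trained = FALSE),
                                MRIVolume(array(1, c(2, 32, 32)))),
               "trained")
})

test_that("model save/load round-trips", {
  ds <- generateSegmentationTrainingSet(8, size = 32, seed = 6)
  m <- trainUnet(ds$images, ds$masks, segModelConfig(baseChannels = 2L),
                 augCfg = NULL, seed = 1, batchSize = 4, maxEpochs = 1)
  f <- tempfile(fileext = ".rds")
  saveUNetModel(m, f)
  m2 <- loadUNetModel(f)
  expect_equal(m$params, m2$params)
  expect_true(file.exists(paste0(f, ".json")))
})
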