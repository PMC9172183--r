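test_that("noise-free vial extraction returns the exact concentrations", {
  ph <- generateVialPhantom(noiseSD = 0)
  vm <- extractVialMeans(ph$volume, ph$layout)
  expect_equal(vm$relative, seq(10, 100, by = 10))
  expect_equal(vm$relative[ph$layout@reference], 100)
})

test_that("oversized vial ROIs on edge vials are rejected", {
  ph <- generateVialPhantom(noiseSD = 0)
  expect_error(extractVialMeans(ph$volume, ph$layout, roiShrink = 1.2),
               "leaves the volume")
})

test_that("noisy extraction stays within 3% of truth across seeds", {
  for (s in 1:3) {
    ph <- generateVialPhantom(noiseSD = 0.02, seed = s)
    vm <- extractVialMeans(ph$volume, ph$layout)
    expect_lt(max(abs(vm$relative - vm$known)), 3)
  }
})

test_that("linear agreement matches hand-solved least squares", {
  k <- c(0, 1, 2); m <- c(1, 1, 3)
  fit <- linearAgreement(k, m)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 2 / 3)
  ident <- linearAgreement(1:10, 1:10)
  expect_equal(ident$slope, 1); expect_equal(ident$intercept, 0)
  expect_equal(ident$r2, 1)
  aff <- linearAgreement(1:10, 2 * (1:10) + 5)
  expect_equal(aff$slope, 2); expect_equal(aff$intercept, 5)
  expect_equal(aff$r2, 1)
  expect_error(linearAgreement(rep(1, 5), 1:5), "zero variance")
  expect_error(linearAgreement(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman bias and spread follow their definitions", {
  a <- c(10, 20, 30, 40)
  expect_equal(blandAltman(a, a), list(bias = 0, sd = 0,
                                       loa = c(lower = 0, upper = 0)))
  off <- blandAltman(a + 4.3, a)
  expect_equal(off$bias, 4.3)
  expect_equal(off$sd, 0)
  two <- blandAltman(c(1, -1), c(0, 0))
  expect_equal(two$bias, 0)
  expect_equal(two$sd, sqrt(2))
  expect_equal(unname(two$loa), c(-1.96 * sqrt(2), 1.96 * sqrt(2)))
  expect_error(blandAltman(1:3, 1:4), "length mismatch")
})

test_that("ICC(A,1) matches hand-evaluated mean squares", {
  expect_equal(iccAbsoluteAgreement(1:4, 1:4), 1)
  expect_equal(iccAbsoluteAgreement(c(1, 2, 3, 4), c(4, 3, 2, 1)), -2)
  expect_lt(iccAbsoluteAgreement(c(1, 2, 3, 4), c(4, 3, 2, 1)), 0)
  expect_error(iccAbsoluteAgreement(1:2, 1:2), "at least 3")
  expect_error(iccAbsoluteAgreement(rep(2, 5), rep(2, 5)), "zero total")
})

test_that("ICC equals an aov-derived variance-components computation", {
  set.seed(33)
  for (rep in 1:20) {
    x <- runif(10, 0, 100)
    y <- x + rnorm(10, runif(1, -5, 5), runif(1, 0.5, 10))
    tab <- data.frame(v = c(x, y),
                      subj = factor(rep(1:10, 2)),
                      rater = factor(rep(1:2, each = 10)))
    ms <- summary(aov(v ~ subj + rater, data = tab))[[1]]$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    k <- 2; n <- 10
    sr <- (msr - mse) / k
    sc <- (msc - mse) / n
    icc <- sr / (sr + sc + mse)
    expect_equal(iccAbsoluteAgreement(x, y), icc, tolerance = 1e-10)
  }
})

test_that("agreement statistics carry the expected invariances", {
  set.seed(9)
  x <- runif(10, 10, 100); y <- x + rnorm(10, 1, 4)
  # r^2 invariant under affine rescaling of either column
  expect_equal(linearAgreement(x, y)$r2,
               linearAgreement(2 * x + 3, 5 * y - 1)$r2)
  # ICC invariant under a common shift of both columns
  expect_equal(iccAbsoluteAgreement(x, y),
               iccAbsoluteAgreement(x + 17, y + 17), tolerance = 1e-12)
})

test_that("the simulated phantom experiment is accurate and noise-monotone", {
  perfect <- runPhantomExperiment(2, noiseSD = 0, seeds = 1:2)
  expect_equal(perfect$blandAltman$bias, 0)
  expect_equal(perfect$iccPooled, 1)
  expect_equal(perfect$regression$r2, 1)

  lo <- vapply(1:20, function(s)
    runPhantomExperiment(1, noiseSD = 0.02, seeds = s)$iccPooled, 0)
  hi <- vapply(1:20, function(s)
    runPhantomExperiment(1, noiseSD = 0.04, seeds = 100 + s)$iccPooled, 0)
  expect_gt(mean(lo), mean(hi))
  expect_error(runPhantomExperiment(2, seeds = 1), "one seed per repeat")
})
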