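test_that("FA and MD formulas match their closed forms", {
  d <- 1.3e-3
  expect_equal(computeFA(c(d, d, d)), 0)
  expect_equal(computeMD(c(d, d, d)), d)
  expect_equal(computeFA(c(d, 0, 0)), 1)
  expect_equal(computeFA(c(1.7e-3, 0.3e-3, 0.3e-3)), 0.799, tolerance = 1e-3)
  expect_equal(computeMD(c(1.7e-3, 0.3e-3, 0.3e-3)), 0.76667e-3,
               tolerance = 1e-4)
  expect_equal(computeFA(c(0, 0, 0)), 0)       # convention for null tensor
  expect_error(computeFA(c(1e-3, -1e-4, 1e-4)), "non-negative")
})

test_that("noiseless fits recover tensors to machine precision over the FA grid", {
  set.seed(21)
  for (faT in seq(0.1, 0.9, by = 0.2)) {
    tn <- prolateTensor(faT, orientation = randomRotation_(), s0 = 1.5)
    s <- simulateSignal(tn, ovp48)
    fit <- fitTensor(s, ovp48)
    expect_equal(fa(fit), faT, tolerance = 1e-9)
    expect_equal(md(fit), 1.1e-3, tolerance = 1e-12)
    expect_equal(unname(exp(fit@coefficients[1, "logS0"])), 1.5,
                 tolerance = 1e-9)
    rob <- fitTensorRobust(s, ovp48)
    expect_equal(fa(rob), faT, tolerance = 1e-9)
  }
})

test_that("weighting conventions behave: all-equal weights match no weights", {
  tn <- prolateTensor(0.55, orientation = rotationWithAxis(c(2, 1, 3)))
  s <- simulateSignal(tn, ovp48)
  f0 <- fitTensor(s, ovp48)
  f1 <- fitTensor(s, ovp48, weights = rep(1, 48))
  expect_equal(f0@coefficients, f1@coefficients, tolerance = 1e-9)
})

test_that("FA and MD are invariant to global signal scaling", {
  set.seed(22)
  tn <- prolateTensor(0.5, orientation = randomRotation_())
  s <- addRicianNoise(simulateSignal(tn, ovp48), 20, seed = 3)
  fit1 <- fitTensor(s, ovp48)
  fitC <- fitTensor(s * 5.5, ovp48)
  expect_equal(fa(fitC), fa(fit1), tolerance = 1e-9)
  expect_equal(md(fitC), md(fit1), tolerance = 1e-12)
})

test_that("clean noiseless data yields all-ones outlier weights", {
  tn <- prolateTensor(0.4)
  s <- simulateSignal(tn, ovp48)
  fit <- fitTensorRobust(s, ovp48)
  expect_equal(unname(outlierWeights(fit)[1, ]), rep(1, 48))
})

test_that("a single dropped volume is down-weighted, clean volumes kept", {
  set.seed(23)
  hit <- 0L
  cleanOk <- 0L
  for (i in 1:100) {
    tn <- prolateTensor(0.5, orientation = randomRotation_())
    s <- addRicianNoise(simulateSignal(tn, ovp48), 20)
    k <- sample(which(bValues(ovp48) > 0), 1)
    s[k] <- s[k] * 0.25
    w <- outlierWeights(fitTensorRobust(s, ovp48))[1, ]
    hit <- hit + (w[k] < 0.5)
    # clean volumes stay essentially retained: at most a couple of
    # borderline down-weightings from modified-Z tail noise
    cleanOk <- cleanOk + (median(w[-k]) == 1 && mean(w[-k]) > 0.95)
  }
  expect_gte(hit / 100, 0.95)
  expect_gte(cleanOk / 100, 0.95)
})

test_that("detection sensitivity on a 15%-corrupted phantom is high", {
  set.seed(24)
  ph <- simulatePhantom(rep(0.5, 10), ovp48, region = "FMA")
  noisy <- addRicianNoise(ph, snr = 20)
  corr <- injectOutliers(noisy, fraction = 0.15, magnitude = 0.25)
  fit <- fitTensorRobust(corr)
  w <- outlierWeights(fit)
  truthMask <- outlierMask(corr)
  sens <- sum(w < 0.5 & truthMask) / sum(truthMask)
  expect_gte(sens, 0.8)
})

test_that("robust fit equals plain WLS when no outliers are present", {
  set.seed(25)
  tn <- prolateTensor(0.5, orientation = randomRotation_())
  s <- addRicianNoise(simulateSignal(tn, ovp48), 30)
  expect_equal(fa(fitTensorRobust(s, ovp48)), fa(fitTensor(s, ovp48)),
               tolerance = 0.02)
  # and the robust fit is deterministic: identical on repeat
  expect_identical(fa(fitTensorRobust(s, ovp48)),
                   fa(fitTensorRobust(s, ovp48)))
})

test_that("robust fit beats plain WLS under dropout in a clear majority of trials", {
  set.seed(26)
  wtd <- which(bValues(ovp48) > 0)
  win <- 0L
  for (t in 1:200) {
    tn <- prolateTensor(0.5, orientation = randomRotation_())
    s <- addRicianNoise(simulateSignal(tn, ovp48), 20)
    idx <- sample(wtd, 7)
    s[idx] <- s[idx] * 0.25
    eR <- abs(fa(fitTensorRobust(s, ovp48)) - 0.5)
    eP <- abs(fa(fitTensor(s, ovp48)) - 0.5)
    win <- win + (eR < eP)
  }
  expect_gte(win / 200, 0.70)
})

test_that("median FA error at SNR 20 stays within the protocol's tolerance", {
  set.seed(27)
  errs <- replicate(200, {
    tn <- prolateTensor(0.5, orientation = randomRotation_())
    s <- addRicianNoise(simulateSignal(tn, ovp48), 20)
    abs(fa(fitTensorRobust(s, ovp48)) - 0.5)
  })
  expect_lte(median(errs), 0.05)
})
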