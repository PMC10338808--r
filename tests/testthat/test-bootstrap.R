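test_that("zero residuals give a degenerate bootstrap distribution", {
  tn <- prolateTensor(0.5, orientation = rotationWithAxis(c(1, 1, 2)))
  s <- simulateSignal(tn, ovp48)
  fit <- fitTensor(s, ovp48)
  bs <- wildBootstrap(fit, nSamples = 200, seed = 1)
  expect_equal(max(abs(bs@faSamples - fa(fit))), 0, tolerance = 1e-9)
  expect_equal(max(abs(bs@mdSamples - md(fit))), 0, tolerance = 1e-12)
  expect_equal(unname(medianFAMap(bs)), fa(fit), tolerance = 1e-9)
  expect_true(checkConvergence(bs, "fa"))
  expect_true(checkConvergence(bs, "md"))
  expect_error(wildBootstrap(fit, nSamples = 1), ">= 2")
})

test_that("bootstrap is seed-reproducible and median lies inside the CI", {
  set.seed(31)
  tn <- prolateTensor(0.45, orientation = randomRotation_())
  s <- addRicianNoise(simulateSignal(tn, ovp48), 20)
  fit <- fitTensorRobust(s, ovp48)
  b1 <- wildBootstrap(fit, nSamples = 300, seed = 5)
  b2 <- wildBootstrap(fit, nSamples = 300, seed = 5)
  expect_identical(b1@faSamples, b2@faSamples)
  ci <- bootstrapCI(b1, "fa")
  medFA <- medianFAMap(b1)
  expect_true(ci[, "lower"] <= medFA && medFA <= ci[, "upper"])
})

test_that("median FA map matches an independent sort-based median", {
  set.seed(32)
  tn <- prolateTensor(0.3, orientation = randomRotation_())
  s <- addRicianNoise(simulateSignal(tn, ovp48), 15)
  fit <- fitTensorRobust(s, ovp48)
  bs <- wildBootstrap(fit, nSamples = 201, seed = 9)   # odd n: order stat
  v <- sort(bs@faSamples[1, ])
  expect_identical(unname(medianFAMap(bs)), v[101])
})

test_that("doubling SNR shrinks the FA confidence interval", {
  set.seed(33)
  widthAt <- function(snr, trials = 40) {
    median(replicate(trials, {
      tn <- prolateTensor(0.5, orientation = randomRotation_())
      s <- addRicianNoise(simulateSignal(tn, ovp48), snr)
      ci <- bootstrapCI(wildBootstrap(fitTensorRobust(s, ovp48),
                                      nSamples = 400), "fa")
      ci[, "upper"] - ci[, "lower"]
    }))
  }
  expect_lt(widthAt(40), widthAt(20))
})

test_that("infinite thresholds declare everything converged", {
  set.seed(34)
  tn <- prolateTensor(0.5, orientation = randomRotation_())
  s <- addRicianNoise(simulateSignal(tn, ovp48), 10)
  bs <- wildBootstrap(fitTensorRobust(s, ovp48), nSamples = 200, seed = 2)
  expect_true(checkConvergence(bs, "fa", ciWidthThreshold = Inf))
  expect_true(checkConvergence(bs, "md", ciWidthThreshold = Inf))
})

test_that("bootstrap FA distribution ignores volume ordering", {
  # permuting volumes (with their attached sign draws) relabels rows only
  set.seed(35)
  tn <- prolateTensor(0.4, orientation = randomRotation_())
  s <- addRicianNoise(simulateSignal(tn, ovp48), 20)
  fit <- fitTensorRobust(s, ovp48)
  perm <- sample(48)
  schP <- GradientScheme("perm", bValues(ovp48)[perm],
                         gradientDirections(ovp48)[perm, ],
                         repetitionIndex(ovp48)[perm])
  fitP <- fitTensorRobust(s[perm], schP)
  expect_equal(fa(fitP), fa(fit), tolerance = 1e-9)
  bs <- wildBootstrap(fit, nSamples = 2000, seed = 11)
  bsP <- wildBootstrap(fitP, nSamples = 2000, seed = 11)
  # same distribution: compare robust summaries, not draw-by-draw order
  expect_equal(unname(medianFAMap(bsP)), unname(medianFAMap(bs)),
               tolerance = 0.01)
  expect_equal(unname(bootstrapCI(bsP, "fa")), unname(bootstrapCI(bs, "fa")),
               tolerance = 0.02)
})

test_that("median-FA bias at the protocol's working point is small", {
  set.seed(36)
  medFAs <- replicate(100, {
    tn <- prolateTensor(0.5, orientation = randomRotation_())
    s <- addRicianNoise(simulateSignal(tn, ovp48), 20)
    medianFAMap(wildBootstrap(fitTensorRobust(s, ovp48), nSamples = 300))
  })
  expect_lte(abs(mean(medFAs) - 0.5), 0.03)
})
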