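test_that("forward model honours tensor geometry", {
  d <- 1.1e-3
  iso <- simulateSignal(tensorSpec(c(d, d, d), s0 = 2), ovp16)
  wtd <- bValues(ovp16) > 0
  expect_equal(iso[!wtd], 2, tolerance = 1e-12)          # b=0 gives S0
  expect_equal(iso[wtd], rep(2 * exp(-700 * d), 15), tolerance = 1e-12)

  # principal axis aligned with a measurement direction: that volume sees
  # the fastest diffusion, hence the smallest signal on the shell
  g7 <- gradientDirections(ovp16)[which(wtd)[7], ]
  tn <- tensorSpec(c(1.7e-3, 0.3e-3, 0.3e-3),
                   orientation = rotationWithAxis(g7))
  s <- simulateSignal(tn, ovp16)
  expect_equal(which.min(s[wtd]), 7L)
})

test_that("prolate construction inverts the FA formula at fixed MD", {
  for (faT in seq(0.05, 0.95, by = 0.1)) {
    tn <- prolateTensor(faT, md = 1.1e-3)
    expect_equal(computeFA(tn$eigenvalues), faT, tolerance = 1e-12)
    expect_equal(computeMD(tn$eigenvalues), 1.1e-3, tolerance = 1e-15)
  }
  expect_error(prolateTensor(1.2), "\\[0, 1\\)")
})

test_that("Rician noise has the right limits and is seed-reproducible", {
  s <- simulateSignal(prolateTensor(0.4), ovp48)
  expect_equal(addRicianNoise(s, snr = 1e12, seed = 1), s,
               tolerance = 1e-9)                         # snr -> Inf limit
  # zero signal: Rayleigh mean sigma * sqrt(pi/2) (closed-form oracle)
  z <- addRicianNoise(rep(0, 1e5), snr = 1, s0 = 1, seed = 2)
  expect_equal(mean(z), sqrt(pi / 2), tolerance = 0.01)
  expect_identical(addRicianNoise(s, 20, seed = 7),
                   addRicianNoise(s, 20, seed = 7))
  expect_error(addRicianNoise(s, -5), "positive")
})

test_that("dropout injection corrupts the configured share of weighted volumes", {
  ph <- simulatePhantom(rep(0.3, 6), ovp48, region = "FMA", seed = 3)
  out0 <- injectOutliers(ph, fraction = 0, seed = 1)
  expect_equal(dwiSignals(out0), dwiSignals(ph))
  expect_false(any(outlierMask(out0)))

  out <- injectOutliers(ph, fraction = 0.15, magnitude = 0.25, seed = 1)
  mask <- outlierMask(out)
  expect_equal(unname(rowSums(mask)), rep(7L, 6))   # round(0.15 * 45) = 7
  b0 <- bValues(ovp48) == 0
  expect_false(any(mask[, b0]))                     # b=0 never corrupted
  expect_equal(sum(mask) / (6 * 45), 7 / 45, tolerance = 1e-12)
  changed <- dwiSignals(out) != dwiSignals(ph)
  expect_identical(changed, mask)
  expect_equal(dwiSignals(out)[mask], (dwiSignals(ph) * 0.25)[mask])
  expect_error(injectOutliers(ph, 0.7), "0.5")
})

test_that("repetition scaling composes with normalization as exact inverse", {
  ph <- simulatePhantom(c(0.2, 0.35, 0.5), ovp48,
                        region = c("FMA", "CST_l", "CST_r"), seed = 5)
  expect_equal(dwiSignals(applyRepetitionScaling(ph, c(1, 1, 1))),
               dwiSignals(ph))
  sc <- applyRepetitionScaling(ph, c(1, 1.1, 0.9))
  rep_idx <- repetitionIndex(ovp48)
  b0 <- bValues(ovp48) == 0
  m <- vapply(1:3, function(r) mean(dwiSignals(sc)[, b0 & rep_idx == r]),
              numeric(1))
  expect_equal(m / m[1], c(1, 1.1, 0.9), tolerance = 1e-12)
  back <- normalizeRepetitions(sc)
  expect_equal(dwiSignals(back$dataset), dwiSignals(ph), tolerance = 1e-9)
  expect_error(applyRepetitionScaling(ph, c(1, -1, 1)), "positive")
})

test_that("cohort simulation is deterministic and recovers configured effects", {
  a <- simulateCohort(seed = 33)
  b <- simulateCohort(seed = 33)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$faMatrix, b$faMatrix)
  expect_setequal(sub("^fa_", "", grep("^fa_", names(a$cohort), value = TRUE)),
                  wmBundles())
  expect_equal(nrow(a$cohort), 20L)

  # configured FA group difference converges with n (FMA: d = 0.70,
  # sd = 0.03 => mean difference 0.021)
  big <- simulateCohort(cohortConfig(nPerGroup = 200), seed = 11)$cohort
  diffFMA <- mean(big$fa_FMA[big$group == "optimal"]) -
    mean(big$fa_FMA[big$group == "nonoptimal"])
  expect_equal(diffFMA, 0.70 * 0.03, tolerance = 0.02)

  # infeasible FA targets rejected
  rg <- defaultRegionConfig()
  rg$mean_optimal[1] <- 1.2
  expect_error(cohortConfig(regions = rg), "infeasible")
})

test_that("null cohort configuration yields near-zero effect sizes", {
  rg <- defaultRegionConfig()
  rg$cohen_d <- 0
  oc <- defaultOutcomeConfig()
  oc$mean_nonoptimal <- oc$mean_optimal
  oc$fa_slope <- 0
  set.seed(42)
  ds <- replicate(60, {
    co <- simulateCohort(cohortConfig(nPerGroup = 10, regions = rg,
                                      outcomes = oc))$cohort
    cohensD(co$fa_FMA[co$group == "optimal"],
            co$fa_FMA[co$group == "nonoptimal"])
  })
  expect_lt(abs(mean(ds)), 0.15)
})

test_that("noiseless phantoms yield exact downstream FA recovery", {
  faT <- c(0.1, 0.3, 0.55, 0.8)
  ph <- simulatePhantom(faT, ovp48, region = "FMA", seed = 8)
  fit <- fitTensorRobust(ph)
  expect_lt(max(abs(fa(fit) - faT)), 1e-6)
})
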