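test_that("over-plus scheme has the protocol's volume layout and valid b-matrices", {
  expect_equal(nVolumes(ovp48), 48L)           # 3 b=0 + 45 weighted
  expect_equal(sum(bValues(ovp48) == 0), 3L)
  expect_equal(sum(bValues(ovp48) > 0), 45L)
  expect_equal(nRepetitions(ovp48), 3L)
  g <- gradientDirections(ovp48)
  wtd <- bValues(ovp48) > 0
  expect_true(all(abs(sqrt(rowSums(g[wtd, ]^2)) - 1) <= 1e-9))
  bm <- bMatrices(ovp48)
  traces <- vapply(seq_len(48), function(k) sum(diag(bm[, , k])), numeric(1))
  expect_true(all(abs(traces[wtd] - 700) <= 1e-6))
  expect_true(all(abs(traces[!wtd]) == 0))
  expect_true(all(bm[, , 1] == 0))             # b=0 volume: zero matrix
  expect_error(buildOverplusScheme(-700), "positive")
})

test_that("antipodal flip of any direction leaves b-matrices unchanged", {
  dirs <- gradientDirections(ovp16)[bValues(ovp16) > 0, ]
  flipped <- dirs
  flipped[c(2, 9, 14), ] <- -flipped[c(2, 9, 14), ]
  sch2 <- buildOverplusScheme(700, 1, directions = flipped)
  expect_equal(bMatrices(sch2), bMatrices(ovp16), tolerance = 1e-12)
})

test_that("uniform scheme spreads directions more evenly than over-plus", {
  expect_gt(minimumAntipodalAngle(uni15), minimumAntipodalAngle(ovp48))
  expect_lte(conditionNumber(uni15), conditionNumber(ovp48))
  expect_error(buildUniformScheme(5), "under-determined")
})

test_that("uniform scheme construction is seed-deterministic", {
  a <- buildUniformScheme(8, 700, 1, seed = 9)
  b <- buildUniformScheme(8, 700, 1, seed = 9)
  expect_identical(gradientDirections(a), gradientDirections(b))
})

test_that("six uniform directions give an exact noiseless tensor solve", {
  uni6 <- buildUniformScheme(6, 700, 1)
  # independent oracle: closed-form log-linear solve of the 7x7 system
  tn <- prolateTensor(0.6, orientation = rotationWithAxis(c(1, 2, 2)))
  s <- simulateSignal(tn, uni6)
  X <- designMatrix(uni6)
  theta <- solve(crossprod(X), crossprod(X, log(s)))
  lamOracle <- sort(eigen(matrix(c(theta[2], theta[5], theta[6],
                                   theta[5], theta[3], theta[7],
                                   theta[6], theta[7], theta[4]), 3, 3),
                          symmetric = TRUE)$values, decreasing = TRUE)
  fit <- fitTensor(s, uni6)
  expect_equal(as.numeric(tensorEigenvalues(fit)), lamOracle,
               tolerance = 1e-9)
  expect_equal(fa(fit), 0.6, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected", {
  dup <- GradientScheme("dup", c(0, rep(700, 15)),
                        rbind(0, matrix(rep(c(1, 0, 0), 15), 15, 3,
                                        byrow = TRUE)))
  expect_error(conditionNumber(dup), "cannot support")
  expect_error(fitTensor(simulateSignal(tensorSpec(rep(1e-3, 3)), dup), dup),
               "insufficient usable volumes")
})

test_that("bval/bvec files round-trip a scheme", {
  prefix <- file.path(tempdir(), "sch")
  writeScheme(ovp48, prefix)
  back <- readScheme(paste0(prefix, ".bval"), paste0(prefix, ".bvec"),
                     name = "overplus15")
  expect_equal(bValues(back), bValues(ovp48))
  expect_equal(gradientDirections(back), gradientDirections(ovp48),
               tolerance = 1e-12)
  expect_equal(nRepetitions(back), 3L)
  expect_equal(bMatrices(back), bMatrices(ovp48), tolerance = 1e-9)
})
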