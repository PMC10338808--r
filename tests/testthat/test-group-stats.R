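test_that("Cohen's D matches the pooled-SD hand computation", {
  # two n=10 samples with exact means 10.8/8.2 and SDs 2.1/2.3:
  # pooled SD = sqrt((9*2.1^2 + 9*2.3^2)/18) = 2.2023, d = 2.6/2.2023
  z <- as.numeric(scale(seq_len(10)))
  x <- 10.8 + 2.1 * z
  y <- 8.2 + 2.3 * z
  expect_equal(cohensD(x, y), 2.6 / sqrt((9 * 2.1^2 + 9 * 2.3^2) / 18),
               tolerance = 1e-12)
  expect_equal(cohensD(x, y), 1.18, tolerance = 0.005)
  expect_equal(cohensD(y, x), -cohensD(x, y))
  expect_equal(cohensD(x, x), 0)
  expect_error(cohensD(rep(1, 5), rep(2, 5)), "degenerate dispersion")
  expect_equal(cohensD(rep(1, 5), rep(1, 5)), 0)
})

test_that("Harrell-Davis quantiles track the distribution", {
  set.seed(41)
  x <- rnorm(5000)
  expect_equal(hdQuantile(x, 0.5), median(x), tolerance = 0.02)
  expect_equal(hdQuantile(x, c(0.25, 0.75)),
               unname(quantile(x, c(0.25, 0.75))), tolerance = 0.03)
  expect_error(hdQuantile(x, 1.5), "\\(0, 1\\)")
})

test_that("Akinshin gamma collapses to a point under pure shift and matches D", {
  set.seed(42)
  x <- rnorm(1e4, 0.5)
  y <- rnorm(1e4, 0)
  g <- akinshinGamma(x, y)
  d <- cohensD(x, y)
  expect_lte(abs(g$min - d), 0.1)
  expect_lte(abs(g$max - d), 0.1)
  expect_lt(g$max - g$min, 0.08)    # near-degenerate range under pure shift
})

test_that("Akinshin gamma range widens under tail inflation", {
  set.seed(43)
  x <- rnorm(4000)
  y <- c(rnorm(3200), rnorm(800, 2.5, 1.5))   # upper-tail contamination
  g <- akinshinGamma(x, y)
  expect_gt(g$max - g$min, 0.3)
  expect_error(akinshinGamma(rep(1, 10), rep(1, 10)), "degenerate")
})

test_that("permutation inference handles degenerate and rescaled inputs", {
  set.seed(44)
  dat <- data.frame(group = rep(c("optimal", "nonoptimal"), each = 10),
                    sex = sample(c("M", "F"), 20, TRUE))
  expect_equal(permutationLM(rep(0.3, 20), dat, nPermutations = 100)$p_raw,
               1)
  fa <- rnorm(20, 0.25, 0.03)
  p1 <- permutationLM(fa, dat, nPermutations = 300, seed = 7)
  p2 <- permutationLM(fa * 100 - 3, dat, nPermutations = 300, seed = 7)
  expect_equal(p1$p_raw, p2$p_raw)                 # affine invariance
  expect_identical(p1, permutationLM(fa, dat, nPermutations = 300,
                                     seed = 7))   # seed determinism
  expect_error(permutationLM(fa, dat, nPermutations = 50), ">= 100")
  dat$dup <- as.numeric(dat$group == "optimal")
  expect_error(permutationLM(fa, dat, covariates = c("sex", "dup"),
                             nPermutations = 100), "rank-deficient")
})

test_that("permutation power at a one-SD group difference is substantial", {
  set.seed(45)
  rej <- 0L
  for (i in 1:200) {
    fa <- c(rnorm(10, 0.28, 0.03), rnorm(10, 0.25, 0.03))   # d = 1
    dat <- data.frame(group = rep(c("optimal", "nonoptimal"), each = 10),
                      sex = sample(c("M", "F"), 20, TRUE))
    rej <- rej + (permutationLM(fa, dat, nPermutations = 400)$p_raw <= 0.05)
  }
  expect_gte(rej / 200, 0.5)
})

test_that("Bonferroni adjustment dominates the raw p-values", {
  set.seed(46)
  fa <- matrix(rnorm(5 * 20, 0.25, 0.03), 5,
               dimnames = list(paste0("r", 1:5), NULL))
  dat <- data.frame(group = rep(c("optimal", "nonoptimal"), each = 10),
                    sex = sample(c("M", "F"), 20, TRUE))
  res <- permutationLM(fa, dat, nPermutations = 200, seed = 3)
  expect_true(all(res$p_bonferroni >= res$p_raw))
  expect_true(all(res$p_bonferroni <= 1))
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 5))
  one <- permutationLM(fa[1, ], dat, nPermutations = 200, seed = 3)
  expect_equal(one$p_bonferroni, one$p_raw)        # single test: equality
})

test_that("the FA-score and interaction contrasts are exposed", {
  set.seed(47)
  n <- 24
  dat <- data.frame(group = rep(c("optimal", "nonoptimal"), each = n / 2),
                    sex = sample(c("M", "F"), n, TRUE),
                    Arrows = rnorm(n, 10, 2))
  fa <- 0.25 + 0.01 * dat$Arrows + rnorm(n, 0, 0.01)
  ps <- permutationLM(fa, dat, effect = "Arrows", nPermutations = 300,
                      seed = 5)
  expect_lt(ps$p_raw, 0.05)    # strong built-in association detected
  pi <- permutationLM(fa, dat, effect = "interaction", score = "Arrows",
                      nPermutations = 300, seed = 5)
  expect_true(pi$p_raw > 0 && pi$p_raw <= 1)
})

test_that("region report assembles effects and quartiles per region", {
  sim <- simulateCohort(seed = 61)
  rep_ <- regionReport(sim$cohort, nPermutations = 200, seed = 8)
  expect_setequal(rep_$effects$region, wmBundles())
  expect_equal(nrow(rep_$quartiles), 2L * length(wmBundles()))
  expect_true(all(rep_$effects$gamma_min <= rep_$effects$gamma_max))
  expect_true(all(rep_$quartiles$q25 <= rep_$quartiles$q50 &
                  rep_$quartiles$q50 <= rep_$quartiles$q75))
  expect_true(all(rep_$effects$n_optimal == 10))
  # deterministic given seed
  rep2 <- regionReport(sim$cohort, nPermutations = 200, seed = 8)
  expect_identical(rep_, rep2)
  # missing group is an error
  broken <- sim$cohort[sim$cohort$group == "optimal", ]
  expect_error(regionReport(broken, nPermutations = 200),
               "both groups")
})
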