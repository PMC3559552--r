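# independent brute-force entropy oracle
entropyOracle <- function(x, C) {
  v <- floor(x / C)
  tab <- table(v)
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log2(p))
}

test_that("contracted-count entropy matches hand computations", {
  expect_equal(entropyOfCounts(rep(7, 10)), 0)
  expect_equal(entropyOfCounts(c(0, 0, 9, 9), C = 5), 1)        # log2(2)
  expect_equal(entropyOfCounts(c(10, 14), C = 5), 0)            # both floor to 2
  expect_equal(entropyOfCounts(c(0, 5, 10, 15), C = 5), 2)      # 4 equal bins
  # base invariance up to the log factor
  expect_equal(entropyOfCounts(c(0, 0, 9, 9), C = 5, base = exp(1)), log(2))
  expect_error(entropyOfCounts(numeric(0)), "empty")
  expect_error(entropyOfCounts(c(-1, 2)), "non-negative")
})

test_that("entropy matches a brute-force histogram oracle on random inputs", {
  set.seed(211)
  for (k in 1:50) {
    x <- rpois(50, lambda = sample(5:60, 1))
    C <- sample(1:8, 1)
    expect_equal(entropyOfCounts(x, C), entropyOracle(x, C))
  }
  # bounds: 0 <= H <= log2(n), zero iff all contracted values equal
  x <- rpois(50, 30)
  expect_lte(entropyOfCounts(x, 1), log2(50))
  expect_gte(entropyOfCounts(x, 1), 0)
  expect_equal(entropyOfCounts(x, 10000), 0)
})

test_that("variability fitness is the entropy ratio with carry-forward", {
  p <- matrix(c(0, 0, 9, 9), 4, 3)
  expect_equal(unname(variabilityFitness(p, p)), rep(1, 3))
  # A uniform over 4 bins vs P over 2: ratio 2, independent of log base
  pa <- matrix(rep(c(0, 5, 10, 15), 3), 4, 3)
  pp <- matrix(rep(c(0, 0, 9, 9), 3), 4, 3)
  expect_equal(unname(variabilityFitness(pp, pa)), rep(2, 3))
  # zero pro-inflammatory entropy carries the last finite value forward
  pp2 <- cbind(c(0, 0, 9, 9), c(1, 1, 1, 1), c(0, 0, 9, 9))
  pa2 <- cbind(c(0, 5, 10, 15), c(0, 5, 10, 15), c(0, 5, 10, 15))
  f <- variabilityFitness(pp2, pa2)
  expect_equal(unname(f), c(2, 2, 2))
  # and is 0 at t = 1 when undefined from the start
  f0 <- variabilityFitness(matrix(1, 4, 2), pa2[, 1:2])
  expect_equal(unname(f0), c(0, 0))
  expect_error(variabilityFitness(pp, pa[1:3, ]), "misaligned")
})

test_that("synchronization is the mean correlation with the population mean", {
  tr <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  colnames(tr) <- 0:3
  expect_equal(synchronization(tr, tEnd = 3), 1)
  # mirrored halves: the population mean is constant, correlation undefined
  mir <- rbind(1:4, 4:1, 2 * (1:4), 2 * (4:1))
  colnames(mir) <- 0:3
  expect_true(is.na(synchronization(mir, tEnd = 3)))
  # all-constant trajectories are flagged as missing
  flat <- matrix(5, 3, 4, dimnames = list(NULL, 0:3))
  expect_true(is.na(synchronization(flat, tEnd = 3)))
  # bounded in [-1, 1] on random panels
  set.seed(223)
  for (k in 1:20) {
    pan <- matrix(rpois(40, 20), 5, 8, dimnames = list(NULL, 0:7))
    s <- synchronization(pan, tEnd = sample(3:7, 1))
    if (!is.na(s)) expect_true(s >= -1 && s <= 1)
  }
  expect_error(synchronization(tr[, 1:2, drop = FALSE], tEnd = 1), "window")
})

test_that("fitness percentage change matches hand arithmetic", {
  expect_equal(pctChangeFitness(c(1, 2, 3), c(1, 2, 3)), 0)
  f <- c(2, 4, 4, 10)
  expect_equal(pctChangeFitness(f, 1.1 * f), 0.1)
  expect_equal(pctChangeFitness(c(1, 1), c(0, 2)), 1)
  # scale equivariance in the perturbation
  d <- c(0.1, -0.2, 0.3, 0)
  expect_equal(pctChangeFitness(f, f + 2 * d), 2 * pctChangeFitness(f, f + d))
  expect_error(pctChangeFitness(c(0, 0), c(1, 1)), "zero denominator")
  expect_error(pctChangeFitness(1:3, 1:4), "misaligned")
})

test_that("effective concentration follows its closed form", {
  expect_equal(effectiveConcentration(0), 0)
  expect_equal(effectiveConcentration(198), 0.33)
  expect_equal(effectiveConcentration(600), 1)
  expect_equal(effectiveConcentration(c(0, 300), nCells = 10, cellArea = 100),
               c(0, 30))
})

test_that("a null perturbation yields zero sensitivity", {
  cfg <- tinyConfig(nCells = 4L)
  res <- sensitivitySweep(cfg, horizonDays = 1, Dp = 0, replicates = 1,
                          seed = 5)
  expect_equal(nrow(res), 18)
  expect_true(all(res$coefficient == 0))
  expect_true(all(res$DFvar == 0))
})

test_that("the up-perturbation cap reports the realized parameter change", {
  cfg <- tinyConfig(nCells = 4L)
  # pt = 0.70: up by 75% would exceed 1, so the realized change is 0.30/0.70
  res <- sensitivitySweep(cfg, horizonDays = 1, Dp = 0.75, replicates = 1,
                          seed = 5)
  up <- res[res$parameter == "pt" & res$direction == "up", ]
  expect_equal(up$DpRealized, 0.30 / 0.70, tolerance = 1e-12)
  expect_equal(up$Dp, 0.75)
  dn <- res[res$parameter == "pt" & res$direction == "down", ]
  expect_equal(dn$DpRealized, 0.75)
})
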