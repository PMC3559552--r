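test_that("initial count derivation reproduces the published budget chain", {
  hl <- c(IkB = 0.5, NFkB.IkB = 2.5, IKK = 2.5, P = 1.5, A = 1.5,
          E = 2, TLR4 = 2, GR = 2)
  d <- deriveInitialCounts(hl, occupancyFraction = 0.25, cellArea = 1200)
  expect_equal(d$budget, 300)
  expect_equal(sum(d$weights), 29)
  expect_equal(d$f, 10)
  expect_equal(unname(d$counts),
               c(10L, 50L, 50L, 30L, 30L, 40L, 40L, 40L))
  expect_equal(d$lifeScale, 20)
})

test_that("derivation handles the unit baseline and arbitrary weights", {
  hl <- c(IkB = 0.5, NFkB.IkB = 2.5, IKK = 2.5, P = 1.5, A = 1.5,
          E = 2, TLR4 = 2, GR = 2)
  # budget exactly equal to the weight sum: one copy per weight unit
  d <- deriveInitialCounts(hl, occupancyFraction = 29 / 1200, cellArea = 1200)
  expect_equal(d$f, 1)
  expect_equal(unname(d$counts), unname(as.integer(d$weights)))
  # hand-computed case: weights 1,2,3 and budget 60 -> f = 10
  d2 <- deriveInitialCounts(c(a = 0.5, b = 1, c = 1.5),
                            occupancyFraction = 0.05, cellArea = 1200)
  expect_equal(d2$budget, 60)
  expect_equal(d2$f, 10)
  expect_equal(unname(d2$counts), c(10L, 20L, 30L))

  expect_error(deriveInitialCounts(c(a = -1, b = 2)), "positive")
  expect_error(deriveInitialCounts(hl, occupancyFraction = 0.01,
                                   cellArea = 100), "infeasible")
})

test_that("default geometry derives the 11 x 11 nucleus and 20 ticks/hour", {
  cfg <- abmConfig()
  expect_equal(cfg@nucleusSide, 11L)
  expect_equal(cfg@lifeScale, 20L)
  expect_equal(cfg@timeScale, 20L)
  expect_equal(cfg@nCells, 50L)
  expect_equal(cfg@plasmaDims, c(80L, 50L))
  expect_equal(cfg@cellDims, c(40L, 30L))
})

test_that("species table matches the model components", {
  sp <- speciesTable()
  expect_equal(nrow(sp), 14)
  expect_equal(sp$lifetime, 2 * sp$half_life)
  expect_equal(sum(sp$init_per_cell), 290)
  expect_true(all(sp$name[sp$membrane_bound] == "TLR4"))
  # permission matrix spot checks
  expect_false(sp$brain[sp$name == "A"])
  expect_false(sp$brain[sp$name == "M"])
  expect_false(sp$nucleus[sp$name == "F"])
  expect_true(all(sp$plasma[sp$name == "LPS"]))
  expect_false(any(sp[sp$name == "LPS", c("brain", "cytoplasm", "nucleus")] ==
                     TRUE))
})

test_that("world construction honours initial populations and the 10% rule", {
  cfg <- abmConfig()
  w <- worldSnapshot(cfg, seed = 42)
  intra <- w[w$compartment %in% c("cytoplasm", "nucleus"), ]
  percell <- table(intra$cell)
  expect_equal(length(percell), 50L)
  expect_true(all(percell == 290))
  expect_equal(sum(w$species == "P" & w$compartment == "plasma"), 150)
  expect_equal(sum(w$species == "A" & w$compartment == "plasma"), 150)
  # TLR4 sits on the cell boundary
  tlr <- w[w$species == "TLR4", ]
  expect_true(all(tlr$x == 0 | tlr$x == 39 | tlr$y == 0 | tlr$y == 29))
  # nothing starts active, no nucleus residents at t = 0
  expect_false(any(w$active))
  expect_equal(sum(w$compartment == "nucleus"), 0)
})

test_that("a single-cell world gets a 3-molecule plasma pool", {
  w <- worldSnapshot(abmConfig(nCells = 1L), seed = 1)
  expect_equal(sum(w$species == "P" & w$compartment == "plasma"), 3)
})

test_that("world construction is reproducible under a fixed seed", {
  cfg <- tinyConfig()
  expect_identical(worldSnapshot(cfg, seed = 7), worldSnapshot(cfg, seed = 7))
})

test_that("cell state classification follows the 1.5-fold rule", {
  expect_equal(classifyCellState(31, 20), "pro")
  expect_equal(classifyCellState(0, 0), "homeostatic")
  expect_equal(classifyCellState(30, 20), "homeostatic")  # exact tie excluded
  expect_equal(classifyCellState(20, 31), "anti")
  expect_equal(classifyCellState(c(31, 30), c(20, 20)),
               c("pro", "homeostatic"))
  expect_error(classifyCellState(-1, 0), "non-negative")
})

test_that("invalid configurations are rejected", {
  expect_error(abmConfig(nCells = 0), "cells")
  expect_error(abmConfig(probs = c(kp = 2, ki = .7, fi = .7, fa = .7, fm = .7,
                                   mp = .7, pf = .7, pt = .7, ae = .7)),
               "probabilities")
})
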