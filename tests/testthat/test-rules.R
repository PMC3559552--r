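test_that("idle molecules are degraded after one lifetime", {
  # plasma pool of P (lifetime 3 h), nothing else; ages staggered uniformly
  cfg <- abmConfig(nCells = 1L, plasmaInit = c(P = 600, A = 0),
                   defaultRate = 0, disabledRules = c(1, 5, 9))
  cfg <- withInitCounts(cfg, TLR4 = 0, IKK = 0, `NFkB.IkB` = 0, IkB = 0,
                        P = 0, A = 0, E = 0, GR = 0)
  sim <- simulateAbm(cfg, hours = 4, seed = 17, circadian = FALSE)
  p <- systemCounts(sim)["P", ]
  expect_equal(p[["0"]], 600)
  # uniform age staggering: about one third survives each elapsed hour
  expect_lt(abs(p[["1"]] - 400), 60)
  expect_lt(abs(p[["2"]] - 200), 60)
  expect_equal(p[["3"]], 0)
  expect_equal(p[["4"]], 0)
})

test_that("default production runs at R per life-scale step", {
  cfg <- inertConfig(nCells = 2L)
  cfg@defaultRate <- 0.5
  sim <- simulateAbm(cfg, hours = 24, seed = 23, circadian = FALSE)
  ev <- rowSums(eventCounts(sim))
  # 8 intracellular species x 2 cells + 2 brain hormones, 10 units/h each
  expected <- (8 * 2 + 2) * 10 * 24
  expect_lt(abs(ev[["default_prod"]] - expected), 5 * sqrt(expected))

  cfg0 <- inertConfig(nCells = 2L)            # R = 0
  sim0 <- simulateAbm(cfg0, hours = 6, seed = 23, circadian = FALSE)
  expect_equal(rowSums(eventCounts(sim0))[["default_prod"]], 0)
})

test_that("nucleus production fires once per entry at the configured rate", {
  cfg <- abmConfig(nCells = 1L, plasmaInit = c(P = 0, A = 0),
                   defaultRate = 0, disabledRules = c(3L, 20L))
  cfg <- withInitCounts(cfg, TLR4 = 0, IKK = 0, `NFkB.IkB` = 0, IkB = 0,
                        P = 0, A = 0, GR = 0, NFkB = 2000, E = 9000)
  sim <- simulateAbm(cfg, hours = 12, seed = 29, circadian = FALSE)
  ev <- rowSums(eventCounts(sim))
  expect_gt(ev[["entry_NFkB"]], 300)
  fr <- ev[["prod_kp"]] / ev[["entry_NFkB"]]
  se <- sqrt(0.6944 * (1 - 0.6944) / ev[["entry_NFkB"]])
  expect_lt(abs(fr - 0.6944), 4 * se + 0.01)
  # kp and ki draws are independent per entry
  fr2 <- ev[["prod_ki"]] / ev[["entry_NFkB"]]
  expect_lt(abs(fr2 - 0.7008), 4 * se + 0.01)
})

test_that("production is gated by the cell's energy pool", {
  cfg <- abmConfig(nCells = 1L, plasmaInit = c(P = 0, A = 0),
                   defaultRate = 0, disabledRules = c(3L, 20L))
  cfg <- withInitCounts(cfg, TLR4 = 0, IKK = 0, `NFkB.IkB` = 0, IkB = 0,
                        P = 0, A = 0, GR = 0, NFkB = 100, E = 0)
  sim <- simulateAbm(cfg, hours = 4, seed = 31, circadian = FALSE)
  ev <- rowSums(eventCounts(sim))
  expect_gt(ev[["entry_NFkB"]], 0)
  expect_equal(ev[["prod_kp"]], 0)
  expect_equal(ev[["prod_ki"]], 0)
  expect_equal(ev[["e_consumed"]], 0)
})

test_that("nuclear FR excess suppresses NFkB-driven production", {
  cfg <- abmConfig(nCells = 1L, plasmaInit = c(P = 0, A = 0),
                   defaultRate = 0, disabledRules = c(3L, 10L, 20L))
  cfg <- withInitCounts(cfg, TLR4 = 0, IKK = 0, `NFkB.IkB` = 0, IkB = 0,
                        P = 0, A = 0, GR = 0, NFkB = 60, FR = 500, E = 5000)
  sim <- simulateAbm(cfg, hours = 12, seed = 37, circadian = FALSE)
  ev <- rowSums(eventCounts(sim))
  expect_gt(ev[["entry_NFkB"]], 20)
  expect_lt(ev[["prod_kp"]] / ev[["entry_NFkB"]], 0.15)
})

test_that("energy bookkeeping matches stimulated production", {
  sim <- simulateAbm(abmConfig(), hours = 24, seed = 41, circadian = TRUE)
  ev <- rowSums(eventCounts(sim))
  stim <- sum(ev[c("prod_kp", "prod_ki", "prod_pt", "prod_fa", "prod_fi",
                   "prod_mp")])
  expect_equal(ev[["e_consumed"]], stim)
})

test_that("complexation conserves total NFkB mass", {
  cfg <- abmConfig(nCells = 3L, plasmaInit = c(P = 0, A = 0),
                   defaultRate = 0, disabledRules = c(1, 2, 20))
  cfg <- withInitCounts(cfg, TLR4 = 0, IKK = 0, P = 0, A = 0, E = 0, GR = 0,
                        NFkB = 100, IkB = 100, `NFkB.IkB` = 50)
  sim <- simulateAbm(cfg, hours = 8, seed = 43, circadian = FALSE)
  counts <- systemCounts(sim)
  total <- counts["NFkB", ] + counts["NFkB.IkB", ]
  expect_true(all(total == total[1]))
  expect_gt(rowSums(eventCounts(sim))[["complex_formed"]], 0)
})

test_that("disabling P-A annihilation raises steady-state P and A", {
  base <- abmConfig(nCells = 10L)
  on <- simulateAbm(base, hours = 24, seed = 47, circadian = FALSE)
  off <- simulateAbm(abmConfig(nCells = 10L, disabledRules = 9L),
                     hours = 24, seed = 47, circadian = FALSE)
  expect_gt(systemCounts(off)["P", 25], systemCounts(on)["P", 25])
  expect_gt(systemCounts(off)["A", 25], systemCounts(on)["A", 25])
  expect_equal(rowSums(eventCounts(off))[["pa_annihilation"]], 0)
})

test_that("the circadian probability ramp follows the half-sine", {
  expect_equal(endoabm:::cpp_circadian_prob(3, 3, 9), 0)
  expect_equal(endoabm:::cpp_circadian_prob(9, 3, 9), 1)
  expect_equal(endoabm:::cpp_circadian_prob(6, 3, 9), sin(pi / 4))
  expect_equal(endoabm:::cpp_circadian_prob(12, 3, 9), 0)
  # melatonin window wraps midnight: 22:00 -> 2:00
  expect_equal(endoabm:::cpp_circadian_prob(22, 22, 2), 0)
  expect_equal(endoabm:::cpp_circadian_prob(0, 22, 2), sin(pi / 4))
  expect_equal(endoabm:::cpp_circadian_prob(2, 22, 2), 1)
  expect_equal(endoabm:::cpp_circadian_prob(12, 22, 2), 0)
})

test_that("circadian additions stay inside their windows", {
  sim <- simulateAbm(abmConfig(nCells = 5L), hours = 24, seed = 53,
                     circadian = TRUE)
  ev <- eventCounts(sim)
  hrs <- as.numeric(colnames(ev))
  expect_equal(sum(ev["circ_F", hrs >= 9 | hrs < 3]), 0)
  expect_gt(sum(ev["circ_F", hrs >= 3 & hrs < 9]), 0)
  expect_equal(sum(ev["circ_M", hrs >= 2 & hrs < 22]), 0)
  expect_gt(sum(ev["circ_M", hrs >= 22 | hrs < 2]), 0)
  # additions come in batches of c_fm
  expect_equal(sum(ev["circ_F", ]) %% sim@config@cfm, 0)
})

test_that("LPS injection places the exact dose in plasma", {
  cfg <- tinyConfig()
  sim <- simulateAbm(cfg, hours = 12, seed = 59, circadian = FALSE,
                     injections = data.frame(hour = 9, dose = 1000))
  expect_equal(systemCounts(sim)["LPS", "9"], 1000)
  sim0 <- simulateAbm(cfg, hours = 2, seed = 59, circadian = FALSE,
                      injections = data.frame(hour = 1, dose = 0))
  expect_equal(sum(systemCounts(sim0)["LPS", ]), 0)
  sim2 <- simulateAbm(cfg, hours = 2, seed = 59, circadian = FALSE,
                      injections = data.frame(hour = c(1, 1),
                                              dose = c(200, 300)))
  expect_equal(systemCounts(sim2)["LPS", "1"], 500)
  expect_error(simulateAbm(cfg, hours = 2,
                           injections = data.frame(hour = 1, dose = -5)),
               "non-negative")
  expect_error(simulateAbm(cfg, hours = 2,
                           injections = data.frame(hour = 5, dose = 10)),
               "span")
})
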