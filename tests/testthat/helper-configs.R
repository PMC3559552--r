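# shared fixtures: all worlds are built in code, none stored on disk

# a small, fast world for structural tests
tinyConfig <- function(nCells = 5L, ...) {
  abmConfig(nCells = nCells, ...)
}

# override the per-cell initial population of selected species
withInitCounts <- function(config, ...) {
  counts <- c(...)
  sp <- config@species
  for (nm in names(counts)) sp$init_per_cell[sp$name == nm] <- counts[[nm]]
  config@species <- sp
  config
}

# a config whose dynamics are frozen: no production, no degradation,
# no imports, no collision rules, no circadian additions
inertConfig <- function(nCells = 5L, ...) {
  abmConfig(nCells = nCells, defaultRate = 0, lifeScale = 20L,
            disabledRules = c(1:5, 7:21), ...)
}

paramNames <- c("kp", "ki", "fi", "fa", "fm", "mp", "pf", "pt", "ae")

table3Adjusted <- c(kp = 0.6944, ki = 0.7008, fi = 0.7008, fa = 0.7477,
                    fm = 0.2748, mp = 0.6944, pf = 0.2498, pt = 0.7000,
                    ae = 0.7572)
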