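#' @useDynLib endoabm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats lm coef residuals qt sd cor setNames
#' @importFrom utils write.table read.delim packageVersion
NULL

## fixed species order shared with the compiled core
.speciesNames <- c("LPS", "TLR4", "LPSR", "IKK", "NFkB.IkB", "NFkB", "IkB",
                   "P", "A", "E", "F", "GR", "FR", "M")

.paramNames <- c("kp", "ki", "fi", "fa", "fm", "mp", "pf", "pt", "ae")

## published homeostatic calibration (probabilities)
.adjustedProbs <- c(kp = 0.6944, ki = 0.7008, fi = 0.7008, fa = 0.7477,
                    fm = 0.2748, mp = 0.6944, pf = 0.2498, pt = 0.7000,
                    ae = 0.7572)

## species whose abundance each production parameter feeds; two-parameter
## species use the half-adjustment rule during tuning
.paramTargets <- list(
  P = c("kp", "mp"), IkB = c("ki", "fi"), A = "fa", E = "ae",
  TLR4 = "pt", F = "pf", M = "fm")

.eventNames <- c("default_prod", "degrade", "import_attempt", "import",
                 "lps_attempt", "lps_import", "release", "ikk_activated",
                 "nfkb_freed", "complex_formed", "fr_formed", "pa_annihilation",
                 "entry_NFkB", "entry_P", "entry_A", "entry_FR", "entry_M",
                 "entry_IkB", "brain_entry_F", "brain_entry_P",
                 "prod_kp", "prod_ki", "prod_pt", "prod_ae", "prod_fa",
                 "prod_fi", "prod_mp", "prod_fm", "prod_pf",
                 "circ_F", "circ_M", "e_consumed")

#' Species table of the endotoxemia model
#'
#' Static description of the fourteen molecule types: approximate half-life in
#' hours (lifetime is twice the half-life), the initial per-cell copy number of
#' the intracellular species, compartment permissions and whether the species
#' is membrane bound (TLR4 only, once it reaches the cell boundary).
#'
#' @return A \code{data.frame} with one row per species.
#' @examples
#' speciesTable()
#' @export
speciesTable <- function() {
  df <- data.frame(
    name = .speciesNames,
    half_life = c(1, 2, 2, 2.5, 2.5, 2, 0.5, 1.5, 1.5, 2, 1, 2, 2, 1),
    init_per_cell = c(0L, 40L, 0L, 50L, 50L, 0L, 10L, 30L, 30L, 40L, 0L, 40L,
                      0L, 0L),
    membrane_bound = .speciesNames == "TLR4",
    plasma = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
               FALSE, TRUE, FALSE, FALSE, TRUE),
    brain = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
              FALSE, TRUE, FALSE, FALSE, FALSE),
    cytoplasm = c(FALSE, rep(TRUE, 13)),
    nucleus = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  df$lifetime <- 2 * df$half_life
  df
}

#' Derive initial copy numbers, the unit count f, and the life-scale
#'
#' A homeostatic cell is assumed to fill a fixed fraction of its lattice area
#' with molecules. The per-species budget shares are the lifetime ratios
#' relative to the shortest-lived species, so that under balanced production
#' and degradation each species' standing count is production rate times
#' lifetime. \code{f} (the copy number of the shortest-lived species) is the
#' floor of budget over the summed lifetime weights; the life-scale is
#' \code{f / defaultRate} ticks per hour.
#'
#' @param halfLives named positive numeric vector of half-lives (hours) for the
#'   intracellular species.
#' @param occupancyFraction fraction of the cell area occupied by molecules at
#'   homeostasis (default 0.25).
#' @param cellArea cell lattice area in grid units (default 40 x 30 = 1200).
#' @param defaultRate default production probability per life-scale step
#'   (default 0.5).
#' @return list with \code{budget}, \code{weights}, \code{f}, \code{counts}
#'   (named integer vector) and \code{lifeScale}.
#' @examples
#' hl <- c(IkB = 0.5, NFkB.IkB = 2.5, IKK = 2.5, P = 1.5, A = 1.5,
#'         E = 2, TLR4 = 2, GR = 2)
#' deriveInitialCounts(hl)
#' @export
deriveInitialCounts <- function(halfLives, occupancyFraction = 0.25,
                                cellArea = 1200, defaultRate = 0.5) {
  if (any(!is.finite(halfLives)) || any(halfLives <= 0))
    stop("invalid species: half-lives must be positive")
  if (occupancyFraction <= 0 || occupancyFraction >= 1)
    stop("occupancyFraction must lie in (0, 1)")
  budget <- occupancyFraction * cellArea
  weights <- 2 * halfLives / min(2 * halfLives)
  if (budget < sum(weights))
    stop("infeasible budget: ", budget, " < ", sum(weights))
  f <- floor(budget / sum(weights))
  counts <- as.integer(weights * f)
  names(counts) <- names(halfLives)
  list(budget = budget, weights = weights, f = f, counts = counts,
       lifeScale = f / defaultRate)
}

#' Classify a cell's inflammatory state
#'
#' A cell is pro-inflammatory when its pro-inflammatory count exceeds 1.5 times
#' its anti-inflammatory count, anti-inflammatory in the mirrored case, and
#' homeostatic otherwise (exact 1.5-fold ties are homeostatic).
#'
#' @param nP,nA non-negative counts of P and A in the cell (vectorised).
#' @return character vector in \code{c("pro", "anti", "homeostatic")}.
#' @examples
#' classifyCellState(31, 20)
#' classifyCellState(c(30, 0), c(20, 0))
#' @export
classifyCellState <- function(nP, nA) {
  if (any(nP < 0) || any(nA < 0)) stop("counts must be non-negative")
  ifelse(nP > 1.5 * nA, "pro", ifelse(nA > 1.5 * nP, "anti", "homeostatic"))
}

#' Model configuration
#'
#' S4 container of the static model structure: species table, grid geometry,
#' the two clock scales, movement parameters, production probabilities and
#' circadian driver settings. Defaults reproduce the published model: an
#' 80 x 50 plasma grid holding 50 point cells and an 11 x 11 brain region,
#' 40 x 30 cell grids with 11 x 11 nuclei, life-scale 20 ticks/hour,
#' default production rate 0.5, import probability 0.30 and the adjusted
#' production probabilities of the homeostatic calibration.
#'
#' @slot species species table (see \code{\link{speciesTable}}).
#' @slot nCells number of leukocytes.
#' @slot plasmaDims,cellDims integer width/height of the plasma and cell grids.
#' @slot nucleusSide side of the square nucleus (and brain) region.
#' @slot lifeScale,timeScale ticks per hour for life processes and for the
#'   wall-clock/circadian mapping.
#' @slot startHour clock hour at tick 0 (default midnight).
#' @slot defaultRate default production probability per life-scale step.
#' @slot importProb probability a non-LPS plasma molecule is imported on
#'   contact with a cell or the brain.
#' @slot theta molecule-molecule attraction threshold (Chebyshev grid units).
#' @slot cellAttractRadius molecule-cell attraction radius on the plasma grid;
#'   the default 1 pulls molecules adjacent to a cell onto it.
#' @slot waitMax,persistMax random-walk wait (uniform on 0..waitMax ticks) and
#'   persistence (uniform on 1..persistMax steps) bounds.
#' @slot probs named production probabilities kp, ki, fi, fa, fm, mp, pf, pt, ae.
#' @slot cfm circadian addition batch size.
#' @slot cortisolWindow,melatoninWindow onset and peak clock hours of the
#'   sine-ramped hormone additions.
#' @slot plasmaInit optional fixed initial plasma P and A counts (NA = 10 pct
#'   of the summed cellular counts).
#' @slot disabledRules integer rule ids switched off (for experiments/tests).
#' @export
setClass("AbmConfig", representation(
  species = "data.frame",
  nCells = "integer",
  plasmaDims = "integer",
  cellDims = "integer",
  nucleusSide = "integer",
  lifeScale = "integer",
  timeScale = "integer",
  startHour = "numeric",
  defaultRate = "numeric",
  importProb = "numeric",
  theta = "integer",
  cellAttractRadius = "integer",
  waitMax = "integer",
  persistMax = "integer",
  probs = "numeric",
  cfm = "integer",
  cortisolWindow = "numeric",
  melatoninWindow = "numeric",
  plasmaInit = "numeric",
  disabledRules = "integer"))

setValidity("AbmConfig", function(object) {
  msg <- character()
  if (!identical(object@species$name, .speciesNames))
    msg <- c(msg, "species table must keep the canonical species order")
  if (any(object@species$lifetime != 2 * object@species$half_life))
    msg <- c(msg, "lifetime must equal twice the half-life")
  if (length(object@probs) != 9 || !identical(names(object@probs), .paramNames))
    msg <- c(msg, "probs must be the 9 named production probabilities")
  if (any(object@probs < 0 | object@probs > 1))
    msg <- c(msg, "production probabilities must lie in [0, 1]")
  if (object@defaultRate < 0 || object@defaultRate > 1)
    msg <- c(msg, "defaultRate must lie in [0, 1]")
  if (object@importProb < 0 || object@importProb > 1)
    msg <- c(msg, "importProb must lie in [0, 1]")
  if (any(object@plasmaDims < 1) || any(object@cellDims < 1))
    msg <- c(msg, "grid dimensions must be positive")
  if (object@nucleusSide > min(object@cellDims) ||
      object@nucleusSide > min(object@plasmaDims))
    msg <- c(msg, "nucleus/brain region must fit inside its grid")
  if (object@nCells < 1 ||
      object@nCells > prod(object@plasmaDims) - object@nucleusSide^2)
    msg <- c(msg, "cells cannot be placed disjointly on the plasma grid")
  if (object@lifeScale < 1 || object@timeScale < 1)
    msg <- c(msg, "clock scales must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a model configuration
#'
#' @param nCells number of leukocytes (default 50).
#' @param plasmaDims,cellDims grid dimensions (defaults 80 x 50 and 40 x 30).
#' @param nucleusSide side of the nucleus/brain square; the default is derived
#'   from the 10 pct nuclear volume fraction: round(sqrt(0.10 * cell area)).
#' @param lifeScale ticks/hour of life processes; default derived from the
#'   occupancy budget (f / defaultRate = 20).
#' @param timeScale ticks/hour of the wall-clock mapping (default equal to the
#'   life-scale; the calibrated response mapping uses 50).
#' @param startHour clock hour at tick 0 (default 0, midnight).
#' @param defaultRate,importProb,theta,cellAttractRadius,waitMax,persistMax,cfm
#'   see slots.
#' @param probs named production probabilities (default: the published
#'   adjusted calibration).
#' @param cortisolWindow,melatoninWindow circadian windows (defaults 3->9 h and
#'   22->2 h).
#' @param plasmaInit optional c(P=, A=) fixed plasma pools (default NA: 10 pct
#'   rule).
#' @param disabledRules integer rule ids to switch off.
#' @return an \code{\linkS4class{AbmConfig}} object.
#' @examples
#' cfg <- abmConfig(nCells = 10)
#' cfg
#' @export
abmConfig <- function(nCells = 50L,
                      plasmaDims = c(80L, 50L),
                      cellDims = c(40L, 30L),
                      nucleusSide = round(sqrt(0.10 * prod(cellDims))),
                      lifeScale = NULL,
                      timeScale = NULL,
                      startHour = 0,
                      defaultRate = 0.5,
                      importProb = 0.30,
                      theta = 3L,
                      cellAttractRadius = 1L,
                      waitMax = 2L,
                      persistMax = 5L,
                      probs = .adjustedProbs,
                      cfm = 3L,
                      cortisolWindow = c(3, 9),
                      melatoninWindow = c(22, 2),
                      plasmaInit = c(P = NA_real_, A = NA_real_),
                      disabledRules = integer()) {
  sp <- speciesTable()
  if (is.null(lifeScale)) {
    if (defaultRate > 0) {
      hl <- setNames(sp$half_life, sp$name)
      intra <- hl[sp$init_per_cell > 0]
      lifeScale <- deriveInitialCounts(intra, cellArea = prod(cellDims),
                                       defaultRate = defaultRate)$lifeScale
    } else {
      lifeScale <- 20L   # production off: keep the canonical tick rate
    }
  }
  if (is.null(timeScale)) timeScale <- lifeScale
  probs <- probs[.paramNames]
  names(probs) <- .paramNames
  new("AbmConfig", species = sp, nCells = as.integer(nCells),
      plasmaDims = as.integer(plasmaDims), cellDims = as.integer(cellDims),
      nucleusSide = as.integer(nucleusSide),
      lifeScale = as.integer(lifeScale), timeScale = as.integer(timeScale),
      startHour = startHour, defaultRate = defaultRate,
      importProb = importProb, theta = as.integer(theta),
      cellAttractRadius = as.integer(cellAttractRadius),
      waitMax = as.integer(waitMax), persistMax = as.integer(persistMax),
      probs = probs, cfm = as.integer(cfm),
      cortisolWindow = cortisolWindow, melatoninWindow = melatoninWindow,
      plasmaInit = plasmaInit, disabledRules = as.integer(disabledRules))
}

#' @describeIn AbmConfig compact display
#' @param object an \code{AbmConfig}.
#' @export
setMethod("show", "AbmConfig", function(object) {
  cat("AbmConfig:", object@nCells, "cells on a",
      paste(object@plasmaDims, collapse = "x"), "plasma grid\n")
  cat("  cell grid", paste(object@cellDims, collapse = "x"),
      "| nucleus/brain", object@nucleusSide, "x", object@nucleusSide, "\n")
  cat("  life-scale", object@lifeScale, "ticks/h | time-scale",
      object@timeScale, "ticks/h | R =", object@defaultRate, "\n")
  cat("  probs:", paste(sprintf("%s=%.4f", names(object@probs), object@probs),
                        collapse = " "), "\n")
  if (length(object@disabledRules))
    cat("  disabled rules:", paste(object@disabledRules, collapse = ", "), "\n")
})

## assemble the list consumed by the compiled core
.cfgList <- function(config) {
  sp <- config@species
  initP <- sp$init_per_cell[sp$name == "P"]
  initA <- sp$init_per_cell[sp$name == "A"]
  pP <- config@plasmaInit[["P"]]
  pA <- config@plasmaInit[["A"]]
  if (is.na(pP)) pP <- floor(0.10 * config@nCells * initP)
  if (is.na(pA)) pA <- floor(0.10 * config@nCells * initA)
  list(
    plasmaWidth = config@plasmaDims[1], plasmaHeight = config@plasmaDims[2],
    cellWidth = config@cellDims[1], cellHeight = config@cellDims[2],
    nucleusSide = config@nucleusSide, nCells = config@nCells,
    lifeScale = config@lifeScale, timeScale = config@timeScale,
    startHour = config@startHour, defaultRate = config@defaultRate,
    importProb = config@importProb,
    probs = unname(config@probs[.paramNames]),
    theta = config@theta, cellAttractRadius = config@cellAttractRadius,
    waitMax = config@waitMax,
    persistMax = config@persistMax, cfm = config@cfm,
    cortisolWindow = config@cortisolWindow,
    melatoninWindow = config@melatoninWindow,
    halfLife = sp$half_life, initCell = as.integer(sp$init_per_cell),
    plasmaInitP = as.integer(pP), plasmaInitA = as.integer(pA),
    disabledRules = config@disabledRules)
}

#' Initial world snapshot
#'
#' Builds the homeostatic initial state (cells placed disjointly on the plasma
#' grid, per-cell molecule populations with TLR4 on the membrane, 10 pct
#' plasma pools of P and A) and returns it as a molecule table without
#' simulating any tick. Construction is a pure function of the seed.
#'
#' @param config an \code{\linkS4class{AbmConfig}}.
#' @param seed integer RNG seed.
#' @return \code{data.frame} with one row per molecule: species, compartment
#'   (plasma/brain/cytoplasm/nucleus), cell id (NA outside cells), x, y,
#'   active flag.
#' @examples
#' w <- worldSnapshot(abmConfig(nCells = 2), seed = 1)
#' table(w$species)
#' @export
worldSnapshot <- function(config, seed = NULL) {
  stopifnot(is(config, "AbmConfig"))
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  df <- cpp_world_snapshot(.cfgList(config))
  df$species <- factor(.speciesNames[df$species], levels = .speciesNames)
  df$compartment <- factor(c("plasma", "brain", "cytoplasm", "nucleus")
                           [df$compartment + 1L],
                           levels = c("plasma", "brain", "cytoplasm",
                                      "nucleus"))
  df$active <- df$active == 1L
  df
}
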