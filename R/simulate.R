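#' Simulation result container
#'
#' Holds the hourly sampled state of one simulation run: system-wide counts of
#' every species (all compartments), per-cell intracellular counts, the rule
#' event log aggregated per hour, and the per-tick total count of LPS-TLR4
#' complexes (the basis of the effective-concentration statistic).
#'
#' @slot config the \code{\linkS4class{AbmConfig}} that produced the run.
#' @slot hours simulated span in hours.
#' @slot seed RNG seed used (NA if the caller managed the RNG).
#' @slot circadian whether the circadian drivers were enabled.
#' @slot injections data.frame of LPS injections (hour, dose).
#' @slot systemCounts species x (hours + 1) matrix of hourly system counts.
#' @slot cellCounts species x cells x (hours + 1) array of intracellular
#'   counts.
#' @slot events event-type x hour matrix of rule event counts.
#' @slot lpsrPerTick integer vector of total LPSR at each tick.
#' @slot snapshot final molecule table, or NULL.
#' @export
setClass("AbmSimulation", representation(
  config = "AbmConfig",
  hours = "integer",
  seed = "integer",
  circadian = "logical",
  injections = "data.frame",
  systemCounts = "matrix",
  cellCounts = "array",
  events = "matrix",
  lpsrPerTick = "integer",
  snapshot = "ANY"))

setValidity("AbmSimulation", function(object) {
  msg <- character()
  if (nrow(object@systemCounts) != length(.speciesNames))
    msg <- c(msg, "systemCounts must have one row per species")
  if (ncol(object@systemCounts) != object@hours + 1L)
    msg <- c(msg, "systemCounts must hold hours + 1 hourly samples")
  if (any(object@systemCounts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Run the agent-based endotoxemia simulation
#'
#' Simulates the model for a whole number of hours, sampling every species
#' system-wide and per cell on the hour. Time starts at
#' \code{config@startHour} (midnight by default). All stochasticity is driven
#' by R's RNG, so a fixed \code{seed} makes the run bit-reproducible.
#'
#' @param config an \code{\linkS4class{AbmConfig}}.
#' @param hours simulated hours (default 24).
#' @param seed integer seed; NULL leaves the RNG state untouched.
#' @param circadian enable the sine-ramped cortisol/melatonin additions.
#' @param injections NULL or data.frame with columns \code{hour} (hours since
#'   the start of the reported span) and \code{dose} (LPS molecules placed
#'   uniformly at random in the plasma).
#' @param warmupHours hours simulated and discarded before the reported span.
#'   The constructed initial world takes several hours to relax into its
#'   dynamic equilibrium; a warm-up of whole days (default 0) plays the role of
#'   starting from a saved homeostatic state while preserving clock alignment.
#' @param snapshot also return the final molecule table.
#' @return an \code{\linkS4class{AbmSimulation}}.
#' @examples
#' cfg <- abmConfig(nCells = 5)
#' sim <- simulateAbm(cfg, hours = 2, seed = 1)
#' systemCounts(sim)[, 1:3]
#' @export
simulateAbm <- function(config, hours = 24L, seed = NULL, circadian = TRUE,
                        injections = NULL, warmupHours = 0L,
                        snapshot = FALSE) {
  stopifnot(is(config, "AbmConfig"))
  validObject(config)
  hours <- as.integer(hours)
  warm <- as.integer(warmupHours)
  if (hours < 1) stop("hours must be >= 1")
  if (warm < 0) stop("warmupHours must be >= 0")
  if (is.null(injections))
    injections <- data.frame(hour = numeric(), dose = integer())
  if (any(injections$dose < 0)) stop("LPS dose must be non-negative")
  if (length(injections$hour) &&
      any(injections$hour < 0 | injections$hour > hours))
    stop("injection outside the simulated span")
  injTick <- as.integer(round((injections$hour + warm) * config@timeScale))
  if (!is.null(seed)) set.seed(seed)
  tot <- warm + hours
  res <- cpp_simulate(.cfgList(config), tot, injTick,
                      as.integer(injections$dose), circadian, snapshot)
  keepS <- warm + seq_len(hours + 1L)          # hourly samples kept
  sys <- res$systemCounts[, keepS, drop = FALSE]
  dimnames(sys) <- list(.speciesNames, 0:hours)
  cellArr <- array(res$cellCounts,
                   dim = c(length(.speciesNames), config@nCells, tot + 1L))
  cellArr <- cellArr[, , keepS, drop = FALSE]
  dimnames(cellArr) <- list(.speciesNames, NULL, 0:hours)
  ev <- res$events[, warm + seq_len(hours), drop = FALSE]
  dimnames(ev) <- list(.eventNames, seq_len(hours) - 1L)
  lpsr <- res$lpsrPerTick[warm * config@timeScale +
                            seq_len(hours * config@timeScale + 1L)]
  new("AbmSimulation", config = config, hours = hours,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      circadian = circadian, injections = injections,
      systemCounts = sys, cellCounts = cellArr, events = ev,
      lpsrPerTick = lpsr,
      snapshot = if (snapshot) res$snapshot else NULL)
}

#' @rdname AbmSimulation-accessors
#' @export
setGeneric("systemCounts", function(x) standardGeneric("systemCounts"))

#' @rdname AbmSimulation-accessors
#' @export
setGeneric("cellCounts", function(x, species) standardGeneric("cellCounts"))

#' @rdname AbmSimulation-accessors
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))

#' @rdname AbmSimulation-accessors
#' @export
setGeneric("timeOfDay", function(x) standardGeneric("timeOfDay"))

#' @rdname AbmSimulation-accessors
#' @export
setGeneric("cellStates", function(x) standardGeneric("cellStates"))

#' Accessors for simulation results
#'
#' \code{systemCounts} returns the species x time matrix of hourly system-wide
#' counts; \code{cellCounts} the cells x time panel of one species (or the full
#' array); \code{eventCounts} the per-hour rule event log; \code{timeOfDay} the
#' clock hour of each hourly sample; \code{cellStates} the per-cell
#' inflammatory state (pro/anti/homeostatic by the 1.5-fold rule) at each
#' sample.
#'
#' @param x an \code{\linkS4class{AbmSimulation}}.
#' @param species species name (one of the model's fourteen); omit for the
#'   whole array.
#' @return matrix, array or character matrix as described.
#' @name AbmSimulation-accessors
#' @aliases systemCounts cellCounts eventCounts timeOfDay cellStates
NULL

#' @rdname AbmSimulation-accessors
#' @export
setMethod("systemCounts", "AbmSimulation", function(x) x@systemCounts)

#' @rdname AbmSimulation-accessors
#' @export
setMethod("cellCounts", "AbmSimulation", function(x, species) {
  if (missing(species)) return(x@cellCounts)
  stopifnot(species %in% .speciesNames)
  m <- x@cellCounts[species, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, 0:x@hours))
  m
})

#' @rdname AbmSimulation-accessors
#' @export
setMethod("eventCounts", "AbmSimulation", function(x) x@events)

#' @rdname AbmSimulation-accessors
#' @export
setMethod("timeOfDay", "AbmSimulation", function(x)
  (x@config@startHour + 0:x@hours) %% 24)

#' @rdname AbmSimulation-accessors
#' @export
setMethod("cellStates", "AbmSimulation", function(x) {
  p <- cellCounts(x, "P")
  a <- cellCounts(x, "A")
  matrix(classifyCellState(p, a), nrow = nrow(p), dimnames = dimnames(p))
})

#' @describeIn AbmSimulation compact display
#' @param object an \code{AbmSimulation}.
#' @export
setMethod("show", "AbmSimulation", function(object) {
  cat("AbmSimulation:", object@hours, "h,", object@config@nCells, "cells,",
      "time-scale", object@config@timeScale, "ticks/h\n")
  cat("  circadian:", object@circadian,
      "| injections:", nrow(object@injections),
      "| seed:", object@seed, "\n")
  tot <- systemCounts(object)[, ncol(systemCounts(object))]
  cat("  final counts:", paste(sprintf("%s=%d", c("P", "A", "E", "F", "M"),
                                       tot[c("P", "A", "E", "F", "M")]),
                               collapse = " "), "\n")
})

#' Coerce the per-cell panels to a SummarizedExperiment
#'
#' One assay per species (cells x hourly samples), with the sampling hour and
#' clock time as column data. Requires the SummarizedExperiment package.
#'
#' @param sim an \code{\linkS4class{AbmSimulation}}.
#' @return a \code{SummarizedExperiment} with cells as rows.
#' @export
asSummarizedExperiment <- function(sim) {
  stopifnot(is(sim, "AbmSimulation"))
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE) ||
      !requireNamespace("S4Vectors", quietly = TRUE))
    stop("the SummarizedExperiment package is required for this coercion")
  assays <- lapply(.speciesNames, function(s) cellCounts(sim, s))
  names(assays) <- .speciesNames
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(hour = 0:sim@hours,
                                   clock = timeOfDay(sim)))
}
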