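## experiment runners: replicate-averaged homeostasis runs, LPS challenges,
## time-of-day vulnerability sweeps, and tabular output with a run manifest

.replicateSims <- function(config, hours, replicates, seed, circadian = TRUE,
                           injections = NULL, warmupHours = 24L) {
  lapply(seq_len(replicates), function(r)
    simulateAbm(config, hours = hours, seed = seed + r,
                circadian = circadian, injections = injections,
                warmupHours = warmupHours))
}

.meanCounts <- function(sims, species) {
  m <- vapply(sims, function(s) systemCounts(s)[species, ],
              numeric(sims[[1]]@hours + 1L))
  rowMeans(m)
}

.seMat <- function(x) apply(x, 1, sd) / sqrt(ncol(x))

#' Homeostasis experiment under circadian control
#'
#' Simulates \code{days} of the tuned system with circadian drivers and no
#' endotoxin, over seeded replicates, and returns hourly replicate-averaged
#' system counts (with standard errors) for the main species together with the
#' raw simulations.
#'
#' @param config tuned \code{\linkS4class{AbmConfig}}.
#' @param days simulated days (default 2).
#' @param replicates seeded replicate runs; replicate r uses seed + r.
#' @param seed base seed.
#' @param species species to summarise.
#' @param warmupDays discarded warm-up days before the reported span (see
#'   \code{\link{simulateAbm}}).
#' @return list with \code{mean} (species x time), \code{se}, \code{hours}
#'   (sample times), \code{clock} (clock hour of each sample) and \code{sims}.
#' @export
runHomeostasis <- function(config, days = 2, replicates = 20, seed = 1,
                           species = c("P", "A", "E", "F", "M", "NFkB"),
                           warmupDays = 1) {
  hours <- as.integer(days * 24)
  sims <- .replicateSims(config, hours, replicates, seed,
                         warmupHours = as.integer(warmupDays * 24))
  avg <- t(vapply(species, function(sp) .meanCounts(sims, sp),
                  numeric(hours + 1)))
  se <- t(vapply(species, function(sp) {
    m <- vapply(sims, function(s) systemCounts(s)[sp, ], numeric(hours + 1))
    .seMat(m)
  }, numeric(hours + 1)))
  dimnames(avg) <- dimnames(se) <- list(species, 0:hours)
  list(kind = "homeostasis", mean = avg, se = se, hours = 0:hours,
       clock = (config@startHour + 0:hours) %% 24, sims = sims,
       seed = seed, replicates = replicates)
}

#' Endotoxin challenge experiment
#'
#' Starts at midnight of the injection day and simulates \code{days} days with
#' circadian drivers, injecting an LPS bolus at \code{injectionHour}. Returns
#' replicate-averaged panels, the variability-based fitness series, the
#' synchronization series of P and A at trailing 3-h windows, and the
#' effective-concentration series.
#'
#' @param config tuned \code{\linkS4class{AbmConfig}} (time-scale set to the
#'   calibrated response mapping, typically 50).
#' @param dose LPS molecules (default 1000).
#' @param injectionHour clock hour of the bolus (default 9).
#' @param days simulated days (default 2, so every injection time has >= 24 h
#'   of follow-up).
#' @param replicates,seed seeded replicates; replicate r uses seed + r.
#' @param C entropy contraction divisor.
#' @param warmupDays discarded warm-up days before the reported span.
#' @return list with replicate-averaged \code{mean}/\code{se} count panels,
#'   \code{fitness} (mean and se), \code{sync} (P and A levels at 3,6,...,24 h
#'   windows), \code{ec} (mean effective-concentration series, pct, per tick),
#'   \code{ecPeak}, P peak summary, and the raw \code{sims}.
#' @export
runChallenge <- function(config, dose = 1000, injectionHour = 9, days = 2,
                         replicates = 20, seed = 1, C = 5, warmupDays = 1) {
  hours <- as.integer(days * 24)
  if (injectionHour < 0 || injectionHour > hours)
    stop("injection outside the simulated span")
  inj <- data.frame(hour = injectionHour, dose = dose)
  sims <- .replicateSims(config, hours, replicates, seed, injections = inj,
                         warmupHours = as.integer(warmupDays * 24))
  species <- c("P", "A", "E", "F", "M", "NFkB", "LPS", "LPSR")
  avg <- t(vapply(species, function(sp) .meanCounts(sims, sp),
                  numeric(hours + 1)))
  dimnames(avg) <- list(species, 0:hours)

  fits <- vapply(sims, function(s)
    variabilityFitness(cellCounts(s, "P"), cellCounts(s, "A"), C),
    numeric(hours + 1))
  ecs <- vapply(sims, effectiveConcentrationSeries,
                numeric(hours * config@timeScale + 1L))
  syncT <- seq(3, 24, by = 3)
  syncP <- vapply(sims, function(s)
    synchronizationSeries(cellCounts(s, "P"), syncT), numeric(length(syncT)))
  syncA <- vapply(sims, function(s)
    synchronizationSeries(cellCounts(s, "A"), syncT), numeric(length(syncT)))

  meanP <- avg["P", ]
  post <- (injectionHour + 1):hours
  peakHour <- post[which.max(meanP[post + 1])]
  ecMean <- rowMeans(ecs)

  list(kind = "challenge", dose = dose, injectionHour = injectionHour,
       mean = avg, hours = 0:hours,
       clock = (config@startHour + 0:hours) %% 24,
       fitness = list(mean = rowMeans(fits), se = .seMat(fits)),
       sync = list(times = syncT,
                   P = rowMeans(syncP, na.rm = TRUE),
                   A = rowMeans(syncA, na.rm = TRUE),
                   seP = .seMat(syncP), seA = .seMat(syncA)),
       ec = ecMean, ecPeak = max(ecMean),
       pPeakHour = peakHour, pPeakDelay = peakHour - injectionHour,
       sims = sims, seed = seed, replicates = replicates)
}

#' Time-of-day vulnerability sweep
#'
#' Repeats the endotoxin challenge at several injection times and summarises,
#' per time: the per-replicate maximum of the system P count in the 24 h after
#' injection (P_max), the A maximum (A_max) and the minimum of the
#' variability-based fitness (F_var_min), each with standard errors over
#' replicates.
#'
#' @param config tuned \code{\linkS4class{AbmConfig}}.
#' @param times injection clock hours (default 0, 3, ..., 24).
#' @param dose LPS molecules per bolus.
#' @param days simulated days per run (default 2).
#' @param replicates,seed seeded replicates per injection time.
#' @param C entropy contraction divisor.
#' @param warmupDays discarded warm-up days before the reported span.
#' @return data.frame with one row per injection time: Pmax, Amax, FvarMin and
#'   their standard errors.
#' @export
runDoseTimeSweep <- function(config, times = seq(0, 24, by = 3), dose = 1000,
                             days = 2, replicates = 10, seed = 1, C = 5,
                             warmupDays = 1) {
  hours <- as.integer(days * 24)
  rows <- lapply(seq_along(times), function(k) {
    tinj <- times[k]
    inj <- data.frame(hour = tinj, dose = dose)
    sims <- .replicateSims(config, hours, replicates,
                           seed + 10000L * k, injections = inj,
                           warmupHours = as.integer(warmupDays * 24))
    post <- seq(tinj, min(tinj + 24, hours)) + 1   # sample columns
    pmax <- vapply(sims, function(s) max(systemCounts(s)["P", post]),
                   numeric(1))
    amax <- vapply(sims, function(s) max(systemCounts(s)["A", post]),
                   numeric(1))
    fmin <- vapply(sims, function(s)
      min(variabilityFitness(cellCounts(s, "P"),
                             cellCounts(s, "A"), C)[post]), numeric(1))
    data.frame(time = tinj,
               Pmax = mean(pmax), PmaxSE = sd(pmax) / sqrt(replicates),
               Amax = mean(amax), AmaxSE = sd(amax) / sqrt(replicates),
               FvarMin = mean(fmin), FvarMinSE = sd(fmin) / sqrt(replicates))
  })
  out <- do.call(rbind, rows)
  attr(out, "spec") <- list(kind = "dose_time_sweep", dose = dose,
                            days = days, replicates = replicates, seed = seed)
  out
}

#' Write experiment outputs and a reproducibility manifest
#'
#' Emits tidy tab-separated tables (hourly replicate-mean panels, and the
#' statistic tables present in the result) plus \code{manifest.json} holding
#' the full configuration, seeds and package version, sufficient to re-run the
#' experiment bit-identically.
#'
#' @param result a result list from \code{\link{runHomeostasis}},
#'   \code{\link{runChallenge}}, or a \code{\link{runDoseTimeSweep}} frame.
#' @param dir output directory (created if missing).
#' @param config the \code{\linkS4class{AbmConfig}} used (needed for the
#'   manifest when \code{result} does not carry simulations).
#' @return invisibly, the paths written.
#' @export
emitOutputs <- function(result, dir, config = NULL) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- character()
  writeTable <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (is.data.frame(result)) {                    # sweep summary
    writeTable(result, "sweep_summary.tsv")
    spec <- attr(result, "spec")
  } else {
    spec <- result[setdiff(names(result), c("sims", "mean", "se", "fitness",
                                            "sync", "ec", "hours", "clock"))]
    if (!is.null(result$mean)) {
      m <- result$mean
      long <- data.frame(
        hour = rep(as.numeric(colnames(m)), each = nrow(m)),
        species = rep(rownames(m), ncol(m)),
        mean = as.vector(m))
      writeTable(long, "panel_mean.tsv")
    }
    if (!is.null(result$fitness))
      writeTable(data.frame(hour = result$hours,
                            fvar = result$fitness$mean,
                            se = result$fitness$se), "fitness.tsv")
    if (!is.null(result$sync))
      writeTable(data.frame(tEnd = result$sync$times,
                            syncP = result$sync$P, syncA = result$sync$A),
                 "synchronization.tsv")
  }
  if (is.null(config) && !is.data.frame(result) && length(result$sims))
    config <- result$sims[[1]]@config
  manifest <- list(
    package = "endoabm",
    version = as.character(packageVersion("endoabm")),
    spec = spec,
    config = if (!is.null(config)) .cfgList(config))
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
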