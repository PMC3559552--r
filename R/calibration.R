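#' Trend verdict for one species' daily samples
#'
#' Ordinary least-squares regression of hourly counts on time, with a 95 pct
#' confidence interval for the slope (t quantile on n - 2 degrees of freedom),
#' plus the means of the first and last half of the sample vector. A change is
#' called significant - and triggers a parameter adjustment during tuning -
#' when zero lies outside the slope interval and the half-to-half mean shift
#' also exceeds the threshold. Hourly counts are autocorrelated (molecules
#' persist for hours), so the OLS interval alone rejects far too often on
#' stationary series; the mean-shift condition is what makes the verdict
#' usable, with the regression corroborating the direction.
#'
#' @param counts hourly counts over one simulated day (>= 4 samples).
#' @param ciLevel confidence level of the slope interval (default 0.95).
#' @param pctThreshold mean-shift significance threshold (default 0.10).
#' @return list with slope, slopeCI (length 2), m1, m2, pctChange and
#'   significant.
#' @examples
#' fitTrend(rep(40, 24))          # flat: not significant
#' fitTrend(10 + 2 * (0:23))      # exact line: significant
#' @export
fitTrend <- function(counts, ciLevel = 0.95, pctThreshold = 0.10) {
  n <- length(counts)
  if (n < 4) stop("need at least 4 samples")
  x <- seq_len(n) - 1
  fit <- lm(counts ~ x)
  beta1 <- unname(coef(fit)[2])
  se <- sqrt(sum(residuals(fit)^2) / (n - 2) / sum((x - mean(x))^2))
  tq <- qt(1 - (1 - ciLevel) / 2, df = n - 2)
  ci <- beta1 + c(-1, 1) * tq * se
  h <- floor(n / 2)
  m1 <- mean(counts[seq_len(h)])
  m2 <- mean(counts[(n - h + 1):n])
  pct <- if (m1 > 0) (m2 - m1) / m1 else NA_real_
  sig <- (ci[1] > 0 || ci[2] < 0) &&
    (!is.na(pct) && abs(pct) > pctThreshold)
  list(slope = beta1, slopeCI = ci, m1 = m1, m2 = m2, pctChange = pct,
       significant = sig)
}

#' Opposite-direction proportional parameter adjustment
#'
#' The production parameter responsible for a trending species is moved against
#' the trend by the relative mean shift: \code{p' = p * (1 - (m2 - m1)/m1)},
#' clamped to (eps, 1]. When two parameters share responsibility for one
#' species, each moves by half the shift.
#'
#' @param p current probability in (0, 1].
#' @param m1,m2 first- and last-half means of the species' daily samples.
#' @param shared halve the adjustment (two responsible parameters).
#' @param eps lower clamp keeping probabilities positive (default 0.001).
#' @return adjusted probability, or \code{p} unchanged when \code{m1} is 0.
#' @examples
#' adjustParameter(0.70, 10, 12)            # 0.56
#' adjustParameter(0.70, 10, 12, TRUE)      # 0.63
#' @export
adjustParameter <- function(p, m1, m2, shared = FALSE, eps = 0.001) {
  if (m1 <= 0) return(p)
  delta <- (m2 - m1) / m1
  if (shared) delta <- delta / 2
  min(max(p * (1 - delta), eps), 1)
}

#' Tune production parameters to homeostasis
#'
#' The calibration of the model: with circadian drivers and endotoxin disabled,
#' the system is simulated one day at a time; each monitored species' hourly
#' system-wide counts are tested for a significant trend
#' (\code{\link{fitTrend}}) and, when significant, the responsible production
#' parameter(s) are adjusted against the trend
#' (\code{\link{adjustParameter}}). The procedure stops when no parameter has
#' changed for \code{convergenceDays} consecutive simulated days.
#'
#' Monitored species and their parameters: P (kp, mp), IkB (ki, fi), A (fa),
#' E (ae), TLR4 (pt), F (pf), M (fm); two-parameter species use the
#' half-adjustment rule.
#'
#' @param config an \code{\linkS4class{AbmConfig}}; its time-scale should equal
#'   the life-scale during calibration.
#' @param initialProbs starting probabilities (default all 0.70).
#' @param maxRounds cap on simulated days (default 60).
#' @param convergenceDays consecutive unchanged days required (default 3).
#' @param warmupDays days simulated and discarded before the sampled day, so
#'   trends are measured on the relaxed state rather than on the constructed
#'   world's settling transient (default 1).
#' @param replicates independent simulated days averaged per round before the
#'   trend tests (default 4). With a few dozen molecules per hormone species,
#'   a single day's hourly series is noisy enough that the 10 pct mean-shift
#'   test fires on sampling noise alone; averaging reduces the variance of the
#'   verdicts without changing the thresholds.
#' @param seed base seed; day d, replicate r uses seed + 100 * d + r.
#' @param pctThreshold,ciLevel passed to \code{\link{fitTrend}}.
#' @return list with \code{probs} (tuned named vector), \code{converged},
#'   \code{rounds}, \code{config} (the input config carrying the tuned probs)
#'   and \code{history} (one row per species per round).
#' @export
tuneHomeostasis <- function(config,
                            initialProbs = setNames(rep(0.70, 9), .paramNames),
                            maxRounds = 60, convergenceDays = 3,
                            warmupDays = 1, replicates = 4, seed = 1,
                            pctThreshold = 0.10, ciLevel = 0.95) {
  stopifnot(is(config, "AbmConfig"))
  probs <- initialProbs[.paramNames]
  names(probs) <- .paramNames
  stable <- 0
  hist <- list()
  round <- 0
  warm <- as.integer(warmupDays * 24)
  while (round < maxRounds && stable < convergenceDays) {
    round <- round + 1
    cfg <- config
    cfg@probs <- probs
    reps <- lapply(seq_len(replicates), function(r)
      systemCounts(simulateAbm(cfg, hours = 24L, warmupHours = warm,
                               seed = seed + 100L * round + r,
                               circadian = FALSE)))
    counts <- Reduce(`+`, reps) / replicates
    changed <- FALSE
    for (spName in names(.paramTargets)) {
      v <- fitTrend(counts[spName, 1:24], ciLevel = ciLevel,
                    pctThreshold = pctThreshold)
      pars <- .paramTargets[[spName]]
      if (v$significant) {
        for (par in pars) {
          newp <- adjustParameter(probs[[par]], v$m1, v$m2,
                                  shared = length(pars) > 1)
          if (newp != probs[[par]]) changed <- TRUE
          probs[[par]] <- newp
        }
      }
      hist[[length(hist) + 1]] <- data.frame(
        round = round, species = spName, slope = v$slope,
        ciLow = v$slopeCI[1], ciHigh = v$slopeCI[2], pctChange = v$pctChange,
        significant = v$significant)
    }
    stable <- if (changed) 0 else stable + 1
  }
  converged <- stable >= convergenceDays
  if (!converged)
    warning("tuning did not converge within ", maxRounds, " rounds")
  cfg <- config
  cfg@probs <- probs
  list(probs = probs, converged = converged, rounds = round, config = cfg,
       history = do.call(rbind, hist))
}

#' Search the time-scale matching the in vivo response timing
#'
#' The life-scale anchors lifetimes and production to hours; the time-scale is
#' chosen so the simulated pro-inflammatory peak after a morning endotoxin
#' bolus falls in the observed 2-6 h post-injection window. Candidates are
#' tried in increasing order and the smallest scale whose replicate-averaged
#' P peak (3-point moving-average smoothed) lies inside the window is chosen.
#'
#' @param config tuned \code{\linkS4class{AbmConfig}}.
#' @param candidates time-scales to try, ticks/hour (default 20, 30, 40, 50).
#' @param window acceptance window, hours post injection (default c(2, 6)).
#' @param dose,injectionHour endotoxin bolus (default 1000 at 9:00).
#' @param replicates seeded runs per candidate (default 5).
#' @param warmupDays discarded warm-up days before the injection day.
#' @param seed base seed.
#' @return list with \code{chosen} (or NA if none matches) and
#'   \code{peakTimes} (named by candidate).
#' @export
searchTimeScale <- function(config, candidates = c(20, 30, 40, 50),
                            window = c(2, 6), dose = 1000, injectionHour = 9,
                            replicates = 5, warmupDays = 1, seed = 1) {
  stopifnot(is(config, "AbmConfig"))
  peaks <- setNames(numeric(length(candidates)), candidates)
  chosen <- NA_real_
  for (k in seq_along(candidates)) {
    cfg <- config
    cfg@timeScale <- as.integer(candidates[k])
    hours <- injectionHour + 15
    sims <- lapply(seq_len(replicates), function(r)
      simulateAbm(cfg, hours = hours, seed = seed + 100L * k + r,
                  circadian = TRUE, warmupHours = as.integer(warmupDays * 24),
                  injections = data.frame(hour = injectionHour, dose = dose)))
    p <- rowMeans(vapply(sims, function(s) systemCounts(s)["P", ],
                         numeric(hours + 1)))
    sm <- stats::filter(p, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- p[is.na(sm)]
    post <- (injectionHour + 1):hours
    peaks[k] <- post[which.max(sm[post + 1])] - injectionHour
    if (is.na(chosen) && peaks[k] >= window[1] && peaks[k] <= window[2])
      chosen <- candidates[k]
  }
  list(chosen = chosen, peakTimes = peaks)
}
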