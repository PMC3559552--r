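# endoabm

An agent-based model of acute systemic inflammation (human endotoxemia) under
circadian control, for computational immunologists studying cell-to-cell
variability and time-of-day effects in the innate immune response.

Fifty leukocytes live as point agents on an 80 x 50 plasma lattice that also
embeds an 11 x 11 brain region; each cell owns a 40 x 30 lattice with an
11 x 11 nucleus. Fourteen molecule species — LPS, TLR4 and their complex
LPSR; the NFkB signalling proxy (IKK, NFkB.IkB, NFkB, IkB); aggregate pro-
and anti-inflammatory cytokines P and A; bio-energetic proteins E; and the
hormone layer cortisol (F), its receptor (GR), their complex (FR) and
melatonin (M) — perform Moore-neighbourhood random walks, collide according
to twenty interaction rules, and fire per-nucleus-entry Bernoulli
transcription draws (probabilities kp, ki, pt, ae, fa, fi, mp, plus the brain
pathways pf and fm). Cortisol and melatonin are added in the brain on
half-sine circadian ramps (3:00-9:00 and 22:00-2:00). Molecule lifetimes are
twice their half-lives; a cell's initial populations follow the lifetime
ratios of its species under the homeostatic budget `f = floor(0.25 x 1200 /
29) = 10`, which also fixes the life-scale at `f / R = 20` ticks per hour.

On top of the simulator the package implements:

* **homeostasis tuning** — the trend-analysis calibration (OLS slope CI +
  10% half-day mean-shift) that adjusts production probabilities until no
  monitored species drifts for three consecutive simulated days;
* **time-scale search** — raising the wall-clock tick rate (20 -> 30 -> 40 ->
  50 ticks/hour) until the pro-inflammatory peak after a morning LPS bolus
  matches the 2-6 h in vivo window;
* **population statistics** — the variability-based fitness
  `F_var(t) = H_A(t) / H_P(t)` (Shannon entropies of contracted per-cell
  counts), synchronization (mean per-cell correlation with the population
  mean over trailing 3 h windows), percentage change of fitness
  `sum|F0 - F1| / sum F0`, sensitivity coefficients `DF_var / Dp` under ±75%
  parameter perturbations, and the effective LPS concentration
  `100 x LPSR_total / (50 x 1200)`;
* **experiment runners** — seeded, replicate-averaged homeostasis runs, LPS
  challenges and time-of-day vulnerability sweeps, with tab-separated outputs
  and a JSON manifest that reproduces any run bit-identically.

## A worked example

```r
library(endoabm)

cfg <- abmConfig()          # published configuration, life-scale 20 ticks/h
cfg@timeScale <- 50L        # calibrated response mapping

# one seeded challenge: 1000 LPS molecules at 9:00, one day of follow-up
ch <- runChallenge(cfg, dose = 1000, injectionHour = 9, days = 1.5,
                   replicates = 4, seed = 1)
round(ch$mean["P", 9:16])
#>   8   9  10  11  12  13  14  15
#> 242 230 303 566 616 561 519 454
ch$pPeakDelay
#> [1] 3
round(ch$ecPeak, 2)
#> [1] 0.85
round(ch$fitness$mean[c(9, 12, 14, 20)], 2)
#>    8   11   13   19
#> 1.82 0.92 0.77 0.93
```

The pro-inflammatory count (here the system-wide total over all 50 cells and
the plasma) rises from its homeostatic level of about 250 to a peak of about
600 three hours after the bolus, then decays toward its circadian pattern.
The effective concentration peaks below 1% of the total cellular volume, and
the variability-based fitness drops from ~1.8 to ~0.8 within four hours
(anti- and pro-inflammatory cell-to-cell entropies converging and diverging,
respectively) before recovering.

A homeostatic run with circadian drivers shows the hormone architecture:

```r
hm <- runHomeostasis(cfg, days = 2, replicates = 8, seed = 1)
# cortisol peaks at the end of its 3:00-9:00 window, melatonin near 2:00,
# and the pro-inflammatory level crests around 3:00-4:00
```

A thin command-line runner over the same functions lives at
`inst/scripts/endoabm.R` (verbs: `tune`, `timescale`, `run`, `challenge`,
`sweep`, `sensitivity`).

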