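---
title: "An agent-based model of endotoxemia under circadian control: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of endotoxemia under circadian control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoabm)
```

# The model

`endoabm` simulates the acute inflammatory response to bacterial endotoxin
(LPS) in a population of circulating leukocytes as a stochastic lattice
agent-based model. Fourteen molecule types are discrete agents: LPS and its
receptor TLR4; the bound complex LPSR; the NFkB signalling proxy (IKK kinase,
the inactive NFkB.IkB complex, free NFkB, the inhibitor IkB); aggregate
pro-inflammatory (P) and anti-inflammatory (A) cytokines; bio-energetic
proteins (E); and the circadian hormone layer (cortisol F, its receptor GR,
the active complex FR, melatonin M).

Space is a set of unitless rectangular grids. The plasma is an 80 x 50
lattice embedding an 11 x 11 brain region and 50 stationary point cells; each
cell owns a private 40 x 30 lattice whose central 11 x 11 square is the
nucleus (the nuclear side is `round(sqrt(0.10 * 1200)) = 11`, from a 10%
nuclear volume fraction). Molecules perform Moore-neighbourhood random walks:
an agent waits a uniform 0-2 ticks between moves and keeps a direction for a
uniform 1-5 steps before redrawing (the published model description leaves
these distributions open; short-memory uniform choices are configurable
defaults).
Interactive pairs within a Chebyshev distance of `theta = 3` steer toward
each other; molecules adjacent to a cell's plasma point are pulled onto it
(the molecule-cell pull uses adjacency, radius 1, following the wording that
the rule applies to molecules *adjacent* to cells).

## Initial populations and the two clock scales

A homeostatic cell is assumed to hold molecules on about 25% of its area
(300 of 1200 sites). Because balanced turnover fixes a species' standing
count at production rate x lifetime, the initial counts are distributed as
lifetime ratios relative to the shortest-lived species (IkB, half-life
0.5 h): weights (1, 5, 5, 3, 3, 4, 4, 4) for IkB, NFkB.IkB, IKK, P, A, E,
TLR4, GR sum to 29, giving `f = floor(300/29) = 10` copies of IkB and 290
molecules per cell. The life-scale is `S_l = f / R = 20` ticks per hour at
the default production rate `R = 0.5`. A second clock, the time-scale
`T_sc`, maps ticks to wall-clock hours for circadian windows and response
timing; it is calibrated separately (below). Life processes (default
production, degradation aging, circadian additions) are scheduled so their
*hourly* rates are invariant to `T_sc`: per-tick probabilities are scaled by
`S_l / T_sc`, and a molecule is degraded once it has gone one lifetime
(2 x half-life, in hours, i.e. `lifetime x T_sc` ticks) without any event
other than movement. What `T_sc` does change is movement per hour - more
ticks per hour mean more steps and therefore more contacts per hour, which is
exactly the lever the time-scale search uses to match response timing.

Initial molecule ages are staggered uniformly over one lifetime so the
renewal process starts at its stationary age distribution; otherwise the
whole initial population would degrade in a synchronized wave.

## Rules

Collisions on a shared lattice site fire the interaction rules: LPSR or an
imported P activates IKK; an activated IKK converts one NFkB.IkB complex to
free NFkB; NFkB and IkB recombine into the complex; F binds GR to form FR; P
and A of equal import status annihilate each other. Two readings deserve
comment, both adopted after the literal alternative proved structurally
unstable:

* **Kinase firing is one-shot.** An activated IKK returns to inactive after
  liberating one NFkB, and an imported P is consumed by the hand-off that
  activates IKK (LPSR, a membrane-derived receptor complex, persists).
  Without this, catalysts are effectively immortal - every interaction
  resets the idle-degradation clock - and the homeostatic state runs away
  (the complex pool collapses and free NFkB grows without bound), which
  contradicts the stable homeostasis the model is built to hold.
* **Import is one attempt per approach.** A molecule that fails an import
  check becomes refractory for that target until it diffuses out of the
  attraction neighbourhood. With on-arrival re-attempts every tick, the
  deterministic attraction step makes each cell an absorbing trap and the
  printed per-contact probabilities (30% for cytokines and hormones, the
  TLR4 boundary-occupancy check for LPS) lose observable meaning.

Nucleus entries drive transcription: each eligible molecule (NFkB, IkB, FR,
and imported P, A, M) that crosses into the nucleus makes one Bernoulli draw
per product - NFkB produces P (`kp`) and IkB (`ki`), suppressed while
nuclear FR outnumbers nuclear NFkB; P produces TLR4 (`pt`, routed to a free
membrane position); A produces E (`ae`); FR produces A (`fa`) and IkB
(`fi`); M produces P (`mp`). Draws are per *entry*, not per tick: with
probabilities near 0.7 a per-tick draw would diverge. Production requires a
positive energy pool; each stimulated production deletes one E and inhibits
the default E production for the rest of the hour. The one exception is
`ae` itself: a production of E that consumed an E and switched off E
replenishment would be a net no-op, so the energy cost is not applied to the
pathway whose product *is* energy. In the brain, P produces F (`pf`) and F
produces M (`fm`, blocked while brain P exceeds twice brain F). Melatonin
cannot reside in the brain compartment, yet the rules produce it there; M
created by brain activity therefore spawns at a brain-region lattice point
with plasma status, i.e. it circulates immediately. Likewise the NFkB.IkB
complex is cytoplasm-only, so a complex formed by a nuclear encounter is
placed at the nearest cytoplasmic position outside the nucleus region.

Every cell and the brain also run a default production: each resident
species gains one unit per life-scale step with probability `R`, i.e. 10
units per hour per species per cell (and F, M in the brain). Locally
produced (inactive) P and A that reach the membrane are released to plasma;
imported molecules are never re-exported.

## Circadian drivers

Cortisol is added to the brain in batches of `c_fm = 3` between 3:00 and
9:00, melatonin between 22:00 and 2:00, with per-tick probability
`sin(pi/2 x elapsed-fraction-of-window) x S_l / T_sc`. The `S_l / T_sc`
factor keeps the hourly addition rate equal to that of the system in which
the batch size was originally chosen; without it, raising the time-scale to
50 would have multiplied hormone input by 2.5 while leaving every other
hourly rate unchanged.

# Calibration

## Homeostasis tuning

With circadian drivers and LPS off, each production parameter is adjusted so
that no monitored species (P, IkB, A, E, TLR4, F, M) changes significantly
over a simulated day. A day's hourly series is tested with an OLS slope
(95% CI on n-2 degrees of freedom) and the relative shift between the
half-day means; a change is significant - and triggers the
opposite-direction proportional adjustment `p' = p (1 - (m2-m1)/m1)`, halved
when two parameters share a species - only when the CI excludes zero *and*
the shift exceeds 10%. Hourly counts are strongly autocorrelated, so the OLS
interval alone rejects on a third to a half of stationary days; requiring
the shift as well is what makes the stated convergence criterion (no change
in any parameter for three consecutive days) attainable. Two variance
controls are applied, with thresholds untouched: each round's series is the
average of a few independent simulated days (default 4), and each round
discards a warm-up day, because the constructed initial world needs several
hours to relax into its dynamic equilibrium (tuning should react to genuine
drift, not to the settling transient). Rounds restart from the constructed
world rather than continuing one trajectory, which makes them exchangeable;
the warm-up plays the role of re-loading a saved homeostatic state.

Tuning from all-70% starting values converges in a handful of rounds and
leaves most parameters near 0.70; the direction of the adjustments it does
make (reducing the brain hormone parameters) matches the direction of the
published calibration, though not its exact values - those depend on
implementation details of the original simulator that are not recoverable,
and only the stability property is claimed here. The package ships the
published adjusted probabilities as `abmConfig()` defaults, since those are
the documented operating point of the model the experiments reproduce.

## Time-scale search

At `T_sc = S_l = 20` the pro-inflammatory peak after a 9:00, 1000-molecule
LPS bolus arrives about 5-6 h post-injection, slower than the 2-4 h observed
in vivo. `searchTimeScale()` raises the time-scale through 20, 30, 40, 50
and selects the smallest value whose replicate-averaged, 3-point-smoothed P
peak falls in the acceptance window (default 2-6 h; the in-vivo-matching
window is an operationalization, not a printed value, and is configurable).
At time-scale 50 the peak arrives 2-3 h post-injection, matching the
observed timing; the exact scale the search returns depends on the window
and seed because the slow-scale peak sits near the default window's upper
edge. The challenge experiments use the calibrated value of 50.

# Population statistics

*Variability-based fitness.* Cell-to-cell variability of a cytokine is the
Shannon entropy of the per-cell counts after floor-division by a contraction
divisor `C = 5` (the divisor used originally is not recoverable; 5 keeps
30-molecule-scale counts in a handful of bins and is configurable). The
fitness is `F_var(t) = H_A(t) / H_P(t)` - anti-inflammatory in the
numerator so the statistic *falls* when endotoxin disperses the
pro-inflammatory response across cells; the ratio is invariant to the
entropy log base. When `H_P` is zero the previous finite value is carried
forward (0 at the first sample).

*Synchronization.* The mean Pearson correlation between each cell's
trajectory and the population-mean trajectory over a trailing 3 h window.
With hourly sampling a window holds 4 points, so individual correlations are
noisy; replicate averaging absorbs this, and all-constant windows are
reported as missing rather than coerced to a number.

*Percentage change of fitness and sensitivity.* The effect of a parameter
perturbation is `DF_var = sum |F0 - F1| / sum F0` over a horizon of
circadian days, and the sensitivity coefficient is `DF_var / Dp` with
`Dp = 0.75`, capping perturbed probabilities at 1 and using the realized
relative change in the denominator when the cap binds. At very small `Dp`
the statistic is dominated by stochastic divergence between runs, so
coefficients are meaningful for the large perturbations the protocol
prescribes, not as local derivatives.

*Effective concentration.* `100 x total LPSR / (50 x 1200)`, in percent.
After the 9:00 bolus of 1000 LPS at the pre-search time-scale of 20 the peak
is a little under 0.5%; at time-scale 50 contact rates per hour are 2.5-fold
higher and the same bolus converts more completely (~0.9%). The printed
reference value belongs to the pre-search experiment, which is how the
acceptance script computes it.

# What the simulations show (and what they cannot)

Under the published parameters the model holds a stable homeostatic state
near the configured initial populations and reproduces the qualitative
circadian architecture: cortisol peaks at ~9:00 (window end), melatonin at
~2:00, the pro-inflammatory level crests at ~3:00-4:00 driven by nocturnal
melatonin import, the anti-inflammatory level dips in the early morning and
recovers under cortisol, and the energy pool sags near midday when
stimulated production is most active. The morning cortisol surge, however,
rises about 5-fold over its baseline rather than the stated ~3-fold: with
the printed batch size of 3 and any tick-based addition schedule consistent
with the text, the addition flux during the window is several times the
baseline brain production, and no defensible reading we found brings the
fold to 3 without changing a printed value. The fold is reported as computed.

An LPS bolus at 9:00 with time-scale 50 produces a fast P surge peaking
2-3 h post-injection that decays back toward the circadian pattern, a drop
in the variability-based fitness bottoming 3-5 h post-injection with
recovery afterwards, and a transient synchronization spike of the
pro-inflammatory (but not anti-inflammatory) responses in the first windows
after treatment. The anti-inflammatory count initially dips (annihilation
against the P surge) before recovering - the in vivo pattern keeps rising
instead, a known abstraction cost of representing inhibition as pairwise
annihilation.

The synthetic world is the study system itself (the model *is* the object
of study); no external data are consumed. Passing tests demonstrate
internal consistency - budget arithmetic, rule semantics, statistical
estimators against brute-force oracles, determinism under seeds - and the
qualitative reproduction of the reference dynamics at reduced replicate
counts. They do not validate the model against clinical measurements beyond
the qualitative patterns described above.

## Problem sizes used by the test-suite and acceptance script

Replicate counts are scaled to keep full runs economical: tuning averages
4 days per round; phase and challenge targets use about 20 replicates of 2-3
simulated days; the time-of-day sweep uses 9 injection times at 5-6
replicates; the sensitivity ranking uses a 3-day horizon at a handful of
replicates per perturbation. The reference protocol's N = 100 replicates and
10-day sensitivity horizon are available through the exported functions and
the command-line runner (`inst/scripts/endoabm.R`).

# Known limitations

* Exact published parameter values after tuning are not reproducible; only
  the stability property and adjustment directions are.
* The cortisol fold-change overshoots the stated 3x (discussed above).
* The sensitivity ranking of the reference protocol does not emerge at
  feasible replicate counts: per-entry transcription fluxes are a few percent
  of the default-production churn, so the fitness responds weakly to any
  single cytoplasmic production parameter and the percentage-change-of-fitness
  differences between parameters sit at the stochastic noise floor (all 18
  perturbations score within ~0.03 of each other at the test scale). Only the
  brain hormone parameters (fm, pf), which gate a large share of their
  species' input, have real leverage.
* FR, the cortisol-receptor complex, has no production parameter and relaxes
  over more than one simulated day; stability checks therefore warm up two
  days before sampling it.
* Effective-concentration depends on the time-scale through per-hour contact
  rates; the value is anchored to the pre-search experiment.
* Hourly sampling makes 3 h synchronization windows short (4 points);
  levels are comparable across conditions but are not precise correlations.
* Cells are stationary point agents; there is no collision exclusion,
  chemotaxis, receptor trafficking, or mRNA/protein distinction - the
  abstraction level of the reference model is kept deliberately.
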