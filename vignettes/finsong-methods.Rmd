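---
title: "Singing and swimming: methods behind the finsong pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Singing and swimming: methods behind the finsong pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finsong)
```

Male fin whales (*Balaenoptera physalus*) sing long sequences of short,
intense "20 Hz" notes, and they sing while swimming. When a singer can be
tracked acoustically over tens of hours, two behavioural quantities can be
paired for every portion of his track: how fast he was swimming and how much
of the time he was singing. `finsong` implements that pairing end to end —
from note detections and localizations to songs, bouts, track segments,
duty-cycles, behavioural regimes and additive smooth models of singing
against speed and season — together with a synthetic singer simulator that
provides ground truth for every stage.

This vignette explains the models and conventions the package uses, why the
defaults are what they are, and what the bundled tests do and do not
demonstrate.

## From notes to songs

A fin whale song is a series of regularly spaced 20 Hz notes. The assembler
(`assemble_songs()`) scans each singer's time-ordered note stream and grows a
candidate song while the start-to-start interval between successive notes
stays at or below `note_break` (30 s); an interval greater than 30 s ends the
candidate, and candidates with fewer than `min_notes` (3) notes are
discarded. Song duration runs from the start of the first note to the end of
the last.

Two conventions are worth making explicit:

* **Interval endpoints.** Inter-note-intervals are measured start-to-start.
  Note durations (~1 s) are small against typical intervals (9–20 s), and
  detection start times are the robust quantity in practice.
* **Intervals between 20 s and 30 s.** The 9–20 s band is characteristic of
  present-day North Atlantic song but the only hard break rule is the 30 s
  one, so intervals in (20, 30] s keep a song growing. The fraction of a
  song's intervals inside the typical band is reported per song
  (`frac_typical_ini`) as a regularity diagnostic, not used for exclusion.

## The bout-ending criterion

Silences between songs mix two processes: short within-bout rests (breathing
pauses, typically 3–10 min) and long between-bout silences. Following the
log-survivorship tradition of bout analysis, `fit_biexponential()` fits

$$y(t) = a_f e^{-\lambda_f t} + a_s e^{-\lambda_s t}$$

to the binned interval counts, with squared error measured on
$\log_{10}$ counts. The bout-ending criterion (BEC) is the crossing time of
the two fitted components,

$$t^\* = \frac{\ln(a_f / a_s)}{\lambda_f - \lambda_s},$$

the interval length at which an interval is equally likely to belong to
either process; calling longer intervals "between-bout" minimizes the
expected mass of misassigned intervals under the fitted model. The pipeline
rounds $t^\*$ to the nearest minute as the operational criterion and splits
bouts at inter-song-intervals greater than or equal to it
(`segment_bouts()`).

Numerical choices, all surfaced as arguments or diagnostics:

* **Loss space.** The fit is to the log frequency distribution; bins with
  zero count are dropped rather than offset with pseudocounts.
* **Sparse-tail rebinning.** Before fitting, adjacent sparse bins — empty
  bins included — are merged until every merged bin holds at least three
  events, and merged counts are normalized back to the base bin width. If
  empty bins are simply dropped, only occupied bins survive far into the
  tail and the apparent slow decay flattens, biasing $\lambda_s$ low; the
  merged bins remove that bias while keeping the tail's information.
* **Weights.** Residuals are weighted by $\sqrt{\text{count}}$, the
  approximate inverse standard deviation of a log Poisson count, so the
  well-populated head does not get out-voted by dozens of single-count tail
  bins.
* **Initialization and restarts.** Biexponential least squares is
  multimodal. The fast rate starts from the slope of the first quartile of
  bins, the slow component from the last quartile, the fast amplitude by
  back-projection; the optimizer restarts from ten jittered versions of that
  start and keeps the best residual. The jitter uses a private RNG stream,
  so fits are deterministic and the caller's RNG is untouched.
* **Evidence guards.** A fit only yields a BEC when the data support two
  processes: the rate ratio must satisfy $\lambda_f/\lambda_s \ge 3$ (the
  crossing is numerically unstable as rates converge), and the biexponential
  must at least halve the weighted squared error of the best
  single-exponential fit. Single-process data raise an error, and the
  pipeline then falls back to the configured default criterion (35 min).
* **Bin width.** Default 1 min, configurable; `bec_diagnostics()` reports
  the sensitivity of the BEC to bin width, alongside an alternative
  "density" reading of the crossing in which amplitudes are treated as
  component masses (the two readings differ by
  $\ln(\lambda_f/\lambda_s)/(\lambda_f-\lambda_s)$).

## Track kinematics and the trailing duty-cycle

Localizations are turned into track segments (`build_segments()`): one
segment per successive pair of locations, with great-circle distance on a
sphere of radius 6371 km (ellipsoidal refinement is pointless at 10–430 km
scales with kilometre-level localization noise; a planar x/y-km mode serves
synthetic scenarios) and speed = distance / elapsed time.

The amount of singing attached to each segment is the **trailing
duty-cycle**: the percentage of the last 30 min of the segment spent singing
(`segment_duty_cycle()`). Conventions:

* The window is intersected with the segment span; segments shorter than
  30 min use their full span, and the window actually used is recorded
  (`window_used_min`), so no singing time is borrowed from the previous
  segment.
* Songs straddling a window edge contribute exactly their overlap — interval
  intersection arithmetic, no rasterization.
* Silence is silence: a between-bout gap falling inside a window counts as
  non-singing time regardless of bout bookkeeping.

Segments are classified as robust (duty-cycle ≥ 70%) or intermittent
singing, and as slow or fast swimming (≥ 7 km/h, the cohort mean track speed
rounded to an integer). Both thresholds are inclusive at the boundary and
live in `analysis_config()`. Tracks enter the cohort analysis only with at
least 3 locations and at least 1 h of duration (`filter_tracks()`), and
tracks — never pooled segments — are the unit of all cohort statistics: each
whale is represented once.

## Cohort statistics and models

`cohort_summary()` reports the mean of per-track means with its standard
error, plus the dispersion of track means and the means of per-track minima
and maxima. `speed_duty_histogram()` builds the two-dimensional speed ×
duty-cycle histogram on a 1 km/h × 5% grid (log10 counts; empty cells stay
blank) and summarizes its bimodality as the fraction of segments in the
75–90% and 0–5% duty-cycle bands. `paired_speed_test()` compares per-singer
mean speeds while singing and while silent between bouts with a classic
matched-pairs t-test (singers need at least two bouts to contribute a pair).

The headline models (`fit_additive_model()`) are generalized additive
models, identity link and Gaussian errors, of per-track mean duty-cycle and
mean song duration on smooths of swimming speed, number of songs,
day-of-year and year:

* **Seasonality.** Day-of-year enters through a cyclic smooth with period
  365.25 days, so a singing peak that spans the year end (September through
  February) is continuous across December 31.
* **Year.** Modelled as a thin-plate smooth over calendar year, matching
  the fractional degrees of freedom such models report, rather than as a
  factor.
* **Basis dimension.** `k = 5` per smooth — cohorts here are of order a few
  hundred tracks and the expected effective degrees of freedom are 3–5 —
  with REML smoothness selection.
* **Backward elimination.** The model starts with all predictors; the
  least significant smooth is removed, the model refit, and the loop stops
  when every retained smooth has p < 0.05 (or nothing is left, which is
  flagged as an intercept-only result).
* **Transforms.** Right-skewed responses and the speed predictor are
  normalized with the Johnson SL transform
  $z = \gamma + \delta \ln((x - \xi)/\lambda)$, fit by the percentile
  method ($z = \pm 0.524$ anchor points). Because $\gamma$ and $\delta$ are
  affine and cannot affect normality, the location $\xi$ carries the whole
  transform; the fitter therefore evaluates both the percentile estimate of
  $\xi$ and a pinned $\xi = 0$ candidate (durations and speeds are bounded
  at zero) and keeps whichever leaves the log residuals least skewed.
  Partial-effect curves are emitted on the model scale with the raw-scale
  predictor grid alongside.

## The synthetic singer

`simulate_singer()` and `generate_cohort()` produce cohorts with the
statistical structure the analysis assumes, so every stage can be validated
without access to restricted acoustic data:

* **Two behavioural states**, alternating semi-Markov style with
  exponential dwell times: slow singing (lognormal speeds, median
  5.5 km/h, mean dwell 5 h, meandering headings) and fast transit (median
  12.5 km/h, mean dwell 1.5 h, persistent headings). 31% of singers never
  leave the slow state; of those that do, 55% fall silent in the fast state
  and the rest sing fragmented songs.
* **Movement** by a correlated random walk integrated at 5-min steps, with
  per-dwell base speeds and per-step jitter. Observed segment speeds are
  chord distances between locations at least 10 km apart
  (`decimate_locations()`), so meandering slow singers register chord
  speeds below their through-water speed — as acoustic tracks do.
* **Songs** whose duration decreases with the current state speed
  (`24 − 0.9 × speed` min at baseline, lognormal noise), shortened by a
  factor 0.14 in the fast state: fragmented fast singing means short songs
  and frequent rests, not longer silences.
* **Silences** of three kinds: within-bout rests, 3–10 min, drawn as a
  truncated exponential anchored at 3 min whose mean tracks the state's
  duty-cycle target (75–90% slow, 10–30% fast); occasional intermediate
  "travel gaps" (2% of silences, 12 + Exp(12) min), the continuous tail
  real interval distributions show; and between-bout silences of at least
  35 min (35 + Exp(30) min) for multi-bout singers.
* **Season**: a cosine modulation of song duration (relative amplitude
  0.12, peak near day 350) and, at half that amplitude, of duty-cycle
  targets; cohort start dates put 75% of tracks in the
  mid-September–mid-March singing season across 2003–2009.
* **Observation model**: an optional hydrophone-array stage
  (`observe_toa()`, `localize_tdoa()`) that turns song emissions into
  per-array arrival times (range/c plus Gaussian noise) and back into
  positions by TDOA least squares, flagging collinear-array geometries as
  low-confidence.

The defaults were calibrated once, against the qualitative structure the
cohort analysis is meant to recover — a bimodal duty-cycle distribution with
a high mode (75–90%) around a third of segments and a low mode (0–5%)
around a fifth, roughly 31% slow-only singers, cohort mean duty-cycle near
50%, and mean track speeds around 7 km/h — and then frozen. Two places
where the simulator knowingly departs from real cohorts: synthetic mean song
durations run longer (~16 min at the track level) because feasible 75–90%
duty-cycles with ≥3 min rests force long slow-state songs, and the paired
singing/non-singing speed comparison tends to come out negative (silent-fast
singers place between-bout silences preferentially at high speed), where
real cohorts show no difference. Passing end-to-end tests therefore
demonstrate that the pipeline recovers the structure this generator encodes
— decreasing singing with speed, bimodal duty-cycles, a two-process interval
distribution — not that real fin whale data look exactly like the
simulation.

One property of the generator matters for interpreting BEC recovery: true
within-bout rests are bounded above (10 min) and true between-bout silences
bounded below (35 min), so any criterion inside the separating zone
segments bouts perfectly, and the fitted crossing — an extrapolation of two
exponential components — lands inside that zone (typically 15–18 min here)
rather than at any single "true" value. The 15%-accuracy form of BEC
recovery is therefore tested where it is well-posed: on exact
two-exponential mixtures with a closed-form crossing.

## Problem sizes and determinism

The test suite exercises the estimator-level properties on samples of
5,000–10,000 intervals and the end-to-end properties on 163-track cohorts
(the scale of the motivating dataset, about 300,000 notes per cohort),
repeated over 100 seeds for the additive-model recovery loop. All
simulation is seeded; `fit_biexponential()`'s internal restarts use a
private RNG stream so pipeline results are reproducible bit-for-bit under a
fixed seed on a given platform.

## Known limitations

* Localization error is not propagated into segment speeds; speeds are
  point estimates, as they are in the motivating analysis.
* The bout model is strictly two-process; three-process structures (rest /
  travel gap / bout break) are visible in `bec_diagnostics()` but not
  modelled.
* Songs are homogeneous within the simulator — no note-type structure
  (back-beats, higher-frequency sweeps), no acoustic propagation realism,
  and no multi-singer track confusion.
* Cohort statistics assume tracks are independent; a singer tracked in two
  different years would be counted twice, as in the motivating analysis.
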