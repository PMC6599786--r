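# finsong

Singing male fin whales (*Balaenoptera physalus*) can be tracked acoustically
for tens of hours at a time, which makes it possible to pair, for every
portion of a singer's track, his swimming speed with the amount of singing he
was doing. `finsong` implements that analysis as a tested R pipeline for
marine bioacousticians and movement ecologists:

* **Song assembly** — 20 Hz note detections become songs: at least three
  regularly spaced notes, with an inter-note-interval greater than 30 s
  breaking the series; song duration runs from the first note's start to the
  last note's end.
* **Bout analysis** — the distribution of inter-song-intervals mixes short
  within-bout rests with long between-bout silences. A four-parameter
  biexponential `y(t) = a_f e^(−λ_f t) + a_s e^(−λ_s t)` is fit to the
  log-frequency distribution of intervals, and the component crossing
  `t* = ln(a_f/a_s)/(λ_f − λ_s)` — the interval length equally likely to come
  from either process — is the bout-ending criterion (BEC) used to split
  songs into bouts.
* **Track kinematics** — successive acoustic localizations define track
  segments with great-circle speeds, and each segment carries a trailing
  duty-cycle: the percentage of its last 30 min spent singing. Duty-cycles
  ≥ 70% are robust singing; speeds ≥ 7 km/h are the fast regime.
* **Cohort statistics and models** — tracks (one whale, one unit) feed
  descriptive cohort statistics, the bimodal speed × duty-cycle histogram, a
  matched-pairs test of singing vs non-singing speeds, and generalized
  additive models (mgcv; identity link, Gaussian errors, cyclic seasonal
  smooth, backward elimination at α = 0.05) of duty-cycle and song duration
  on swimming speed, number of songs, day-of-year and year, with Johnson SL
  normalization of skewed variables.
* **Synthetic singers** — a two-state (slow singing / fast transit)
  semi-Markov simulator over a correlated random walk, emitting note streams
  and decimated, noisy localizations (plus an optional hydrophone-array TDOA
  observation model), so the whole pipeline is testable without access to
  restricted Navy acoustic data.

## Worked example

```r
library(finsong)

cfg <- analysis_config(planar = TRUE)        # synthetic scenarios use x/y km
coh <- generate_cohort(n_tracks = 163, seed = 1)
an  <- run_pipeline(coh$notes, coh$locations, cfg)
an
#> Fin whale singing/swimming analysis
#>   148 tracks (15 excluded), 1197 segments, 6156 songs, BEC 19 min
#>   mean track speed 7.6 km/h, mean duty-cycle 50.9%
#>   duty-cycle modes: 38% high (75-90%), 19% low (0-5%)
#>   paired singing/non-singing speed test: t_107 = -3.97, p = 0.000129
#>   duty_cycle model: adj r2 = 0.60, retained: speed, n_songs
#>   song_duration model: adj r2 = 0.35, retained: speed, n_songs

an$bout_fit
#> Biexponential interval model (counts vs minutes):
#>   fast: a_f = 9080, lambda_f = 0.4094 /min (mean 2.44 min)
#>   slow: a_s = 6.189, lambda_s = 0.01701 /min (mean 58.80 min)
#>   BEC: 18.58 min (operational 19 min)
#>   72 bins, residual norm 16.34, converged: TRUE
```

Reading this: of 163 simulated singers, 148 pass the inclusion filter (≥ 3
locations, ≥ 1 h). Their 1,197 track segments show the bimodal duty-cycle
structure (a high mode of robust singing at 75–90% and a low, mostly silent
mode at 0–5%). The interval distribution resolves into a fast process (rests,
mean 2.4 min) and a slow one (gaps, mean 59 min) whose components cross at
18.6 min — the operational BEC of 19 min cleanly separates the generator's
3–10 min rests from its ≥ 35 min between-bout silences. Both additive models
retain swimming speed with a decreasing partial effect: whales that swim
faster sing less, and their songs are shorter.

`render_report(an)` produces the full markdown report (cohort table, regime
transitions, model tables); `plot_bec_fit()` draws the interval histogram
with the fitted components and the BEC.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/finsong.R simulate --config scenario.yaml --seed 5 --out-dir out/
Rscript inst/cli/finsong.R all --notes out/notes.csv --locations out/locations.csv --out-dir out/
```

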