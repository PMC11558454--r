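---
title: "Quantifying dyadic rival interactions and mate-choice preference strength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic rival interactions and mate-choice preference strength}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalcall)
```

## The problem

In chorusing frogs such as the túngara frog, males advertise in dyadic
vocal contests — each male hears and answers his rival in real time — and
females choose between the two males' calls by phonotaxis (approaching the
speaker that plays them). Quantifying this communication network takes
three linked analyses, each with its own bookkeeping rules:

1. **Segmentation.** From a two-channel recording of a rival pair, find
   the *interactions*: maximal bouts in which both males called with no
   dyad silence longer than 10 s, lasting at least 20 s from the onset of
   the first call to the offset of the last. Per recording session, the
   longest interaction after a 2-min settling window is the unit of
   analysis.
2. **Call metrics.** Within that interaction, characterize each male by
   call rate (calls/min), call complexity (chucks/call — a chuck is the
   short, high-frequency suffix males add to the whine), and whine
   amplitude measured as background-corrected RMS and peak-to-peak (P2P),
   referenced to a 114 dB calibration tone. Pair-level predictors are the
   rivals' trait means, their absolute differences, and their
   *proportional* differences `|a − b| / max(a, b)` — Weber's-law scaling,
   on the premise that receivers discriminate relative, not absolute,
   contrasts.
3. **Preference.** Collate two-alternative female choices into cells and
   measure, per cell, the *preference strength*: the deviation of the
   choice split from equality, scaled to [0, 1]. Compare its mean across
   cells against the distribution expected if every choice were a fair
   coin.

The package implements these computations as composable functions over
plain data frames, together with a synthetic-data generator so that the
full pipeline runs, and is tested, without any field recordings.

## The preference-strength statistic

For a cell of `n` choices of which `k` went to the majority rival,

$$\mathrm{ps} = \frac{k - e}{n - e}, \qquad
  e = \begin{cases} n/2 & n \text{ even}\\ (n+1)/2 & n \text{ odd}\end{cases}$$

`e` is the *equal-choice point*: for odd `n` it is the first possible
count above 50%, so 2 of 3 choices (67%) still counts as "no preference".
Thus `ps = 0` for a 5/5 split of 10, `ps = 1` for 10 of 10, and
`ps = 0` for 2 of 3. Cells with a single choice carry no information about
preference and are excluded. For binomial models the statistic is coded as
`successes = k − e` deviations out of `trials = n − e` possible; the ratio
reproduces `ps` exactly (`binomial_response()`).

```{r}
preference_strength(c(10, 10, 3), c(10, 5, 2))
binomial_response(10, 8)   # ps = 0.6 as 3 successes of 5 trials
```

Two collation schemes are supported, matching the two questions asked of
choice data: `per_stimulus` groups trials by stimulus × female origin ×
female treatment (direct effects of the sensory environment on choosers);
`per_pair` groups by rival pair × male treatment (indirect effects via
changed rival interactions).

## The random-choice null

Is an observed mean preference strength larger than chance? Because `ps`
is a folded, rescaled binomial statistic, its null expectation is well
above zero for small cells, so "chance" must be computed, not assumed.
`simulate_null()` conditions on the observed cell sizes — the only reading
under which asymmetric, non-zero lower confidence bounds arise — and draws
each cell's majority from Binomial(n, ½), 1000 replicates by default. The
95% interval is the empirical 2.5th/97.5th percentile with linear
interpolation (`quantile type 7`); the interval estimator is our choice,
as the underlying procedure leaves it unstated.

`exact_null()` is the analytic oracle: each cell's `ps` takes
`floor(n/2) + 1` values with binomial probabilities, and the distribution
of the (weighted) mean is their convolution. Support is capped (default
10^6 points) to keep enumeration tractable; equal cell sizes collapse the
support dramatically, so realistic designs enumerate easily.

```{r}
ex <- exact_null(10)            # one cell of 10 fair-coin choices
pmf_mean(ex)                    # exactly 1260/5120
sim <- simulate_null(rep(10, 6), n_sims = 1000, seed = 1)
compare_observed(0.55, sim, exact_null(rep(10, 6)))
```

The Monte-Carlo and exact routes are kept deliberately separate: tests
require the simulated 2.5/97.5 percentiles to fall inside the exact
inverse-CDF quantiles evaluated at the level ± 4 binomial standard errors
of the estimated CDF — "agreement within Monte-Carlo error" made precise.

## Segmentation rules and their interpretation

A *dyad silence* is a gap in the pooled timeline of both males (from the
running maximum offset to the next onset). We interpret the "pauses" that
bound an interaction as dyad silences, not per-male gaps: the interaction
is the pair's joint bout, and the stimulus rules below speak of
simultaneous silence. A bout starts at the first call after a dyad silence
strictly longer than `max_pause` (a pause of exactly 10 s is tolerated)
and ends at the last call before one. The both-males and minimum-length
requirements filter bouts; they never trim them. Interaction length runs
from first onset to last offset. The 2-min exclusion window is anchored at
the moment the pair could first interact (`session_start`, defaulting to
recording start); ties for longest break toward the earlier interaction.

Two rules are stated ambiguously in their source and are implemented with
a documented reading, both configurable rather than silently guessed:

* **Pair exclusion** ("very few (< 8) or low amplitude (< 60 dB whine
  RMS) calls in one of their interactions"): `< 8` counts the pair-total
  calls of the interaction and `< 60 dB` the mean measured whine RMS.
  Both thresholds are exclusive — exactly 8 calls or exactly 60.0 dB is
  kept.
* **Stimulus silence rule** ("no simultaneous silence … for more than 5 s
  in the first or last 30 s … or twice within 30 s"): a long silence
  *intersecting* the first/last window violates (the stricter reading,
  rather than wholly-contained), and "twice within 30 s" means two long
  silences whose onsets lie within 30 s of each other (sliding windows
  anchored at silence onsets).

Segmentation is verified against a brute-force oracle that enumerates
every contiguous subsequence of pooled events and applies the bout
definition literally, on hundreds of randomized toy timelines.

## Amplitude measurement

Recordings are band-pass filtered to 300–4500 Hz with a 24 dB/octave
roll-off before measurement. We realize this as a 2nd-order Butterworth
band-pass applied forward and backward (`signal::filtfilt`): zero phase
distortion, 12 dB/octave per pass per edge, 24 dB/octave effective — a
75 Hz tone (two octaves below the low edge) is attenuated by ≈ 48 dB.

`measure_call()` takes the raw RMS and P2P of the call window and
subtracts a background estimate from two flanking windows, 0.1–0.02 s
before onset and 0.02–0.1 s after offset. The background statistic is the
mean of the two flank values (averaging the two flank statistics, not
pooling their samples — an interpretation, flagged as such). Subtraction
is on linear amplitude, mirroring the stated procedure, not on power;
negative differences floor to zero and are flagged (`floored_*`), a
degenerate case the source does not address. Amplitude calls are chosen
per male as up to 3 of the loudest calls (ranked by raw P2P, standing in
for oscillogram inspection) that do not overlap the rival, have ≥ 0.1 s of
dyad silence on both flanks, and are not among that male's first or last
3 calls of the interaction.

dB referencing uses `114 + 20·log10(linear / tone)` against the channel's
recorded calibration tone; linear values are kept for analysis, dB for
reporting and the 60 dB exclusion rule. A missing calibration is an
error, never a silent pass-through.

## What the synthetic generator emulates — and what it does not

`gen_call_timeline()` draws each male's call onsets from a gamma renewal
process (shape 4, mean interval 2 s by default: regular-ish calling at
~30 calls/min, in the range typical of chorusing túngara frogs; shape 1
recovers a Poisson process). No quantitative timing distributions exist
for the study system in our source, so these defaults are documented
choices, not estimates. Chuck counts are drawn from a categorical
distribution over 0–3; call amplitudes are lognormal with CV 0.2 around a
mean linear peak of 0.1 full scale.

Dyad silences require *both* males to fall quiet, which independent
per-male pause processes essentially never produce; the generator
therefore draws a session-level schedule of shared quiet periods
(inter-pause gaps gamma with mean 45 s, durations gamma with mean 15 s)
that both males respect. This yields sessions with a handful of
interactions of realistic length (tens of seconds to ~3 min) separated by
boundary silences — the structure segmentation needs to be exercised.
Antiphony is approximated by a fixed start offset between the males'
otherwise independent processes; true interactive timing (call-by-call
alternation, overlap avoidance) is out of scope. A condition/origin
mismatch attenuates calling (rate × 0.85, amplitude − 1.5 dB), a stylized
rendering of less intense interactions in unfamiliar sensory conditions.

`gen_waveform()` renders whines as 900→400 Hz downward sweeps and chucks
as 2.6 kHz bursts, quantized to 16-bit PCM, plus optional Gaussian
background noise — enough spectro-temporal structure for filter and
round-trip amplitude tests, and deliberately nothing more. The returned
ground-truth table holds each call's true RMS/P2P on the clean quantized
samples, so `measure_call()` can be validated end to end: exact recovery
at zero background, and within 5% (RMS) with known noise.

`gen_choices()` draws `P(choose the faster-calling male) =
logistic(logit(0.5) + slope × prop. call-rate difference)`; slope 0 is a
fair coin. The association direction (higher preference with higher
proportional call-rate difference) matches the empirical finding the
choice model is meant to emulate; the slope magnitude is a free
parameter. Passing tests therefore show the *pipeline* recovers what was
put in (monotone preference in slope, fair-coin behaviour inside the
random-choice interval); they say nothing about real frogs' preference
functions, latencies, or sequential choice behaviour.

All generator randomness flows from a single seed with a documented
stream order (pause schedule, male A, male B; choices per stimulus in row
order); fixed seeds give byte-identical tables, and callers' RNG state is
always restored.

## Numerical choices and degenerate inputs

* Interactions with `segment_interactions()` require strictly positive
  thresholds; empty event tables and zero-duration sessions yield empty,
  schema-stable outputs throughout the pipeline.
* Overlap uses half-open intervals: touching endpoints do not overlap,
  avoiding double counting at sample boundaries.
* Proportional differences define 0/0 = 0 (flagged in documentation);
  one-sided zeros give 1, the Weber-scale maximum.
* Exact-null support values are keyed on 12-digit rounding during
  convolution; quantiles use the inverse CDF with a 10^-12 tolerance.
* `run_pipeline()` derives per-session seeds as
  `seed + 100·pair + (condition == "urban")`, keeping all derived seeds
  small integers.

## Problem sizes used in the tests

The shipped suite validates segmentation against the brute-force oracle
on 500 randomized event sets (≤ 30 events), compares Monte-Carlo null
quantiles to exact enumeration at 100,000 replicates across cell
configurations n ∈ {2, 3, 6, 10} in 1–5 cells, and runs the slope-recovery
experiment at 500 trials per slope in {0, 0.5, 1, 2, 4} plus 100 fair-coin
replicates of 100 trials each — sizes chosen so the whole suite completes
in well under a minute on one CPU while leaving the Monte-Carlo error
bands far tighter than the effects they bound.

## Known limitations

* The generator's timing and amplitude distributions are plausibility
  choices, not fits; parameter-recovery results should be read as
  software validation only.
* Waveform synthesis is single-channel per male and spectrally stylized;
  no microphone cross-talk, reverberation, or live-broadcast loop is
  modeled.
* Statistical *modeling* of the exported tables — (G)LMMs on metrics and
  binomial responses, post-hoc contrasts, information-theoretic model
  averaging — is intentionally out of scope; the package exports
  model-ready columns (`add_model_transforms()`, `binomial_response()`)
  for standard tools.
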