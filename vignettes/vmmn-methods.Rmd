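---
title: "Simulating and detecting the visual mismatch negativity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting the visual mismatch negativity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmmn)
```

## The scientific problem

The visual mismatch negativity (vMMN) is a negative deflection of the
event-related potential (ERP) over posterior scalp, roughly 150–300 ms after
a change in a regular, task-irrelevant stimulus sequence. It indexes
*automatic* change detection: the observer attends something else entirely
while rare "deviant" stimuli embedded among frequent "standards" elicit the
component. This package implements a complete, testable analysis chain for
one particular use of the vMMN: measuring *visual temporal integration*
(stimulus persistence) by splitting characters into two fragments presented
with a stimulus onset asynchrony (SOA). If the visual system still fuses the
fragments at a given SOA, the character category (a legal letter versus a
pseudo-letter) is available to the change-detection machinery and a deviant
category can elicit a vMMN; beyond the persistence limit the fragments no
longer integrate and the vMMN disappears. Comparing the largest SOA at which
a vMMN emerges between age groups turns the component into an index of
age-related changes in temporal acuity at a pre-attentive level.

Because no raw data of this kind is publicly deposited, the package pairs
the analysis chain with a forward simulator whose defaults emulate the
design it was built around: two age cohorts (young, older; n = 15 each), a
passive oddball paradigm with letters and pseudo-letters, and a
two-alternative forced-choice (2AFC) psychophysical task over the same
fragmented stimuli.

## The oddball design encoded by the generator

`session_config()` fixes the stimulus design; its defaults are the
emulated study conditions and are not meant to be tuned:

* 250 stimulus pairs per sequence, deviant probability 0.2; two variants per
  role, so each deviant variant has probability 0.1 — deviant counts are
  exact by construction (50 deviants, 25 + 25), not Bernoulli draws;
* fragments of 30 ms at SOAs of 0 (whole character), 30, 50 or 70 ms;
* inter-trial interval (ITI) of 600 ± 50 ms, uniform; we take the ITI to be
  the *onset-to-onset* gap between successive pairs, so realized onset gaps
  fall in [550, 650] ms with mean 600 ms;
* 16 sequences per session: 4 SOAs × 2 deviant categories × 2 repetitions;
* a frame-thickening detection task (300 ms events, every 5–15 s, sides
  balanced) that keeps attention away from the characters. Task events never
  overlap the presentation of a deviant or of the last standard before it,
  so motor/attention transients cannot contaminate the critical epochs.

Two constraints are design choices where the emulated protocol is silent:
deviants are separated by at least two standards (and two standards precede
the first deviant), a common oddball practice that guarantees every deviant
has a well-defined "last standard"; and deviant positions are sampled
uniformly among all placements satisfying that constraint. Character
rendering is deliberately abstracted away — events carry category, variant
and fragmentation labels only, because the analysis never touches pixels.

## The forward model

`generate_recording()` builds each channel as a sum of Gaussian-windowed
component pulses plus 1/f noise:

* **P1** (positive, ~106–110 ms, right-dominant) and **N1** (negative,
  ~178–185 ms) are locked to the first fragment of *every* stimulus. Their
  default latencies and amplitudes sit inside the ranges such experiments
  report, and they cancel exactly in the opposite-condition subtraction, so
  their precise values are immaterial to detection.
* **vMMN** (−1.0 μV, Gaussian SD 20 ms, posterior topography peaking at
  PO7/PO8/PO9/PO10) is locked to the *second* fragment and inserted only for
  deviant events whose SOA does not exceed the group's *persistence limit*
  for the deviant's category. The limits are the scientific heart of the
  simulator: young adults integrate only whole characters
  (pseudo-letter limit 0 ms, letter limit "never"), older adults integrate
  pseudo-letter deviants up to 50 ms and letter deviants only at 0 ms. The
  young/older vMMN peak latencies default to 234 and 248 ms. Insertion is
  all-or-none per (group, category, SOA) because the emulated results are
  reported as presence/absence, not as graded amplitude decay; a graded
  model can be built by passing custom `component_spec()` predicates.
* **Noise** is per-channel independent 1/f (power ∝ 1/f over 1–30 Hz and
  beyond, flattened below 0.1 Hz), RMS 10 μV — a realistic background level
  for band-limited scalp EEG. Channels are synthesized in pairs from one
  complex-Gaussian spectrum (real and imaginary parts are independent
  realizations). The generator does not model spatially correlated noise,
  ocular artifacts, alpha rhythms, or drifts in electrode impedance; what
  the tests show about detection therefore concerns sensor noise of
  realistic amplitude and spectrum, not every failure mode of real
  recordings.

Everything is deterministic given a seed, and the model is linear: doubling
a component amplitude doubles its contribution, and signal and noise
superpose additively. These invariants are pinned by tests.

## Preprocessing

The analysis filter is 0.1–30 Hz with a 24 dB/octave slope, realized as a
4th-order Butterworth high-pass plus 4th-order low-pass. Both are applied
forward–backward (zero phase), which preserves peak latencies and doubles
the effective slope — standard ERP practice. Numerically, a 4th-order
high-pass at 0.0002 of Nyquist is ill-conditioned in transfer-function
form, so each filter is factored into second-order sections and cascaded;
the filtering then stays linear to machine precision and agrees with a
reference `signal::filtfilt()` implementation away from the edges.

Epochs run from −100 to +600 ms around the onset of the *first* fragment,
endpoints inclusive (701 samples at 1000 Hz), with the −100..0 ms mean
subtracted per channel. For the statistics, time zero is redefined to the
onset of the *second* fragment: every epoch carries both axes, with
`times_ana = times_acq − SOA`. Epochs whose window does not fit in the
recording are flagged `out-of-bounds` rather than silently dropped.

The ±100 μV artifact screen is ambiguous as printed ("amplitude change
exceeding ±100 μV"): we reject an epoch when any sample's absolute value
exceeds the threshold *or* when its peak-to-peak range exceeds twice the
threshold, on any channel including the EOG pair. With baseline-corrected
epochs the absolute-value reading is operative, and the retain/reject
boundary sits exactly between 100 and 101 μV, which a sweep test pins.

## ERPs, difference waves and peaks

Averages are computed per condition over retained epochs, with the two
physical variants of a role pooled (the analysis contrasts letter versus
pseudo-letter, not exemplars). Change-related activity is isolated by the
*opposite-condition* subtraction: the ERP to character X as standard (from
the sequence where roles are swapped) is subtracted from the ERP to the
physically identical X as deviant. Stimulus-specific exogenous components
cancel exactly in this contrast; the function refuses pairings that differ
in category or SOA, since those would contrast physically different
stimuli.

ROIs pool PO8 + PO10 (right) and PO7 + PO9 (left) as unweighted means.
Peaks are measured on the analysis axis in 150–300 ms: latency is the
largest polarity-signed excursion (ties break to the earliest sample), and
reported amplitudes are the mean over an inclusive 20 ms span centred on
the group-average peak, clipped to the search window (and flagged) when
the peak sits within 10 ms of a window edge. P1/N1 are reported from the
whole-character condition with windows of 70–150 ms (positive) and
150–230 ms (negative), bracketing the latencies such experiments observe;
they are descriptive only and play no role in detection.

## The detection criterion

A vMMN counts as present in a condition when the subject-level ROI-pooled
difference potentials, tested pointwise against zero, show at least 20 ms
of consecutively significant samples (p < 0.05) inside 150–300 ms, in at
least one ROI. Decisions taken where the prose under-determines the
algorithm:

* "p < 0.05" is read as **two-tailed** (conservative); a one-tailed variant
  is available since the component's sign is predicted.
* Runs are computed on the full series and then intersected with the search
  window; a straddling run counts only its inside portion.
* Run duration is count-based: n samples at rate r last n·1000/r ms, so 20
  consecutive significant samples at 1000 Hz constitute exactly the
  criterion's 20 ms; at other rates the minimum converts with a ceiling.
* Only runs over which the difference is **negative** qualify by default
  (`polarity = "negative"`): a significantly positive difference is not a
  mismatch *negativity*. Setting `polarity = "any"` restores the purely
  two-sided behaviour.
* Zero across-subject variance makes the t statistic degenerate; such
  samples are flagged and scored p = 0 when the mean is nonzero (an exact
  effect, as in noiseless simulations) and p = 1 when it is zero.

No multiple-comparison correction is applied across conditions or ROIs
beyond the run criterion itself, mirroring common practice with this
criterion.

### How much error control the run criterion actually buys

An honest calibration result, measured by this package's own tests: with
n = 15 subjects and noise matching the default generator (band-limited to
30 Hz), noise-only cohorts satisfy the criterion in roughly 10% of
replicates (any-roi, negative-polarity; ~20% without the polarity
restriction) — not 5%. The reason is structural: 30 Hz band-limited noise
has a correlation time far longer than 20 ms, so once a single sample
crosses the pointwise threshold, a 20 ms excursion is nearly free; the run
requirement adds almost no familywise control within a 150 ms window at
1000 Hz. Published calibrations of consecutive-significance criteria imply
runs of a third to half the window would be needed at comparable
autocorrelation. The acceptance suite states the nominal 5% bound and
reports the measured rate with a binomial confidence interval; users who
need calibrated error control should treat single-condition detections near
threshold with caution (a permutation-based alternative is out of scope
here). The qualitative young/older × category × SOA pattern is robust to
this liberality because true effects at the default signal-to-noise ratio
are detected essentially always, while false positives occur in a minority
of seeds.

## Statistics

Repeated-measures ANOVAs are fitted via the multivariate linear model on
the subject × cell matrix with type-III univariate decomposition
(`car::Anova`), Greenhouse–Geisser epsilon for within factors with more
than two levels, partial eta squared as SS_effect / (SS_effect + SS_error)
within each error stratum, and Tukey HSD post hocs from the studentized
range. Designs must be balanced; nothing is imputed. Amplitude/latency
ANOVAs run only for conditions in which the run criterion flagged a vMMN,
mirroring the emulated analysis. Hit rates score a response within
200–1000 ms after a frame-thickening onset (a conventional simple-RT
window; configurable), each response consumable by one event only.

The 2AFC observer follows an exponential psychometric model:
p(correct) = 0.5 + (p₀ − 0.5)·exp(−(SOA − 30)/τ), mixed with a 2% lapse
rate; defaults p₀ = 0.9, τ = 8 ms place performance well above chance at
30 ms and at chance by 50 ms, in both groups, as the emulated task found.
The printed session length of 164 trials is not divisible by the six
SOA × letter-position cells, so trials are split as evenly as possible
(cells of 27–28; per-SOA totals 55/55/54) — the design's own constraint
makes perfect balance impossible.

## Problem sizes used by the tests

The simulation studies in the test suite use the full cohort design
(n = 15 per group, 250-trial sequences, two repetitions per condition) with
the simulated channel set restricted to the four ROI electrodes, which
leaves every ROI-level quantity unchanged. Type-I calibration uses a
distributional shortcut: a noise-only subject difference wave is one
filtered, baseline-corrected noise epoch scaled by
√(1/n_dev + 1/n_std), exactly the Gaussian-process law of the pipeline's
null difference wave under the approximation that epochs a full ITI apart
are independent after baseline correction (`simulate_noise_difference_wave()`);
its scaling law is itself pinned by an exact test. Presence/absence pattern
checks run 5 seeded replicates per cohort; recovery checks run 20
replicates of the critical older-group condition plus an exact noiseless
cohort.

## Known limitations

* The noise model is spatially independent per channel; no ocular
  artifacts are simulated by default, so the ±100 μV screen is exercised
  synthetically rather than by realistic blinks.
* The persistence limit is all-or-none; real integration presumably decays
  gradually with SOA.
* EDF import/export is not provided; recordings round-trip through the
  package's internal array format, schedules through JSON, and behavioural
  tables through CSV.
* The run criterion's liberal error control at high sampling rates (above)
  is a property of the method itself, reproduced faithfully rather than
  corrected.
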