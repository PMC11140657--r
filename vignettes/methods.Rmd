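---
title: "Methods: sleep-EEG TMR analysis in sleeptmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-EEG TMR analysis in sleeptmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameters and numerical choices behind
`sleeptmr`, in the spirit of a methods section: what each stage computes,
which knobs matter, what the synthetic generator does and does not emulate,
and where the design was genuinely open.

## The analysis problem

A targeted-memory-reactivation (TMR) experiment replays sounds, previously
paired with scenes, during N2/N3 sleep. The analysis has three strands:

1. **Cue-locked EEG.** Epochs −1 to +3 s around every cue are decomposed
   with complex Morlet wavelets; trial-averaged power is dB-normalized
   against a −500…−200 ms pre-cue baseline, and memory cues are contrasted
   against non-learning control cues with a cluster-based permutation test.
   A spindle-probability curve (fraction of trials with an ongoing detected
   spindle at each time point) complements the power analysis.
2. **Endogenous sleep physiology.** Individualized spindle detection
   (wavelet at each participant's fast-spindle spectral peak), slow
   oscillation detection, and SO–spindle coupling (density, mean phase,
   vector length), plus REM theta power around the individual theta peak.
3. **Behavior.** Recognition is scored as corrected recognition
   (hit − false-alarm rate) per condition (emotion × component ×
   cued/uncued); the cueing benefit (cued − uncued) is tested against zero
   and related to cue-evoked EEG with robust regression and circular
   statistics.

## Preprocessing

* **Filters.** All filters are 4th-order Butterworth run forward–backward
  (`signal::filtfilt`), i.e. zero-phase — the conventional choice for
  event-locked analysis because filter delay would shift latencies. The
  60 Hz notch is an IIR biquad with Q = 30, also zero-phase. Zero-phase
  filtering is exactly time-reversal symmetric only for an infinite
  signal; the startup transients of the 0.5 Hz highpass edge decay over a
  few thousand samples, which the tests account for.
* **Resampling** is Fourier-domain truncation at the new Nyquist —
  an ideal anti-alias filter for band-limited signals, exact for sinusoids.
  Only downsampling is supported.
* **Epoch rejection** combines an absolute ±500 µV threshold with a
  joint-probability criterion: per channel, the summed negative log of
  histogram-estimated sample probabilities (50 bins over the pooled epoch
  distribution), z-scored across epochs. Epochs are flagged one-sided
  (only *improbable* epochs are artifacts) beyond 6 SD for single channels
  and 2 SD for the all-channel sum. The estimator's internals (histogram
  density, one-sided flagging) are package decisions; the thresholds are
  the analysis standard. Rejection never modifies sample values — only the
  `kept` flag.
* **Hjorth screening** works on hypnogram-aligned 30-s segments (the epoch
  length is a package decision; aligning to scored epochs simplifies stage
  bookkeeping). Activity, mobility (scaled by `fs`, so a pure f Hz
  sinusoid gives ≈ 2πf rad/s) and complexity are computed per
  epoch × channel; a value deviating from its cross-epoch mean by more
  than 3 SD marks that epoch × channel bad. Channels bad in ≥ 25 % of
  epochs are interpolated globally; epochs with > 50 % bad channels are
  removed; remaining bad channels are interpolated per epoch; the pass
  runs twice. One consequence worth knowing: by Chebyshev's inequality at
  most ~11 % of epochs can exceed 3 SD *in one parameter*, so the 25 %
  global rule can only fire when a channel misbehaves across a mixture of
  parameters — which is what real artifacts do, and what the test fixture
  constructs deliberately.
* **Spherical splines** use order m = 4, 50 Legendre terms and ridge
  regularization 1e-5 — standard published defaults, stated explicitly.
  At least 4 good channels with montage positions are required.

## Spectral estimation and individual peaks

Welch PSD uses 5 s Hamming windows at 50 % overlap (0.2 Hz resolution).
For peak *detection* the PSD is computed on the first difference of the
signal scaled by `fs` — differentiation multiplies power by ω², flattening
the 1/f trend so band peaks stand out; the scaling keeps units
interpretable. The spindle peak is searched in 12.5–16 Hz and the theta
peak in 3–8 Hz. "Most prominent" is implemented as topographic prominence
(peak height minus the higher flanking minimum); the flanking minima are
searched in the band widened by 1 Hz so a genuine peak close to a band edge
keeps its full prominence instead of being truncated by the band cut. Ties
break toward higher prominence, then lower frequency. With no in-band
local maximum, the band midpoint is returned with `fallback_used = TRUE`
so downstream code can audit the decision. REM theta normalization divides
each electrode's spectrum by its own mean power (computed over the same
REM-clean data), making the normalized mean exactly 1; band power is then
averaged over ±1.5 Hz around the peak, clipped to the spectral support
with the clipping recorded.

## Event detection

* **Spindles.** The complex Morlet wavelet is centered on the individual
  peak with a 3 Hz spectral FWHM (σ_f = FWHM/2.355; σ_t = 1/(2πσ_f)), and
  scaled so its magnitude reads out the amplitude (µV) of a matched
  sinusoid. The threshold is 9 × the median magnitude over artifact-free
  samples; supra-threshold runs closer than 100 ms are merged (prevents
  double-counting envelope dips — a package decision), runs ≥ 400 ms
  become events, and events overlapping masked samples are discarded.
  A zero median (flat signal) is a degenerate threshold: the detector
  warns and returns no events. The 9 × median is applied to the wavelet
  *magnitude*, not power.
* **Slow oscillations.** The 0.5–4 Hz filtered trace is scanned for
  positive-to-negative zero crossings; spans of 0.8–2 s between
  consecutive crossings are candidates; the top quartile
  (`ceiling(n/4)` largest peak-to-peak amplitudes, per channel) is
  retained.
* **Coupling.** A spindle couples to an SO when its amplitude peak falls
  inside the SO's crossing-to-crossing span. The coupling phase is the
  angle of the analytic signal (Hilbert transform with 2 s reflection
  padding) of the 0.5–4 Hz trace at the spindle peak, under the stated
  convention **0° = SO positive peak, ±180° = trough**. Summaries report
  coupled density per NREM minute, circular mean phase and resultant
  vector length.

## Cluster-based permutation testing

Condition maps (participants × frequencies × times, or participants ×
times for 1-D curves) are compared with pointwise paired *t* tests;
points beyond the two-tailed *t* critical value at α = 0.05 (the
cluster-forming threshold — a declared default) are clustered under
4-connectivity, with same-sign membership. The cluster statistic is
`t_sum`. The null distribution is the maximum |t_sum| over clusters in each
of 1,000 random within-participant sign flips of the difference maps — the
exact permutation scheme for a paired design — and positive and negative
clusters are tested jointly against this two-sided null with
`p = (1 + #{null ≥ |t_sum|}) / (n_perm + 1)`. The labelling and
permutation loop are C++ for speed; results are reproducible under a fixed
seed. Trial counts are matched between conditions beforehand by random
subsampling of the larger condition.

dB normalization (`10·log10(P / mean baseline P)` per frequency on the
trial average) removes any multiplicative gain exactly; the mean *power
ratio* over the baseline window is identically 1 at every bin, while the
mean *dB* is 0 only where power is stationary across the window — bins
carrying no signal hold wavelet edge leakage whose log fluctuates, which
is why identity checks are run on power-carrying bins or constant maps.

## The synthetic-data generator

`gen_tmr_session()` emulates the statistical structure of a cueing-night
recording; it is ground truth for the detectors, not a biophysical model.

* **Background**: Gaussian noise spectrally shaped to 1/f (slope 1),
  15 µV RMS, 250 Hz.
* **Spindles**: Hann-windowed sinusoidal bursts, 0.5–2 s, amplitude
  10 × background RMS on the standard benchmark. Each session draws one
  spindle *center* frequency inside 12.5–16 Hz and jitters individual
  events by ±0.5 Hz around it — mirroring the individual-peak premise on
  which the detector is built; 4 events/min (uncoupled) by default,
  fixed-count placement for exact tests (Poisson optional).
* **Slow oscillations**: one period of −sin(2πt/T), T drawn from
  0.5–1.25 Hz, positive half-wave scaled by 0.6 (emphasized trough), so
  the bounding positive-to-negative crossings exist by construction;
  3 events/min, gain 10 ×.
* **Coupling**: a configurable fraction of SOs (default 0.5) carries a
  spindle whose envelope peak sits at a phase drawn from von
  Mises(µ = −30°, κ = 5). The placement inverts the analytic phase of the
  *0.5–4 Hz filtered* template — the same convention the measurement uses —
  so waveform asymmetry and filter reshaping cannot bias recovery, and the
  realized phase is stored as ground truth. Placement is clamped 10 %
  inside the span: phases within ~±35° of the zero crossing (+90°) are
  mapped to the nearest achievable interior phase, because a spindle peak
  *at* the crossing is ambiguous between adjacent spans and its
  detectability depends on crossing jitter. This is a known limitation for
  preferred phases very close to +90°, and irrelevant for the empirically
  typical peri-peak phases.
* **Cues**: blocks of 46 memory sounds (23 negative, 23 neutral) plus 6
  controls in random order at a 5 s ISI, rerandomized each block,
  restricted to N2/N3, halted across a simulated mid-session arousal and
  stopped at the first REM epoch. Responding cues (probability 0.8 for
  memory, 0.2 for control — free parameters of the simulation, not claims
  about data) receive additive theta (5.5 Hz, 0.5 s, centered 0.69 s
  post-cue) and spindle (13.5 Hz, 0.6 s, centered 1.05 s) packets with
  2 × RMS gain and 50 ms latency jitter.
* **Behavior**: per participant, condition-mean hit/false-alarm rates are
  shifted by a logit-normal participant effect (SD 0.5, roughly matching
  between-subject spread of recognition rates) and item responses drawn as
  Bernoulli trials over the 368-item recognition list (92 old objects, 92
  old backgrounds, 92 new objects, 92 new backgrounds; old items split 23
  cued / 23 uncued per emotion). With the participant SD set to 0 the
  generator switches to a deterministic quota so observed rates match the
  configured means up to the 1/23 trial quantization.

What the generator does **not** emulate: scalp topography and volume
conduction (events are injected coherently on all channels), EMG/EOG,
stage-transition dynamics beyond the fixed hypnogram template, amplitude
non-stationarity across the night, and any coupling between behavior and
EEG. Passing tests therefore validate the *computational* pipeline —
detection, phase estimation, statistics — not claims about real
recordings.

## Statistical auxiliaries

* `fdr_adjust()` is Benjamini–Hochberg step-up via `stats::p.adjust`,
  oracle-checked in the tests against a direct implementation.
* `circ_linear_corr()` implements
  r = √[(r²_xc + r²_xs − 2 r_xc r_xs r_cs)/(1 − r²_cs)] with the asymptotic
  n·r² ~ χ²(2) p value; r is clamped to [0, 1] against rounding.
* `watson_williams()` uses the F approximation with the 1 + 3/(8κ̂)
  correction and Fisher's A⁻¹ approximation for κ̂; it warns when the
  pooled resultant length drops below 0.45, where the test's assumptions
  fail.
* `robust_regress()` is IRLS with Tukey's bisquare (c = 4.685, tolerance
  1e-8) via `MASS::rlm`; with exactly collinear designs it errors, and on
  noise-free data the IRLS endpoint equals OLS. Approximate p values use
  the normal reference.
* `one_sample_t()` special-cases zero spread (t = 0, p = 1 at the null
  mean) instead of erroring on degenerate but valid input.
* Linear-mixed-model analyses of the behavioral tables are deliberately
  out of scope; `score_recognition()` emits the tidy long-format table
  such models consume.

## Problem sizes and tolerances in the validation suite

The validation suite is sized to make every property measurable quickly:
detector benchmarks use 20-minute single-channel sessions at 10 × gain
(recall/precision ≥ 0.9 at ±0.25 s onset tolerance); coupling recovery uses
200 coupled events at µ = −30°, κ = 5 (mean within ±10°, vector length
within ±0.1 of I₁/I₀(κ)); cluster calibration uses 200 null simulations of
20 pseudo-participants on 20 × 40 maps with 1,000 permutations (familywise
false-positive rate 0.05 ± 0.03) plus 20 power runs with a 1 dB patch
(≥ 70 % overlap in ≥ 90 % of runs); spectral-peak recovery uses 100
recordings with injected peaks well above the floor (≥ 95 % within one
0.2 Hz bin). Identities (dB, PSD normalization, BH-FDR, circular r) are
checked to machine precision on constructed inputs.
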