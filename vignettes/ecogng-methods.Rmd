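---
title: "Quantifying Go/No-Go motor inhibition from ECoG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Go/No-Go motor inhibition from ECoG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ecogng)
```

## The scientific problem

Response inhibition — withholding a prepotent movement when a stop cue
appears — engages the inferior frontal gyrus (IFG), and intracranial
recordings let us watch this at millisecond and millimeter scale.
`ecogng` analyzes subdural electrocorticography (ECoG) recorded during a
child-friendly Go/No-Go task: frequent Go cues demand a button press,
rare No-Go cues (a 1:6 No-Go:Go ratio, 49 trials per run) demand
withholding. Trials are classified as Go-correct, Go-wrong,
No-Go-correct, or No-Go-wrong from the cue type and the presence of a
response.

Three effects are quantified:

1. **Activation contrast.** High-gamma (HG, 70–200 Hz) envelope
   activation over motor cortex during executed Go trials and over the
   IFG during withheld No-Go trials.
2. **Band-power ratio.** Per frequency band (theta 4–8, beta 12–40, HG
   70–200 Hz), the ratio of the No-Go/Correct mean peak power to the
   Go/Correct mean peak power on the selected IFG electrode — above 1
   when inhibition recruits that band.
3. **Phase–amplitude coupling (PAC).** The dependence of the HG
   amplitude envelope on low-frequency phase, summarized by a
   modulation index (MI) per (phase frequency × amplitude frequency)
   bin, with permutation significance, and compared between conditions
   as a ratio map.

A cross-patient layer tests condition differences per hemisphere and
band with Tukey–Kramer correction, and quantifies how the No-Go/Go
ratios change with age — the developmental hypothesis being a shift from
bilateral IFG involvement in young children toward right-lateralized
inhibition in adolescence.

## Pipeline

For each recording: common-average rereference within the grid → notch
filtering at 60/120/180 Hz (second-order IIR notch, quality factor 30,
zero phase) → per-channel HG envelope (4th-order zero-phase Butterworth
band-pass, modulus of the analytic signal) → epoching from 1 s before to
1 s after each visual cue (half-open window, cue sample on the post-cue
side) → z-normalization of each channel against the pooled pre-cue
baseline of all trials.

Electrode selection ranks the z-scored HG envelope: per electrode and
condition, the per-trial post-cue maximum is averaged over *correct*
trials; the motor electrode most activated in Go/Correct becomes `Cm`,
the IFG electrode most activated in No-Go/Correct becomes `Ci`. Ties
break toward the lower electrode index (logged). The pairing of
conditions to regions follows the screening logic of the task: movement
activates motor cortex, withholding activates the IFG. Spatial
(Gaussian) smoothing of activation values is a display device only and
plays no role in selection; `plot_activation_map()` draws a plain
per-electrode bar chart instead of a cortical surface.

Spectral analysis runs on the *raw* (rereferenced, notched) epochs of
`Cm`/`Ci` only: a Morlet event-related spectral perturbation (ERSP) at
2–200 Hz in 3 Hz steps, and STFT band power from which per-trial peaks
and the Eq.-style power ratio are computed. PAC runs on `Ci`.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| Sampling rate | 1200 Hz | clinical acquisition rate of the modeled protocol |
| Epoch window | [−1, +1) s | 1 s baseline, 1 s reaction period |
| Notch | 60/120/180 Hz, Q = 30 | mains + harmonics; narrow enough to spare beta/HG |
| HG band | 70–200 Hz | activation mapping band (reported HG ranges vary between 70–150 and 80–200 Hz in this literature; all bands are configurable) |
| Morlet | 6 cycles, 3 Hz steps | fixed-cycle trade-off between time and frequency resolution |
| STFT | 500 ms Hann window, 5 ms hop | see below |
| PAC phase bins | 2–20 Hz every 3 Hz, 3 Hz wide | theta-range phase resolution |
| PAC amplitude bins | 40–200 Hz, 20 Hz wide, 10 Hz hop | covers the gamma range at modest resolution; the geometry is a package choice and fully configurable |
| Permutation | 1000 shuffles, alpha 0.05 | per-bin null from circular time shifts |
| Bootstrap | 2000 resamples | percentile CI of the power ratio |

**The "5 ms window".** Protocols of this kind describe band power "in
each 5 ms window". A literal 5 ms analysis window cannot resolve 4–8 Hz
theta (one theta cycle lasts 125–250 ms), so `ecogng` reads 5 ms as the
STFT *hop* and uses a 500 ms Hann *analysis window*; both are arguments
of `stft_band_peaks()`. Epochs are reflect-padded by half a window so
frame centers tile the full epoch — exactly 200 post-cue frames at the
defaults.

**Ratios on z-scores.** Peaks are z-scores, so a Go-condition mean near
zero would make the ratio unstable; bands whose Go mean falls below a
small positive floor (0.05 z by default) are flagged undefined rather
than reported.

## The modulation index

For a phase band and an amplitude band, the composite signal
`z(t) = A_high(t) · exp(i φ_low(t))` combines the normalized
high-band Hilbert envelope with the low-band Hilbert phase. Under
independence the phasors cancel and `|mean z|` is near zero; if the
envelope is sinusoidally modulated, `A(t) = A₀(1 + m cos φ)`, the time
average is exactly `m/2`. This analytic law is the package's oracle:
`modulation_index()` recovers `m/2` within 10% on 100 s traces for
`m ∈ {0.2, 0.5, 1}` (tested).

The envelope is divided by its own post-cue mean, so the MI reads as a
*relative* modulation depth and is invariant to amplitude scaling; a
raw-envelope mode is available (`normalize = FALSE`).

**Trial averaging order.** Per trial, `z(t)` is averaged over the
post-cue second; the complex per-trial means are then averaged across
the condition's correct trials and the modulus is taken *last*. This
order is deliberate. The preferred coupling phase is a physiological
constant, so genuine coupling survives complex averaging, while the
estimator's no-coupling bias shrinks as 1/√(trials). Taking the modulus
per trial first was evaluated and rejected: the per-trial modulus is
blind to coupling phase, so circular-shift surrogates — which only
rotate each trial's complex mean — leave the null at coupled bins equal
to the observed value, and no injected coupling can ever reach
significance; the lowest phase bins (few cycles per second) also inflate
badly under that convention.

**Surrogates.** The null randomizes the phase/amplitude alignment by
circular time shifts of each trial's amplitude envelope against its
phase series. Shifts preserve both series' amplitude spectra and
autocorrelation, which sample shuffling would destroy (shuffling whitens
the envelope and inflates significance). The full circular
cross-correlation (one FFT pair per trial and bin) yields every shifted
composite mean at once, so 1000 shuffles cost only indexing. A bin is
significant when the observed MI exceeds the null's 95th percentile;
non-significant bins are zeroed before the condition ratio is formed,
and ratio cells whose Go denominator is zero after masking are flagged
undefined rather than infinite.

## Group statistics

Band-power peaks are pooled across patients at the trial level
(matching cross-patient box plots of such protocols; a per-patient-mean
mode exists as a sensitivity check), and No-Go/Correct vs Go/Correct is
tested per (hemisphere × band) stratum. Correction uses the
Tukey–Kramer studentized-range procedure, which handles the unequal
group sizes that a 1:6 cue ratio guarantees. The default family is *per
band*: the (hemisphere × condition) cells of one band form a one-way
layout with a pooled mean square error, and each hemisphere's condition
contrast is referred to the studentized range over those four means.
Pooling *all* bands into a single family (available as
`family = "global"`) was rejected as the default because peak variance
differs strongly between bands — HG z-peaks are an order of magnitude
more dispersed than theta peaks — and a globally pooled error term is
invalid under that heterogeneity. With equal group sizes the procedure
reduces to Tukey's HSD, which the test suite verifies against
`TukeyHSD()` directly.

Age trends of the per-patient No-Go/Go ratios are summarized by
Spearman rank correlation (two-sided). The source protocols describe
these trends only qualitatively; the rank correlation is this package's
quantitative choice — robust, monotone-invariant, and honest at n = 8.

## The synthetic cohort generator

Clinical ECoG of this kind is not publicly deposited, so validation
runs on synthetic cohorts whose ground truth is known by construction.
`simulate_session()` builds, per channel, 1/f^α Gaussian background
noise (α = 2 by default, synthesized by spectral shaping) plus mains
harmonics with per-channel amplitude and phase jitter, and injects:

* a HG burst (0.05–0.55 s post-cue, Hann-windowed) on the target motor
  channel for *responded Go trials* when the tested hand is
  contralateral to the grid;
* condition-dependent theta (6 Hz sinusoid), beta (band-limited noise),
  and HG (band-limited 90–130 Hz carrier) responses over the post-cue
  second on the target IFG channel, with Go gains of 1 and No-Go gains
  of 2 (in units of the background's own band SD);
* theta-phase modulation of the IFG HG envelope,
  `A(t) ∝ 1 + m cos(φ_theta)`, with depth `m` = 0.2 in Go and 0.6 in
  No-Go — the multiplicative construction matches the composite-signal
  estimator's model exactly, so recovery is checked against the `m/2`
  law;
* an age-dependent laterality weight `w(age)`, logistic with center 12
  years and slope 2 years, that shrinks the *left*-hemisphere No-Go
  excess (band gains and coupling depth) by `1 − w` while leaving the
  right hemisphere intact — the generator's rendering of the
  bilateral-to-right developmental shift. At `w = 1` the left-IFG No-Go
  response equals the Go baseline.

The second electrode of each ROI receives a half-gain copy (no
coupling) to emulate spatial falloff. Behavioral accuracy is Bernoulli
per cue type; responded trials get truncated-normal latencies (mean
0.45 s, SD 0.1 s, clipped to 0.15–1 s). Intertrial intervals are
uniform on [0.75, 1.25] s — a bounded, symmetric reading of a "1 s
jittered" interval; cues display for 1 s, and a response within that
second counts as a reaction.

What the generator does *not* emulate: cortical geometry and volume
conduction, epileptiform discharges, eye/EMG artifacts, electrode
drift, or non-stationary background. Passing tests therefore certify
the *estimators* — that each stage recovers what was injected at
realistic SNR — not robustness to every pathology of clinical data.

Default scales for table-style study conditions: 49 trials per run at
1:6, sampling at 1.2 kHz, 16 channels (a 2×8 strip with two IFG and two
motor contacts on the grid side), eight subjects aged 7–16 with four
left and four right grids and accuracies between 64 and 98%.

## Numerical choices

* **FFT lengths.** All long transforms run at 5-smooth lengths (R's
  mixed-radix FFT degrades sharply on lengths with large prime
  factors); series are reflect-padded to the next admissible length and
  trimmed.
* **Filters.** The HG envelope uses `signal::butter` order 4 applied
  forward–backward with reflect padding; edge state is initialized
  through the filter's DC gain so constant inputs pass exactly. The
  narrow PAC phase bands (down to 0.5–3.5 Hz at 1.2 kHz) make
  transfer-function IIR filters numerically unstable, so PAC
  decomposition and the ERSP pre-filter use FFT-domain zero-phase
  band-passes with raised-cosine transition edges, which also yield the
  analytic signal in the same step.
* **Notch settling.** The Q = 30 notch rings for ~Q/(π f₀) seconds;
  padding is sized to six times that.
* **Baseline pooling.** Baselines are pooled across trials per channel
  (and per frequency for spectral data): with only 7 No-Go trials per
  run, per-trial baseline SDs are too noisy; a per-trial mode exists
  behind `per_trial = TRUE`.
* **Stage order.** Rereference before notch (the two are listed in one
  breath in such protocols; the order is fixed here and immaterial to
  within-grid analyses since both are linear).
* **Determinism.** Every stochastic step takes a seed;
  `run_pipeline()` derives per-subject, per-stage seeds from one master
  seed and records them in a JSON manifest together with the config
  hash, so any run is bit-reproducible.

## Validation scales

The shipped test suite runs the full chain at reduced scale, chosen to
exercise every code path at realistic SNR: single sessions of 21–49
trials with 4–16 channels, 200 permutation shuffles, 10 seeds for
electrode-selection recovery, 6 cohort replicates (8 subjects each) for
the laterality trend, and 4 null sessions × 2 conditions × 105 bins for
permutation calibration. The acceptance script scales up to 20 null
sessions (4200 pooled bins) and a full 8-subject cohort. Sizes are
stated here so that readers know what the green suite does and does not
demonstrate; all of them are arguments, not constants.

## Known limitations

* ROI labels come from channel metadata; no electrode localization or
  template-space mapping is provided, and no cortical surface rendering.
* The PAC ratio map compares *masked* grids, so its defined support
  depends on the Go condition's significance pattern; with few trials
  the map can be sparse or empty (flagged, never silently infinite).
* Tukey–Kramer and the unpaired t-test coexist as in the modeled
  protocol; the corrected inference is the studentized-range one, the
  Welch t is reported unadjusted alongside.
* Trial-level pooling across patients ignores within-patient
  correlation; the per-patient-mean mode is the conservative
  cross-check, and mixed-effects modeling is out of scope.
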