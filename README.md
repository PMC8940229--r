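# ecogng

Analysis of **Go/No-Go motor inhibition from electrocorticography
(ECoG)**, for researchers working with intracranial recordings of
response-inhibition tasks (e.g. pediatric epilepsy-monitoring cohorts).

During a Go/No-Go run, frequent Go cues demand a button press and rare
No-Go cues (1:6 ratio, 49 trials) demand withholding. The package
quantifies where and how withholding shows up in the cortical signal:

* **High-gamma activation mapping.** Per channel, the 70–200 Hz Hilbert
  envelope is z-scored against the pooled pre-cue baseline; the mean
  over correct trials of the per-trial post-cue maximum ranks
  electrodes, selecting the motor electrode `Cm` (Go/Correct) and the
  inferior-frontal electrode `Ci` (No-Go/Correct).
* **Band-power ratio.** Per band (theta 4–8, beta 12–40, high gamma
  70–200 Hz), STFT band-power peaks are z-scored and the ratio

  `power ratio = No-Go/Correct_mean / Go/Correct_mean`

  summarizes the inhibition effect on `Ci` (ratio > 1 means the band is
  more active when withholding).
* **Phase–amplitude coupling.** The composite-signal modulation index
  `MI = |⟨A_high(t) e^{iφ_low(t)}⟩|` is computed per (phase bin ×
  amplitude bin), per trial, averaged across trials as complex means.
  Under sinusoidal modulation of depth *m* the MI is exactly *m*/2.
  Significance comes from circular-shift permutation surrogates (1000
  shuffles, alpha 0.05); non-significant bins are zeroed and the
  No-Go/Go ratio map compares conditions.
* **Group statistics.** Cross-patient No-Go vs Go comparisons per
  hemisphere and band with Tukey–Kramer correction (valid for the
  unequal 1:6 group sizes), and Spearman age trends of the per-patient
  ratios — the developmental question being the shift from bilateral
  IFG inhibition in children toward right lateralization with age.

Because clinical recordings of this kind are not publicly deposited,
the package ships a first-class **synthetic cohort generator** that
injects all of the above effects (1/f background, line noise,
cue-locked bursts, condition-dependent band gains, theta-to-gamma
coupling, and a logistic age–laterality model) with recorded ground
truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(ecogng)

prof <- subject_profile("S01", age = 11, grid_side = "right",
                        hands_tested = "left", behavioral_accuracy = 0.95)
sr <- simulate_session(prof, task_config(), sim_config(), seed = 42)
sr$session
#> <ecog_session> 16 channels x 118934 samples @ 1200 Hz (99.1 s)
#>   ROIs: IFG=2, motor=2, other=12
#>   events: 49 (42 go / 7 nogo)

pw <- subject_power_analysis(sr$session, pipeline_config(n_boot = 500), seed = 1)
pw$selection[c("cm", "ci")]      # matches sr$truth$cm_channel / ci_channel
#> $cm [1] 7      $ci [1] 3

pw$ratios[, c("band", "mean_nogo", "mean_go", "ratio", "ci_lo", "ci_hi")]
#>    band mean_nogo mean_go ratio ci_lo ci_hi
#> 1 theta      4.68    2.68  1.75  1.27  2.49
#> 2  beta     11.26    3.52  3.20  2.78  3.70
#> 3    hg     22.29    4.95  4.50  4.05  4.97

pac <- subject_pac_analysis(pw$epochs_raw, pw$selection$ci,
                            pipeline_config(n_shuffles = 200), seed = 2)
c(defined = sum(pac$ratio$defined), median_ratio = pac$median_ratio)
#> defined 12   median_ratio 3.42
```

Reading the numbers: all three band ratios exceed 1 — theta, beta and
high-gamma peaks are larger when the subject withholds — matching the
2× No-Go gains this session was generated with. The PAC ratio map's
defined cells (bins significant in both conditions) have a median
No-Go/Go modulation ratio of 3.4, recovering the injected 0.6 vs 0.2
coupling-depth contrast.

`run_pipeline()` chains all stages over a cohort and writes TSV tables
plus a reproducibility manifest; `inst/exec/ecogng` exposes `simulate`
and `run-all` verbs for shell use, and EDF/TSV readers and writers
(`write_session()`, `read_session()`) connect the pipeline to standard
clinical interchange formats.

## Layout

```
R/                 implementation (simulation, preprocessing, activation,
                   spectral power, PAC, group stats, I/O, pipeline)
tests/testthat/    unit + property + acceptance suites
vignettes/         methods vignette (model, estimators, design decisions)
scripts/           acceptance script
inst/exec/ecogng   command-line front end
```
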