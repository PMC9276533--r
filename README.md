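# audsleep

Analysis of auditory-evoked intracranial responses across wakefulness and
sleep.

Human depth-electrode recordings (microwire LFP with sorted spike trains,
plus macro-contact iEEG) during natural sleep allow a direct comparison of
auditory responses between wakefulness (W), NREM and REM sleep. `audsleep`
implements the full comparison pipeline for such sessions and a
ground-truth synthetic-session generator so every stage is testable
without patient data.

## What it computes

* **Response-interval detection.** Single-trial spike trains are smoothed
  with a unit-area Gaussian (σ = 10 ms); band power (low gamma 40–80 Hz,
  high gamma 80–200 Hz, alpha–beta 10–30 Hz) is a Hilbert envelope in dB
  after zero-phase filtering at 1 kHz. Each millisecond of the stimulus
  window (+100 ms) is tested against baseline ([−500, 0) ms, subtracted
  per trial and state) with a one-tailed Wilcoxon–Mann–Whitney test,
  FDR-corrected (Benjamini–Hochberg, base alpha 0.01). Significant
  milliseconds are bridged across sub-threshold gaps (< 2 ms spikes /
  < 4 ms power), short components are removed (5 / 10 / 50 ms), and
  spiking responses must exceed 1.5% of the stimulus duration. Latency is
  the first significant millisecond (≤ 200 ms). Six trials per condition
  minimum; trials beyond 5 s.d. in mean power are excluded.
* **Cross-state gain** over the union of intervals detected in either
  state:

  `Gain = 100 · (R_sleep − R_awake) / max(|R_sleep|, |R_awake|)`

* **Mutual information** (bits) between spike counts in 50-ms stimulus
  bins and bin identity, plug-in estimator, trials equalized across
  states by seeded subsampling.
* **Inter-trial phase coherence** at 40 Hz for click-trains:
  `ITPC = |N⁻¹ Σₖ exp(iφₖ)|`.
* **Sound-envelope coupling**: cross-correlation lag (0–250 ms) plus
  Pearson r between the 200-Hz high-gamma response and the 5-ms sound
  envelope, with a circular-shift permutation p.
* **SWA stratification**: responses on low- (< 20th percentile) vs high-
  (> 80th percentile) slow-wave-activity trials, Mann–Whitney compared.
* **Automatic iEEG sleep scoring** from 30-s delta power percentiles
  (> 55th ⇒ NREM, < 20th ⇒ W/REM, split by a behaviour proxy), with
  per-state agreement against a reference hypnogram.

## Worked example

Simulate a 600-s session whose single cluster responds at 100% strength in
wakefulness and 70% in NREM (an injected −30% gain), then detect and
compare:

```r
library(audsleep)

stimuli <- generate_stimulus_set(
  data.frame(stimulus_id = c("word1", "click1"),
             stim_type = c("word", "click_train_40hz"),
             duration = c(1.0, 1.0)), rng_seed = 7)
hyp <- hypnogram_blocks(c("W", "N2", "N3", "W", "N2"), 4)
gt <- session_ground_truth(hyp, rng_seed = 7)
session <- generate_session(gt, stimuli, 600)
#> <synthetic_session> 600 s, 2 channel(s), 1 cluster(s), 199 trial(s)

tt <- session$trial_table
tt$state <- c(W = "W", N1 = "NREM", N2 = "NREM", N3 = "NREM",
              REM = "REM")[tt$state]
tms <- lapply(c(W = "W", NREM = "NREM"), function(s) {
  smooth_spike_trains(session$spikes$spike_time_s,
                      tt$onset_s[tt$stimulus_id == "word1" & tt$state == s],
                      window_ms = c(-500, 1100))
})
cmp <- compare_states(tms, detection_params("spike"), 1000)
cmp$detections$W
#> <response_intervals> 14 interval(s), total 415 ms, magnitude 7.64, latency 134 ms

g <- compute_gain(cmp$magnitudes[["NREM"]], cmp$magnitudes[["W"]])
sprintf("R_wake = %.2f, R_NREM = %.2f spikes/s; gain = %.1f%%",
        g$r_awake, g$r_sleep, g$gain)
#> "R_wake = 6.83, R_NREM = 6.14 spikes/s; gain = -10.0%"
```

The detected intervals track the word's syllabic envelope; the magnitudes
are mean baselined rates over the interval union, and the single-cluster
gain estimate (−10%) scatters around the injected −30% (the acceptance
suite shows the mean over 20 clusters recovering it). The 40-Hz
entrainment of the iEEG channel:

```r
onc <- tt$onset_s[tt$stimulus_id == "click1" & tt$state == "W"]
tmc <- epoch_trials(session$recording$signal[2, ], 1000, onc,
                    c(-500, 1100), baselined = FALSE)
it <- compute_itpc(tmc, 1000)
sprintf("ITPC at 40 Hz (W, iEEG): %.3f over %d trials", it$itpc, it$n)
#> "ITPC at 40 Hz (W, iEEG): 0.935 over 39 trials"
```

close to the value implied by the injected phase jitter of 0.3 rad
(exp(−0.3²/2) ≈ 0.956). `run_pipeline(pipeline_config(...))` chains all
stages (load/simulate → optional auto-scoring → epoch → outlier exclusion
→ detection → statistics) into tidy tables plus a run manifest with trial
conservation counts; `write_session()`/`read_session()` exchange sessions
as EDF + WAV + TSV + JSON.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package end to end on a seeded synthetic session
(stimulus generation → session synthesis → detection → cross-state
statistics), checks trial conservation, and writes the report. Patient
recordings of this kind are not publicly downloadable, so the report
carries no numeric reproduction targets; the package's quantitative
guarantees (estimator
calibration, parameter recovery, scorer agreement) live in
`tests/testthat/test-acceptance.R`.

## Vignette

`vignettes/audsleep-methods.Rmd` documents the models, parameter choices,
numerical conventions, what the generator does and does not emulate, and
the measured caveats of the detection procedure.
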