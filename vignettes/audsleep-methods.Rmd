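---
title: "Methods: auditory-evoked intracranial responses across vigilance states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditory-evoked intracranial responses across vigilance states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human intracranial recordings during natural sleep make it possible to ask
how much of the auditory response survives loss of consciousness. The
recordings combine two spatial scales: microwire local field potentials
(LFP) with sorted single/multi-unit spike trains, and macro-contact iEEG.
Sounds (40-Hz click-trains, tones, words, sentences, music; 0.5–9.4 s) are
presented intermittently across wakefulness (W), NREM and REM sleep, and
the response of every unit and channel is compared across states.

`audsleep` implements that comparison pipeline: trial epoching with
baseline normalization, band-power envelopes, detection of significant
response intervals, cross-state gain, spike-count mutual information (MI),
40-Hz inter-trial phase coherence (ITPC), sound-envelope coupling,
slow-wave-activity (SWA) stratification, and an automatic iEEG sleep
scorer — plus a synthetic-session generator with known ground truth, since
the patient recordings themselves are not publicly available.

## Signal processing

* **Bands** (Hz): low gamma 40–80, high gamma 80–200 (a proxy for local
  firing), alpha–beta 10–30 (the band showing stimulus-induced
  desynchronization, ABD), SWA 0.5–4, sigma 10–16.
* **Filtering.** Signals are down-sampled to 1 kHz (anti-aliased at 0.4×
  the target rate) and band-passed with a zero-phase frequency-domain
  mask with raised-cosine transitions (half-width ≤ 25% of the band
  edge). Zero phase matters because response *latency* is read off the
  filtered envelope; any group delay would bias it. A two-pass FIR would
  serve equally; the FFT mask is simpler and handles the 0.5-Hz SWA edge
  without a 7000-tap kernel.
* **Power envelope.** Hilbert analytic amplitude, expressed as
  20·log10(amplitude) dB. The amplitude-vs-power dB convention is
  immaterial downstream because every statistic is a baseline difference
  or a ratio of baselined magnitudes.
* **Epoching.** Each trial is cut on a 1-ms grid with a [−500, 0) ms
  baseline window; the trial's own mean baseline is subtracted, separately
  per state, channel and band. Trials reaching past the recording bounds
  are flagged (never silently dropped), as are outlier trials whose mean
  epoch power exceeds the group mean + 5 s.d. (computed per channel ×
  stimulus × state; the grouping is a package choice).
* **Spike rates.** Single-trial spike trains are convolved with a
  unit-area Gaussian (σ = 10 ms), giving instantaneous rate in spikes/s;
  each trace integrates back to its spike count.

## Response-interval detection

For every millisecond of the test window (stimulus duration + 100 ms),
across-trial values are compared to baseline activity with a one-tailed
Wilcoxon–Mann–Whitney test (increase for spiking and gamma power,
decrease for alpha–beta), followed by Benjamini–Hochberg FDR control at
base alpha 0.01 ("false-discovery rate" is taken to mean BH, its default
reading in this literature). Significant milliseconds are assembled into
intervals: gaps shorter than 2 ms (spikes) / 4 ms (power) are bridged
first, then components shorter than 5 ms (spikes), 10 ms (gamma) or 50 ms
(alpha–beta) are removed; both orders are available for sensitivity
checks. Spiking responses must additionally total more than 1.5% of the
stimulus duration. A minimum of six usable trials per condition is
enforced. Latency is the first significant millisecond, accepted only if
it falls within 200 ms.

**Baseline sample.** The test needs a baseline distribution that is
*distributionally matched* to the per-millisecond response values. Using
each trial's baseline *mean* turns out to be powerless for sparse
spiking: a σ = 10 ms smoothed rate is zero-inflated (no spike within
kernel reach ⇒ exactly 0), while per-trial means are smooth, so the rank
test compares a spiky sample against a smooth one and its AUC stays near
0.5 even at a several-fold rate increase. The default baseline sample is
therefore the pooled instantaneous values at baseline milliseconds
subsampled every 50 ms (well past the kernel's reach); the per-trial-mean
variant is retained as an option. With the pooled baseline, a doubling of
a 30-spikes/s rate over 30 trials is detected essentially always with
interval Jaccard ≈ 0.9 (see the acceptance tests).

Two honest caveats, both measured by the test suite: (1) the smoothing
kernel advances detected onsets by about one σ, so latencies recover an
injected 50-ms onset at ≈ 39 ± 5 ms — a known, stable bias of the
procedure itself; (2) because the same baseline pool is reused for every
millisecond, channel-level false-positive rates grow with trial count
(the per-column p-values stay calibrated, but their errors are shared);
at realistic tens of trials per condition, fewer than ~1–2% of null
channels yield any detected spiking response.

## Cross-state statistics

* **Gain** = 100 · (R_sleep − R_awake) / max(|R_sleep|, |R_awake|), where
  the magnitudes are mean baselined responses measured over the *union*
  of the intervals detected in either state, so both states are scored on
  identical time support. Gains are saturated at ±100 (the raw ratio can
  reach ±200 when the two magnitudes have opposite signs).
* **MI.** Each stimulus is divided into 50-ms bins (a 450-ms word gives
  9 bins); spike counts per (trial, bin) are pooled over stimuli and the
  plug-in MI between count and bin identity is computed in bits. When
  states are compared, trial counts are equalized per stimulus by seeded
  subsampling, repeated 10× with the median reported. The plug-in
  estimator is biased upward by ≈ (bins−1)(levels−1)/(2N·ln2); tests hold
  it below 3× that bound on independent data. Results are stable across
  20/50/100-ms bins (rank correlation of channels ≥ 0.9).
* **ITPC** = |N⁻¹ Σ exp(iφₖ)| over trials, with φₖ the phase of a
  Hann-tapered Fourier coefficient at 40 Hz over the full stimulus
  window. 1 = perfect locking; uniform phases give ≈ √(π/4)/√N.
* **Envelope coupling.** The sound envelope is the non-overlapping 5-ms
  mean of the squared waveform; the high-gamma response is block-averaged
  to the same 200-Hz grid. The lag (0–250 ms, a physiological bound the
  protocol leaves open) maximizing the cross-correlation is found first,
  then the Pearson r at that lag, with a circular-shift permutation p.
  Shifts are drawn over the *full* cycle: restricting them to
  "well-separated" offsets breaks the group structure and was measured to
  inflate the 1% tail roughly tenfold (even excluding only shifts within
  ±max-lag leaves ~9% at nominal 1%); with full-cycle shifts the null is
  exact. The price is a p floor under true coupling — shifts that happen
  to re-align the trace within the lag window reproduce the observed
  correlation, contributing ≈ (max_lag/step)/L of the permutation mass —
  so short stimuli pay a power cost for an honest null.
* **SWA stratification.** Per trial, SWA (0.5–4 Hz) and sigma (10–16 Hz)
  power in the 2 s before onset; trials below the 20th / above the 80th
  percentile (linear-interpolation percentiles throughout) are compared
  by a two-sample Mann–Whitney test, requiring six trials per tail.
* **Latency–gain correlation.** Pearson r across channels with a
  label-permutation p (10,000 permutations, two-sided).

## Automatic sleep scoring

30-s spectrograms (0–40 Hz, one demeaned periodogram per epoch, averaged
over iEEG channels) give per-epoch delta power. Epochs above the 55th
percentile are NREM; epochs below the 20th are W/REM candidates, split by
a behaviour proxy standing in for video: awake evidence ⇒ W; candidates
in the second half of the night lying inside quiescent periods longer
than 3 min ⇒ REM (quiescence typically spans whole sleep bouts, so the
run may begin earlier; "second part of the night" is read as after the
session midpoint). Everything else — including the 20th–55th percentile
band — is left undetermined and excluded from trial-state assignment, the
conservative reading. Percentiles make the hypnogram invariant to
amplitude rescaling. Agreement with a reference hypnogram is the percent
of auto-labelled epochs whose reference label matches (NREM ↔ N2/N3),
with undetermined epochs excluded from denominators.

## The synthetic-session generator

The generator's defaults state a world matching the experimental protocol:
sessions of at least 10 min with pseudo-random stimulation (shuffled
balanced blocks; the inter-stimulus interval is exposed as a parameter,
uniform 1–3 s by default, since the protocol does not fix one), a minimum
of six trials per stimulus per state, and 30-s hypnogram epochs.

* **Spikes**: inhomogeneous Poisson, rate = baseline × (1 + 3 ·
  strength/100 · envelope(t − latency)), with per-state strengths in
  percent (e.g. W 100, NREM 70 injects a −30% sleep gain) and an optional
  per-trial attenuation that grows with concurrent SWA.
* **Fields** at 1 kHz, in µV: 1/f² Gaussian background (sd 10);
  state-dependent delta (W 3, N1 6, N2 14, N3 24, REM 3.5) with lognormal
  per-epoch amplitude jitter (sd 0.3 emulates the real overlap between
  state distributions; 0.05 gives cleanly separated states for
  best-case scorer tests); sigma bursts in NREM; a high-gamma carrier
  whose amplitude tracks the sound envelope with an *exact* in-sample
  correlation r (the orthogonalized-noise construction makes the injected
  coupling equal the target to machine precision); a tonic alpha–beta
  rhythm attenuated during stimuli by the per-state ABD depth in dB; and
  a 40-Hz steady-state component during click-trains whose per-trial
  phase jitter is Gaussian with a per-state s.d.
* **Reproducibility**: every component draws from a substream derived by
  hashing the master seed with a component key, so sessions are
  bit-identical under a fixed seed and adding a channel never perturbs
  existing ones.

What the generator does **not** emulate: realistic acoustics or
phonetics (words are envelope-modulated noise — only envelope structure
and bin discriminability matter to the analyses), epileptiform activity,
K-complexes and evoked slow waves, eye/EMG channels, electrode geometry,
or non-stationarity beyond the hypnogram. A green recovery test therefore
establishes that the *estimators* are unbiased and calibrated in a world
with the stated effect sizes — not that real recordings meet those
assumptions.

## Numerical conventions

Seconds from session start for all timestamps; half-open [start, end)
intervals; 0-based 1-ms grids relative to stimulus onset; type-7
(linear-interpolation) percentiles; exact Mann–Whitney null (closed-form
when tie-free, full enumeration otherwise) for groups of ≤ 8, mid-rank
normal approximation with tie and continuity corrections above; N1
epochs are treated as NREM where a mapping is needed but the bundled
hypnograms place trials in W/N2/N3/REM so the choice is immaterial.

## Limitations

The pipeline stops at tidy per-response tables; the nested
mixed-model inference over patients/channels/stimuli is deliberately out
of scope, as are spike sorting, electrode localization and manual
artifact rejection. Detection inherits the procedure's
characteristics: onset latencies are advanced by about the kernel σ, and
the shared baseline pool makes channel-level error rates grow with trial
count. The ABD band (10–30 Hz) overlaps sigma (10–16 Hz), so NREM spindle
activity dilutes measured desynchronization — in the generator as in
real data.
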