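Package: audsleep
Title: Auditory-Evoked Intracranial Responses Across Wakefulness and Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for auditory-evoked intracranial recordings
    (microwire LFP, iEEG macro contacts and sorted spike trains) compared
    across wakefulness, NREM and REM sleep. Implements trial epoching with
    baseline normalization, Hilbert band-power envelopes (low/high gamma,
    alpha-beta, slow-wave, sigma), detection of significant response
    intervals by pointwise rank tests with FDR control, component filtering
    and gap bridging, response latency extraction, cross-state response
    gain, mutual information of spike counts, 40-Hz inter-trial phase
    coherence, sound-envelope coupling, slow-wave-activity trial
    stratification, and automatic iEEG-based sleep staging with agreement
    validation. Ships a fully parameterized synthetic-session generator
    (stimuli, inhomogeneous-Poisson spikes, field potentials, hypnogram)
    with known ground truth for end-to-end testing, plus minimal EDF/WAV/TSV
    readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
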