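#' Auditory stimulus set generator
#'
#' Builds the waveforms of the stimulus battery used throughout the
#' package: 40-Hz click-trains, pure tones, word-like and sentence-like
#' utterances, and music-like sequences. Durations are restricted to the
#' 0.5--9.4 s range of the experimental battery. Speech and music stimuli
#' are emulated as amplitude-modulated noise / harmonic stacks: only their
#' intensity envelopes matter to the analyses (envelope tracking, spike
#' rate modulation, mutual information), not their phonetics.
#'
#' @param specs data.frame with columns `stimulus_id`, `stim_type`
#'   (one of `"click_train_40hz"`, `"tone"`, `"word"`, `"sentence"`,
#'   `"music"`) and `duration` in seconds.
#' @param rate audio sampling rate in Hz, at least 8000.
#' @param rng_seed integer master seed; each stimulus draws from its own
#'   substream so the set is reproducible element-wise.
#' @return a named list of `stimulus_spec` objects, each a list with
#'   fields `stimulus_id`, `stim_type`, `duration`, `rate`, `waveform`,
#'   and for click-trains `click_onsets_s`.
#' @examples
#' st <- generate_stimulus_set(
#'   data.frame(stimulus_id = "c1", stim_type = "click_train_40hz",
#'              duration = 1.0), rng_seed = 7)
#' length(st$c1$click_onsets_s)  # 40 clicks
#' @export
generate_stimulus_set <- function(specs, rate = 16000, rng_seed = 1) {
  stopifnot(is.data.frame(specs),
            all(c("stimulus_id", "stim_type", "duration") %in% names(specs)))
  if (rate < 8000) stop("audio sampling rate must be >= 8 kHz", call. = FALSE)
  if (anyDuplicated(specs$stimulus_id)) {
    stop("duplicate stimulus_id in specs", call. = FALSE)
  }
  types <- c("click_train_40hz", "tone", "word", "sentence", "music")
  bad_type <- setdiff(specs$stim_type, types)
  if (length(bad_type)) {
    stop("unknown stim_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  bad <- specs$duration < 0.5 | specs$duration > 9.4
  if (any(bad)) {
    stop(sprintf("stimulus duration out of range [0.5, 9.4] s: %s",
                 paste(specs$stimulus_id[bad], collapse = ", ")),
         call. = FALSE)
  }
  out <- vector("list", nrow(specs))
  names(out) <- specs$stimulus_id
  for (i in seq_len(nrow(specs))) {
    out[[i]] <- make_stimulus(specs$stimulus_id[i], specs$stim_type[i],
                              specs$duration[i], rate,
                              derive_seed(rng_seed,
                                          paste0("stim:", specs$stimulus_id[i])))
  }
  out
}

make_stimulus <- function(id, type, duration, rate, seed) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  wav <- with_seed(seed, switch(
    type,
    click_train_40hz = {
      # exactly round(40 * duration) clicks at 25-ms spacing
      n_clicks <- round(40 * duration)
      onsets <- (seq_len(n_clicks) - 1) * 0.025
      w <- numeric(n)
      click_len <- max(1L, round(0.001 * rate))   # 1-ms rectangular click
      for (o in onsets) {
        i0 <- round(o * rate) + 1L
        idx <- i0:min(n, i0 + click_len - 1L)
        w[idx] <- 1
      }
      attr(w, "click_onsets_s") <- onsets
      w
    },
    tone = {
      f <- stats::runif(1, 300, 2000)
      w <- sin(2 * pi * f * t)
      w * onset_ramp(n, rate)
    },
    word = {
      # 2-4 syllables: gamma-shaped envelope bumps at a 3-6 Hz syllabic rate
      env <- syllabic_envelope(duration, rate,
                               n_syll = max(2L, round(duration * 4)))
      stats::rnorm(n) * env
    },
    sentence = {
      env <- syllabic_envelope(duration, rate,
                               n_syll = max(4L, round(duration * 4)))
      stats::rnorm(n) * env
    },
    music = {
      # harmonic stack with beat-modulated intensity (~2 Hz) and note changes
      n_notes <- max(2L, round(duration * 2))
      f0 <- 220 * 2^(sample(0:12, n_notes, replace = TRUE) / 12)
      note <- pmin(n_notes, 1L + floor(t / duration * n_notes))
      w <- numeric(n)
      for (h in 1:3) {
        w <- w + sin(2 * pi * h * f0[note] * t) / h
      }
      beat <- 0.55 + 0.45 * sin(2 * pi * 2 * t + stats::runif(1, 0, 2 * pi))
      w * beat * onset_ramp(n, rate)
    }))
  onsets <- attr(wav, "click_onsets_s")
  wav <- as.numeric(wav) / max(abs(wav), 1e-12)
  sp <- list(stimulus_id = id, stim_type = type, duration = duration,
             rate = rate, waveform = wav)
  if (!is.null(onsets)) sp$click_onsets_s <- onsets
  class(sp) <- "stimulus_spec"
  sp
}

onset_ramp <- function(n, rate, ramp_s = 0.01) {
  r <- min(n, round(ramp_s * rate))
  ramp <- rep(1, n)
  if (r > 1) {
    ramp[1:r] <- (1 - cos(pi * seq_len(r) / r)) / 2
    ramp[(n - r + 1):n] <- rev(ramp[1:r])
  }
  ramp
}

# syllable-like envelope: gamma bumps centred at jittered syllable times,
# guaranteeing multiple local maxima and >= 3 distinct 50-ms bin levels
syllabic_envelope <- function(duration, rate, n_syll) {
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  centers <- (seq_len(n_syll) - 0.5) / n_syll * duration +
    stats::runif(n_syll, -0.02, 0.02) * duration
  amps <- stats::runif(n_syll, 0.4, 1)
  width <- duration / n_syll / 3
  env <- numeric(n)
  for (k in seq_len(n_syll)) {
    env <- env + amps[k] * exp(-(t - centers[k])^2 / (2 * width^2))
  }
  env / max(env)
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s [%s], %.2f s @ %d Hz\n",
              x$stimulus_id, x$stim_type, x$duration, x$rate))
  invisible(x)
}
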