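#' Pipeline configuration with the protocol defaults
#'
#' All tunables of the end-to-end analysis, defaulting to the protocol
#' values: 0.01 base alpha with FDR correction, [-500, 0) ms baseline,
#' 10-ms spike smoothing kernel, 5-s.d. outlier exclusion, six-trial
#' minimum, 50-ms MI bins, 1000 envelope permutations, 10,000 latency-gain
#' permutations. Validation rejects inconsistent settings (e.g. an
#' alpha--beta band tested for increases) before any computation. The
#' configuration round-trips through JSON unchanged.
#'
#' @param session_dir directory with a serialized session (see
#'   [write_session()]); `NULL` when `simulate` is given
#' @param simulate list with `gt`, `stimuli`, `session_length` to generate
#'   the session in-memory instead of reading one
#' @param power_bands band-power analyses to run (names from
#'   [band_definitions()])
#' @param baseline_ms baseline window, default `c(-500, 0)`
#' @param spike_sigma_ms spike smoothing kernel s.d., default 10
#' @param outlier_sd outlier threshold, default 5
#' @param min_trials minimum trials per condition, default 6
#' @param mi_bin_ms MI bin width, default 50
#' @param n_perm_env,n_perm_latgain permutation counts
#' @param tails named tail overrides per band (validated)
#' @param use_auto_scoring re-assign trial states from the automatic iEEG
#'   scorer instead of the reference hypnogram
#' @param rng_seed master seed for all stochastic stages
#' @param out_dir optional output directory for the tidy TSV tables
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(session_dir = NULL, simulate = NULL,
                            power_bands = c("high_gamma", "alpha_beta"),
                            baseline_ms = c(-500, 0), spike_sigma_ms = 10,
                            outlier_sd = 5, min_trials = 6L, mi_bin_ms = 50,
                            n_perm_env = 1000, n_perm_latgain = 10000,
                            tails = NULL, use_auto_scoring = FALSE,
                            rng_seed = 1, out_dir = NULL) {
  stopifnot(xor(is.null(session_dir), is.null(simulate)))
  bad <- setdiff(power_bands, c("low_gamma", "high_gamma", "alpha_beta"))
  if (length(bad)) stop("unsupported power band(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  expected <- c(low_gamma = "increase", high_gamma = "increase",
                alpha_beta = "decrease")
  if (!is.null(tails)) {
    for (b in names(tails)) {
      if (!identical(tails[[b]], expected[[b]])) {
        stop(sprintf("invalid tail for %s: %s (must be %s)", b, tails[[b]],
                     expected[[b]]), call. = FALSE)
      }
    }
  }
  cfg <- list(session_dir = session_dir, simulate = simulate,
              power_bands = power_bands, baseline_ms = baseline_ms,
              spike_sigma_ms = spike_sigma_ms, outlier_sd = outlier_sd,
              min_trials = as.integer(min_trials), mi_bin_ms = mi_bin_ms,
              n_perm_env = n_perm_env, n_perm_latgain = n_perm_latgain,
              use_auto_scoring = use_auto_scoring,
              rng_seed = as.integer(rng_seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a synthetic session to disk in the interchange formats
#'
#' EDF for the recording, WAV per stimulus, TSV for trials / spikes /
#' hypnogram / behaviour, JSON sidecar for the ground truth.
#'
#' @param session a `synthetic_session`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(session$recording, file.path(dir, "recording.edf"))
  write_trial_table(session$trial_table, file.path(dir, "trials.tsv"))
  write_spike_table(session$spikes, file.path(dir, "spikes.tsv"))
  write_hypnogram(session$hypnogram, file.path(dir, "hypnogram.tsv"))
  write_tsv(session$behavior, file.path(dir, "behavior.tsv"))
  sdir <- file.path(dir, "stimuli")
  dir.create(sdir, showWarnings = FALSE)
  for (s in session$stimuli) {
    write_wav(s$waveform, s$rate, file.path(sdir, paste0(s$stimulus_id, ".wav")))
  }
  stim_meta <- data.frame(
    stimulus_id = vapply(session$stimuli, function(s) s$stimulus_id, ""),
    stim_type = vapply(session$stimuli, function(s) s$stim_type, ""),
    duration = vapply(session$stimuli, function(s) s$duration, numeric(1)))
  write_tsv(stim_meta, file.path(sdir, "stimuli.tsv"))
  if (!is.null(session$ground_truth)) {
    write_ground_truth(session$ground_truth,
                       file.path(dir, "ground_truth.json"))
  }
  invisible(dir)
}

#' Read a serialized session back into memory
#'
#' Validates every container on ingest: recording rate >= 1 kHz, strictly
#' increasing trial onsets (violations name the row), sorted spike times,
#' contiguous hypnogram. Channels with unknown roles are skipped with a
#' warning and counted for the manifest.
#'
#' @param dir session directory written by [write_session()]
#' @return list with `recording`, `spikes`, `trial_table`, `hypnogram`
#'   (or `NULL`), `behavior` (or `NULL`), `stimuli` (waveform + metadata)
#' @export
read_session <- function(dir) {
  recording <- read_edf(file.path(dir, "recording.edf"))
  trial_table <- read_trial_table(file.path(dir, "trials.tsv"))
  spikes <- read_spike_table(file.path(dir, "spikes.tsv"))
  hyp_path <- file.path(dir, "hypnogram.tsv")
  hypnogram <- if (file.exists(hyp_path)) read_hypnogram(hyp_path) else NULL
  beh_path <- file.path(dir, "behavior.tsv")
  behavior <- if (file.exists(beh_path)) {
    utils::read.table(beh_path, header = TRUE, sep = "\t")
  } else NULL
  stimuli <- NULL
  meta_path <- file.path(dir, "stimuli", "stimuli.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    stimuli <- lapply(seq_len(nrow(meta)), function(i) {
      w <- read_wav(file.path(dir, "stimuli",
                              paste0(meta$stimulus_id[i], ".wav")))
      structure(list(stimulus_id = meta$stimulus_id[i],
                     stim_type = meta$stim_type[i],
                     duration = meta$duration[i], rate = w$rate,
                     waveform = w$waveform), class = "stimulus_spec")
    })
    names(stimuli) <- meta$stimulus_id
  }
  list(recording = recording, spikes = spikes, trial_table = trial_table,
       hypnogram = hypnogram, behavior = behavior, stimuli = stimuli)
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in order: load (or simulate) the session; optionally re-score
#' sleep automatically from the iEEG and re-assign trial states; epoch and
#' baseline spike rates and band powers per (unit/channel, stimulus,
#' state); flag outlier trials; detect significant response intervals;
#' compute cross-state gains over the union of intervals, latencies,
#' state-wise mutual information, 40-Hz ITPC for click-trains, and
#' sound-envelope coupling for responsive channels. Deterministic given the
#' config (including its seed); emits tidy tables plus a run manifest whose
#' trial counts obey read = used + outlier-excluded + boundary-skipped +
#' refused (insufficient trials).
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result`: `responses`, `gains`,
#'   `unit_stats`, `manifest` (and the tables written to `out_dir` when
#'   configured)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$simulate)) {
    session <- generate_session(config$simulate$gt, config$simulate$stimuli,
                                config$simulate$session_length)
  } else {
    session <- read_session(config$session_dir)
  }
  tt <- session$trial_table
  if (config$use_auto_scoring) {
    spect <- spectrogram_30s(session$recording)
    hyp <- auto_score(spect, session$behavior)
    ep <- pmin(nrow(hyp), floor(tt$onset_s / 30) + 1L)
    tt$state <- hyp$label[ep]
    tt <- tt[tt$state != "undetermined", ]
  } else {
    tt$state <- map_state(tt$state)
  }
  states <- intersect(c("W", "NREM", "REM"), unique(tt$state))
  stim_ids <- unique(tt$stimulus_id)
  durs <- tt$duration_s[match(stim_ids, tt$stimulus_id)]
  names(durs) <- stim_ids

  # trial bookkeeping in (cluster x trial) units over the spiking stage:
  # every trial of every cluster ends in exactly one disposition
  clusters <- unique(session$spikes$cluster_id)
  counts <- c(read = length(clusters) * nrow(session$trial_table),
              unstaged = length(clusters) *
                (nrow(session$trial_table) - nrow(tt)),
              used = 0, outlier = 0, boundary = 0, refused = 0)
  responses <- list()
  spike_params <- detection_params("spike")

  add_response <- function(unit, kind, band, sid, state, tm, det) {
    responses[[length(responses) + 1L]] <<- data.frame(
      unit_id = unit, kind = kind, band = band, stimulus_id = sid,
      state = state, n_trials = sum(!tm$excluded),
      n_intervals = nrow(det$intervals),
      total_ms = det$total_ms, magnitude = det$magnitude, peak = det$peak,
      latency_ms = det$latency_ms,
      q_min = if (length(det$q)) min(det$q) else NA_real_,
      intervals = paste(sprintf("[%d,%d)", det$intervals$start_ms,
                                det$intervals$end_ms), collapse = ";"),
      stringsAsFactors = FALSE)
  }

  # ---- spiking responses ---------------------------------------------------
  gains <- list()
  for (cl in clusters) {
    stt <- session$spikes$spike_time_s[session$spikes$cluster_id == cl]
    for (sid in stim_ids) {
      dur_ms <- round(durs[[sid]] * 1000)
      win <- c(config$baseline_ms[1], dur_ms + 100)
      tms <- list()
      for (state in states) {
        rows <- tt$stimulus_id == sid & tt$state == state
        tm <- smooth_spike_trains(stt, tt$onset_s[rows], win,
                                  sigma_ms = config$spike_sigma_ms,
                                  baseline_ms = config$baseline_ms,
                                  meta = list(unit = cl, stimulus = sid,
                                              state = state))
        counts["boundary"] <- counts["boundary"] + sum(tm$excluded)
        tm <- exclude_outlier_trials(tm, config$outlier_sd)
        counts["outlier"] <- counts["outlier"] + tm$meta$n_outliers
        if (sum(!tm$excluded) < config$min_trials) {
          counts["refused"] <- counts["refused"] + sum(!tm$excluded)
          message(sprintf("detection refused for %s/%s/%s: too few trials",
                          cl, sid, state))
          next
        }
        counts["used"] <- counts["used"] + sum(!tm$excluded)
        tms[[state]] <- tm
      }
      if (!length(tms)) next
      cmp <- compare_states(tms, spike_params, dur_ms)
      for (state in names(tms)) {
        add_response(cl, "spike", NA_character_, sid, state, tms[[state]],
                     cmp$detections[[state]])
      }
      if (all(c("W", "NREM") %in% names(tms)) && nrow(cmp$union)) {
        g <- compute_gain(cmp$magnitudes[["NREM"]], cmp$magnitudes[["W"]])
        gains[[length(gains) + 1L]] <- data.frame(
          unit_id = cl, kind = "spike", band = NA_character_,
          stimulus_id = sid, gain = g$gain,
          r_sleep = g$r_sleep, r_awake = g$r_awake,
          latency_ms = cmp$latency_ms[["W"]], stringsAsFactors = FALSE)
      }
    }
  }

  # ---- band-power responses ------------------------------------------------
  env_rows <- list()
  for (band in config$power_bands) {
    pw <- band_power_envelope(session$recording, band)
    params <- detection_params("power", band = band)
    for (ci in seq_len(nrow(pw))) {
      chan <- session$recording$channel_ids[ci]
      for (sid in stim_ids) {
        dur_ms <- round(durs[[sid]] * 1000)
        win <- c(config$baseline_ms[1], dur_ms + 100)
        tms <- list()
        for (state in states) {
          rows <- tt$stimulus_id == sid & tt$state == state
          tm <- epoch_trials(pw[ci, ], attr(pw, "rate"), tt$onset_s[rows],
                             win, baseline_ms = config$baseline_ms,
                             meta = list(unit = chan, stimulus = sid,
                                         state = state, band = band))
          tm <- exclude_outlier_trials(tm, config$outlier_sd)
          if (sum(!tm$excluded) < config$min_trials) next
          tms[[state]] <- tm
        }
        if (!length(tms)) next
        cmp <- compare_states(tms, params, dur_ms)
        for (state in names(tms)) {
          add_response(chan, "power", band, sid, state, tms[[state]],
                       cmp$detections[[state]])
        }
        if (all(c("W", "NREM") %in% names(tms)) && nrow(cmp$union)) {
          g <- compute_gain(cmp$magnitudes[["NREM"]], cmp$magnitudes[["W"]])
          gains[[length(gains) + 1L]] <- data.frame(
            unit_id = chan, kind = "power", band = band, stimulus_id = sid,
            gain = g$gain, r_sleep = g$r_sleep, r_awake = g$r_awake,
            latency_ms = cmp$latency_ms[["W"]], stringsAsFactors = FALSE)
        }
        # envelope coupling for responsive high-gamma channels
        if (band == "high_gamma" && !is.null(session$stimuli) &&
            nrow(cmp$union)) {
          stim <- session$stimuli[[sid]]
          if (!is.null(stim)) {
            env <- sound_envelope(stim$waveform, stim$rate)
            for (state in names(tms)) {
              tr <- colMeans(tm_values(tms[[state]], TRUE))
              sel <- tms[[state]]$time_ms >= 0 &
                tms[[state]]$time_ms < dur_ms
              tr5 <- downsample_to_step(tr[sel], 1000, 5)
              ec <- correlate_with_envelope(
                tr5, env, n_perm = config$n_perm_env,
                seed = derive_seed(config$rng_seed,
                                   paste0("env:", chan, ":", sid, ":", state)))
              env_rows[[length(env_rows) + 1L]] <- data.frame(
                unit_id = chan, stimulus_id = sid, state = state,
                r = ec$r, lag_ms = ec$lag_ms, perm_p = ec$perm_p,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }

  responses <- if (length(responses)) do.call(rbind, responses) else
    data.frame()
  gains <- if (length(gains)) do.call(rbind, gains) else data.frame()
  envcorr <- if (length(env_rows)) do.call(rbind, env_rows) else data.frame()

  # ---- unit-level statistics ----------------------------------------------
  mi <- list()
  for (cl in clusters) {
    stt <- session$spikes$spike_time_s[session$spikes$cluster_id == cl]
    cb <- spike_counts_by_bin(stt, tt, config$mi_bin_ms)
    mi_states <- tryCatch(
      estimate_mi_by_state(cb, states = intersect(c("W", "NREM"), states),
                           seed = derive_seed(config$rng_seed,
                                              paste0("mi:", cl))),
      error = function(e) NULL)
    if (!is.null(mi_states)) {
      mi[[length(mi) + 1L]] <- data.frame(unit_id = cl,
                                          state = names(mi_states),
                                          mi_bits = as.numeric(mi_states),
                                          stringsAsFactors = FALSE)
    }
  }
  mi <- if (length(mi)) do.call(rbind, mi) else data.frame()

  manifest <- list(
    config_hash = digest::digest(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("audsleep")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    counts = as.list(counts),
    n_clusters = length(clusters),
    n_channels = nrow(session$recording$signal),
    n_responses = nrow(responses))

  res <- structure(list(responses = responses, gains = gains,
                        envcorr = envcorr, mi = mi, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(responses, file.path(config$out_dir, "responses.tsv"))
    write_tsv(gains, file.path(config$out_dir, "gains.tsv"))
    if (nrow(envcorr)) write_tsv(envcorr, file.path(config$out_dir,
                                                    "envcorr.tsv"))
    if (nrow(mi)) write_tsv(mi, file.path(config$out_dir, "mi.tsv"))
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d response row(s), %d gain(s), %d MI row(s)\n",
              nrow(x$responses), nrow(x$gains), nrow(x$mi)))
  cat(sprintf("  trials: read %d = used %d + outlier %d + boundary %d + refused %d\n",
              x$manifest$counts$read, x$manifest$counts$used,
              x$manifest$counts$outlier, x$manifest$counts$boundary,
              x$manifest$counts$refused))
  invisible(x)
}
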