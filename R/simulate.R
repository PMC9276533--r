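#' Ground truth for a synthetic stimulation session
#'
#' Collects every parameter the session generator injects, so that recovery
#' tests can compare pipeline estimates against known values. Field
#' channels and spiking clusters are parameterized separately: clusters
#' carry the spiking response parameters (baseline rate, per-state response
#' strength in percent, response latency, optional sensitivity to ongoing
#' slow-wave activity), channels carry the field-potential parameters
#' (sound-envelope coupling, 40-Hz phase jitter per state, alpha--beta
#' desynchronization depth per state).
#'
#' @param hypnogram data.frame (`epoch_start_s`, `label`) of 30-s epochs
#'   with labels in `{W, N1, N2, N3, REM}`, covering the session without
#'   gaps (see [simulate_hypnogram()])
#' @param channels data.frame with columns `channel_id`, `role`
#'   (`lfp`/`ieeg`), `envelope_coupling_r` (target Pearson r in [0, 1]),
#'   `envelope_lag_ms`, `itpc_jitter_w`, `itpc_jitter_nrem`,
#'   `itpc_jitter_rem` (radians, >= 0), `abd_w`, `abd_nrem`, `abd_rem`
#'   (alpha--beta suppression depth in dB, >= 0)
#' @param clusters data.frame with columns `cluster_id`, `channel_id`,
#'   `baseline_rate` (spikes/s), `gain_w`, `gain_nrem`, `gain_rem`
#'   (response strength, percent in [-100, 100]; 100 = full strength, 70 in
#'   NREM with 100 in W injects a -30% sleep gain), `latency_ms`,
#'   `swa_sensitivity` (0 disables the SWA-dependent attenuation)
#' @param state_params list of field amplitudes: `delta_amp` (named by
#'   state, uV), `delta_epoch_sd` (lognormal epoch-to-epoch s.d. of the
#'   delta amplitude; 0.3 gives realistic state overlap, ~0.05 gives
#'   well-separated states), `sigma_amp` (named by state), `hg_amp`,
#'   `ab_amp`, `ssr_amp`, `noise_sd`, `onef_exponent`
#' @param response_strength scaling from percent strength to peak rate
#'   multiplier (default 3: a 100% response triples the rate at envelope
#'   peak)
#' @param hg_mod_depth peak relative amplitude modulation of the high-gamma
#'   carrier during stimuli (default 1)
#' @param isi_range inter-stimulus interval range in seconds (uniform;
#'   the experimental protocol does not fix a distribution, so this is a
#'   parameter)
#' @param rng_seed master integer seed; all components use derived
#'   substreams
#' @return an object of class `session_ground_truth`
#' @export
session_ground_truth <- function(hypnogram,
                                 channels = NULL,
                                 clusters = NULL,
                                 state_params = NULL,
                                 response_strength = 3,
                                 hg_mod_depth = 1,
                                 isi_range = c(1, 3),
                                 rng_seed = 1) {
  if (is.null(channels)) {
    channels <- data.frame(
      channel_id = c("lfp1", "ieeg1"), role = c("lfp", "ieeg"),
      envelope_coupling_r = 0.6, envelope_lag_ms = 60,
      itpc_jitter_w = 0.3, itpc_jitter_nrem = 0.8, itpc_jitter_rem = 0.5,
      abd_w = 6, abd_nrem = 2, abd_rem = 4, stringsAsFactors = FALSE)
  }
  if (is.null(clusters)) {
    clusters <- data.frame(
      cluster_id = "u1", channel_id = "lfp1", baseline_rate = 5,
      gain_w = 100, gain_nrem = 70, gain_rem = 90, latency_ms = 30,
      swa_sensitivity = 0, stringsAsFactors = FALSE)
  }
  sp <- list(delta_amp = c(W = 3, N1 = 6, N2 = 14, N3 = 24, REM = 3.5),
             delta_epoch_sd = 0.3,
             sigma_amp = c(W = 0.5, N1 = 1, N2 = 5, N3 = 3, REM = 0.5),
             hg_amp = 2, ab_amp = 4, ssr_amp = 3,
             noise_sd = 10, onef_exponent = 2)
  if (!is.null(state_params)) sp[names(state_params)] <- state_params

  stopifnot(all(c("epoch_start_s", "label") %in% names(hypnogram)))
  if (nrow(hypnogram) > 1 && any(diff(hypnogram$epoch_start_s) != 30)) {
    stop("hypnogram must cover the session in contiguous 30-s epochs",
         call. = FALSE)
  }
  bad <- setdiff(hypnogram$label, c("W", "N1", "N2", "N3", "REM"))
  if (length(bad)) stop("unknown hypnogram label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  g <- unlist(clusters[, c("gain_w", "gain_nrem", "gain_rem")])
  if (any(g < -100 | g > 100)) {
    stop("cluster response strengths must lie in [-100, 100]", call. = FALSE)
  }
  j <- unlist(channels[, c("itpc_jitter_w", "itpc_jitter_nrem",
                           "itpc_jitter_rem")])
  if (any(j < 0)) stop("phase jitter s.d. must be >= 0", call. = FALSE)
  r <- channels$envelope_coupling_r
  if (any(r < 0 | r > 1)) {
    stop("envelope_coupling_r must lie in [0, 1]", call. = FALSE)
  }
  structure(list(hypnogram = hypnogram, channels = channels,
                 clusters = clusters, state_params = sp,
                 response_strength = response_strength,
                 hg_mod_depth = hg_mod_depth, isi_range = isi_range,
                 rng_seed = as.integer(rng_seed)),
            class = "session_ground_truth")
}

#' @export
print.session_ground_truth <- function(x, ...) {
  cat(sprintf("<session_ground_truth> %d epoch(s), %d channel(s), %d cluster(s), seed %d\n",
              nrow(x$hypnogram), nrow(x$channels), nrow(x$clusters),
              x$rng_seed))
  invisible(x)
}

#' Simulated overnight hypnogram
#'
#' A template night: an initial wakefulness block, then four sleep cycles
#' (N1, N2, N3, N2, REM) with slow-wave sleep front-loaded and REM episodes
#' lengthening across the night (so REM bouts fall in the second part and
#' exceed 3 min), and a final awakening.
#'
#' @param n_epochs number of 30-s epochs (>= 40 for a full template)
#' @param seed integer seed (small jitter of block lengths)
#' @return hypnogram data.frame (`epoch_start_s`, `label`)
#' @export
simulate_hypnogram <- function(n_epochs, seed = 1) {
  stopifnot(n_epochs >= 40)
  blocks <- list(c("W", 0.10))
  n3_w <- c(0.45, 0.30, 0.15, 0.10)
  rem_w <- c(0.10, 0.20, 0.30, 0.40)
  for (k in 1:4) {
    blocks <- c(blocks, list(c("N1", 0.05 / 4), c("N2", 0.20 / 4),
                             c("N3", 0.15 * n3_w[k]), c("N2", 0.20 / 4),
                             c("REM", 0.25 * rem_w[k])))
  }
  blocks <- c(blocks, list(c("W", 0.05)))
  props <- vapply(blocks, function(b) as.numeric(b[2]), numeric(1))
  labs <- vapply(blocks, function(b) b[1], "")
  len <- with_seed(seed, {
    l <- round(props / sum(props) * n_epochs *
                 stats::runif(length(props), 0.9, 1.1))
    pmax(l, 1L)
  })
  lab <- rep(labs, len)
  lab <- if (length(lab) >= n_epochs) lab[seq_len(n_epochs)] else
    c(lab, rep("N2", n_epochs - length(lab)))
  data.frame(epoch_start_s = (seq_len(n_epochs) - 1) * 30, label = lab,
             stringsAsFactors = FALSE)
}

#' Block hypnogram helper for controlled simulations
#' @param labels block state labels
#' @param n_epochs_each epochs per block (recycled)
#' @return hypnogram data.frame
#' @export
hypnogram_blocks <- function(labels, n_epochs_each) {
  lab <- rep(labels, times = rep_len(n_epochs_each, length(labels)))
  data.frame(epoch_start_s = (seq_along(lab) - 1) * 30, label = lab,
             stringsAsFactors = FALSE)
}

# map a 5-stage hypnogram label onto the analysis states
map_state <- function(label) {
  c(W = "W", N1 = "NREM", N2 = "NREM", N3 = "NREM", REM = "REM")[label]
}

# 1/f^a background: spectrally shaped Gaussian noise, amplitude
# 1/max(f, 1)^(a/2), scaled to the requested s.d.
one_over_f_noise <- function(n, rate, exponent = 2, sd = 1) {
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, rate - f)
  shape <- 1 / pmax(f, 1)^(exponent / 2)
  shape[1] <- 0
  ph <- stats::runif(n %/% 2 - 1 + n %% 2, 0, 2 * pi)
  X <- complex(modulus = 0, argument = 0, length.out = n)
  half <- 2:(ceiling(n / 2))
  X[half] <- shape[half] * exp(1i * ph[seq_along(half)])
  X[n + 2 - half] <- Conj(X[half])
  if (n %% 2 == 0) X[n / 2 + 1] <- shape[n / 2 + 1]
  x <- Re(stats::fft(X, inverse = TRUE))
  x * sd / stats::sd(x)
}

# modulation sequence on the 5-ms grid whose in-sample Pearson correlation
# with the stimulus envelope is exactly r (noise residualized against the
# envelope), affinely mapped to [0, 1]
hg_modulation <- function(envelope, r, seed) {
  e <- as.numeric(envelope)
  K <- length(e)
  u <- with_seed(seed, stats::rnorm(K))
  if (stats::sd(e) == 0 || K < 3) {
    m0 <- u
  } else {
    ec <- (e - mean(e)) / stats::sd(e)
    uc <- u - mean(u)
    uo <- uc - sum(uc * ec) / sum(ec^2) * ec
    uo <- uo / stats::sd(uo)
    m0 <- r * ec + sqrt(1 - r^2) * uo
  }
  (m0 - min(m0)) / max(max(m0) - min(m0), 1e-12)
}

#' Generate a complete synthetic stimulation session
#'
#' Produces, from a [session_ground_truth()] and a stimulus set, the three
#' raw inputs of the analysis pipeline plus simulator-only ground-truth
#' extras:
#' \itemize{
#' \item trials packed pseudo-randomly (shuffled balanced blocks) with
#'   uniform inter-stimulus intervals, state-labelled from the hypnogram;
#' \item spike trains as inhomogeneous Poisson processes with rate
#'   `baseline * (1 + strength * state_gain/100 * envelope(t - latency))`,
#'   optionally attenuated on high-SWA trials;
#' \item field potentials at 1 kHz: 1/f background, state-dependent delta
#'   with per-epoch amplitude jitter, NREM sigma bursts, a high-gamma
#'   carrier amplitude-modulated by the sound envelope (exact in-sample
#'   coupling r), a tonic alpha--beta rhythm suppressed during stimuli by
#'   the per-state desynchronization depth, and a 40-Hz steady-state
#'   component during click-trains with per-trial Gaussian phase jitter;
#' \item a behaviour proxy (awake evidence / quiescence per epoch).
#' }
#' Everything is reproducible bit-for-bit from `rng_seed`; each component
#' draws from its own derived substream.
#'
#' @param gt a [session_ground_truth()]
#' @param stimuli stimulus set from [generate_stimulus_set()]
#' @param session_length session length in whole seconds (>= 600)
#' @param min_trials minimum trials required per stimulus per analysis
#'   state present in the hypnogram (default 6); shortfalls raise an error
#'   naming the combination
#' @param check_trials set `FALSE` to skip the minimum-trial check
#' @return list of class `synthetic_session`: `recording`, `spikes`,
#'   `trial_table`, `hypnogram`, `behavior`, `ground_truth`, `stimuli`,
#'   and `injected` (per-channel injected high-gamma modulations and
#'   per-trial 40-Hz phases)
#' @export
generate_session <- function(gt, stimuli, session_length, min_trials = 6L,
                             check_trials = TRUE) {
  stopifnot(inherits(gt, "session_ground_truth"))
  if (session_length < 600) {
    stop("session_length must be >= 600 s", call. = FALSE)
  }
  if (session_length != round(session_length)) {
    stop("session_length must be whole seconds", call. = FALSE)
  }
  n_ep <- nrow(gt$hypnogram)
  if (n_ep * 30 < session_length) {
    stop(sprintf("hypnogram covers %d s < session length %d s",
                 n_ep * 30, session_length), call. = FALSE)
  }
  rate <- 1000L
  n <- session_length * rate

  # ---- trial packing -------------------------------------------------------
  durs <- vapply(stimuli, function(s) s$duration, numeric(1))
  ids <- names(stimuli)
  if (1 + min(durs) + gt$isi_range[1] > session_length) {
    stop("stimuli do not fit the session: even one trial exceeds its length",
         call. = FALSE)
  }
  trial <- with_seed(derive_seed(gt$rng_seed, "trials"), {
    onset <- c(); sid <- c()
    t <- 1.0
    repeat {
      block <- sample(ids)
      done <- FALSE
      for (s in block) {
        if (t + durs[[s]] + 0.7 > session_length) { done <- TRUE; break }
        onset <- c(onset, t); sid <- c(sid, s)
        t <- t + durs[[s]] + stats::runif(1, gt$isi_range[1], gt$isi_range[2])
      }
      if (done) break
    }
    list(onset = onset, sid = sid)
  })
  if (!length(trial$onset)) {
    stop("stimuli do not fit the session: no trial packed", call. = FALSE)
  }
  ep_idx <- pmin(n_ep, floor(trial$onset / 30) + 1L)
  state5 <- gt$hypnogram$label[ep_idx]
  trial_table <- data.frame(
    trial_id = sprintf("t%04d", seq_along(trial$onset)),
    stimulus_id = trial$sid,
    stim_type = vapply(stimuli[trial$sid], function(s) s$stim_type, ""),
    onset_s = trial$onset,
    duration_s = durs[trial$sid],
    state = state5, stringsAsFactors = FALSE, row.names = NULL)

  if (check_trials) {
    st_present <- unique(map_state(gt$hypnogram$label))
    cnt <- table(factor(trial_table$stimulus_id, levels = ids),
                 factor(map_state(trial_table$state), levels = st_present))
    short <- which(cnt < min_trials, arr.ind = TRUE)
    if (nrow(short)) {
      msg <- paste(sprintf("%s in %s: %d", rownames(cnt)[short[, 1]],
                           colnames(cnt)[short[, 2]],
                           cnt[short]), collapse = "; ")
      stop("trial packing shortfall (< ", min_trials,
           " trials per stimulus per state): ", msg, call. = FALSE)
    }
  }

  # per-stimulus envelopes, normalized to peak 1, on 5-ms and 1-ms grids
  env5 <- lapply(stimuli, function(s) {
    e <- as.numeric(sound_envelope(s$waveform, s$rate))
    e / max(e, 1e-12)
  })
  env1 <- lapply(env5, function(e) rep(e, each = 5L))

  state_sample <- rep(gt$hypnogram$label, each = 30L * rate)[seq_len(n)]
  sp <- gt$state_params

  # ---- field channels ------------------------------------------------------
  nch <- nrow(gt$channels)
  signal <- matrix(0, nch, n)
  injected <- list(hg_mod = list(), ssr_phase = list())
  delta_series <- vector("list", nch)
  is_click <- trial_table$stim_type == "click_train_40hz"
  t_sess <- (seq_len(n) - 1) / rate

  for (ci in seq_len(nch)) {
    ch <- gt$channels[ci, ]
    x <- with_seed(derive_seed(gt$rng_seed, paste0("channel:", ch$channel_id)), {
      bg <- one_over_f_noise(n, rate, sp$onef_exponent, sp$noise_sd)

      dl <- bandpass_filter(stats::rnorm(n), rate, 0.5, 4)
      dl <- dl / stats::sd(dl)
      ep_jit <- exp(stats::rnorm(n_ep, 0, sp$delta_epoch_sd))
      amp <- (sp$delta_amp[state_sample] *
                rep(ep_jit, each = 30L * rate)[seq_len(n)])
      dl <- dl * amp

      sg <- bandpass_filter(stats::rnorm(n), rate, 10, 16)
      sg <- sg / stats::sd(sg)
      burst <- 0.5 + 0.5 * sin(2 * pi * 0.08 * t_sess +
                                 stats::runif(1, 0, 2 * pi))
      sg <- sg * sp$sigma_amp[state_sample] * burst

      hg <- bandpass_filter(stats::rnorm(n), rate, 80, 200)
      hg <- hg / stats::sd(hg)
      hg_amp_mod <- rep(1, n)
      mods <- list()
      for (s in ids) {
        mods[[s]] <- hg_modulation(
          env5[[s]], ch$envelope_coupling_r,
          derive_seed(gt$rng_seed, paste0("hgmod:", ch$channel_id, ":", s)))
      }
      for (j in seq_len(nrow(trial_table))) {
        m1 <- rep(mods[[trial_table$stimulus_id[j]]], each = 5L)
        i0 <- round((trial_table$onset_s[j] +
                       ch$envelope_lag_ms / 1000) * rate) + 1L
        idx <- i0:min(n, i0 + length(m1) - 1L)
        hg_amp_mod[idx] <- 1 + gt$hg_mod_depth * m1[seq_along(idx)]
      }
      hg <- hg * sp$hg_amp * hg_amp_mod

      ab <- bandpass_filter(stats::rnorm(n), rate, 10, 30)
      ab <- ab / stats::sd(ab)
      supp <- rep(1, n)
      abd <- c(W = ch$abd_w, NREM = ch$abd_nrem, REM = ch$abd_rem)
      for (j in seq_len(nrow(trial_table))) {
        i0 <- round(trial_table$onset_s[j] * rate) + 1L
        i1 <- min(n, i0 + round(trial_table$duration_s[j] * rate) - 1L)
        supp[i0:i1] <- 10^(-abd[[map_state(trial_table$state[j])]] / 20)
      }
      ab <- ab * sp$ab_amp * supp

      ssr <- numeric(n)
      phi0 <- stats::runif(1, 0, 2 * pi)
      jit_sd <- c(W = ch$itpc_jitter_w, NREM = ch$itpc_jitter_nrem,
                  REM = ch$itpc_jitter_rem)
      ssr_phase <- rep(NA_real_, nrow(trial_table))
      for (j in which(is_click)) {
        jit <- stats::rnorm(1, 0, jit_sd[[map_state(trial_table$state[j])]])
        ssr_phase[j] <- phi0 + jit
        i0 <- round(trial_table$onset_s[j] * rate) + 1L
        i1 <- min(n, i0 + round(trial_table$duration_s[j] * rate) - 1L)
        tt <- (0:(i1 - i0)) / rate
        ssr[i0:i1] <- ssr[i0:i1] + sp$ssr_amp * cos(2 * pi * 40 * tt +
                                                      ssr_phase[j])
      }
      list(x = bg + dl + sg + hg + ab + ssr, dl = dl, mods = mods,
           ssr_phase = ssr_phase)
    })
    signal[ci, ] <- x$x
    delta_series[[ci]] <- x$dl
    injected$hg_mod[[ch$channel_id]] <- x$mods
    injected$ssr_phase[[ch$channel_id]] <- x$ssr_phase
  }
  recording <- continuous_recording(signal, rate, gt$channels$channel_id,
                                    gt$channels$role)

  # ---- spikes --------------------------------------------------------------
  spikes <- vector("list", nrow(gt$clusters))
  for (ki in seq_len(nrow(gt$clusters))) {
    cl <- gt$clusters[ki, ]
    gain <- c(W = cl$gain_w, NREM = cl$gain_nrem, REM = cl$gain_rem)
    # per-trial SWA attenuation from the host channel's delta component
    mult <- rep(1, nrow(trial_table))
    if (cl$swa_sensitivity > 0) {
      ci <- match(cl$channel_id, gt$channels$channel_id)
      swa <- vapply(trial_table$onset_s, function(o) {
        i1 <- round(o * rate); i0 <- max(1L, i1 - 2L * rate + 1L)
        mean(delta_series[[ci]][i0:i1]^2)
      }, numeric(1))
      pr <- (rank(swa) - 1) / max(1, length(swa) - 1)
      mult <- 1 - cl$swa_sensitivity * pr
    }
    rate_vec <- rep(cl$baseline_rate, n)
    for (j in seq_len(nrow(trial_table))) {
      e1 <- env1[[trial_table$stimulus_id[j]]]
      g <- gain[[map_state(trial_table$state[j])]] / 100
      i0 <- round((trial_table$onset_s[j] + cl$latency_ms / 1000) * rate) + 1L
      idx <- i0:min(n, i0 + length(e1) - 1L)
      rate_vec[idx] <- cl$baseline_rate *
        pmax(0, 1 + gt$response_strength * g * mult[j] * e1[seq_along(idx)])
    }
    st <- with_seed(derive_seed(gt$rng_seed, paste0("cluster:", cl$cluster_id)), {
      cnt <- stats::rpois(n, rate_vec / rate)
      pos <- which(cnt > 0)
      tms <- rep((pos - 1) / rate, cnt[pos]) +
        stats::runif(sum(cnt[pos])) / rate
      sort(tms)
    })
    spikes[[ki]] <- data.frame(cluster_id = cl$cluster_id,
                               channel_id = cl$channel_id,
                               spike_time_s = st, stringsAsFactors = FALSE)
  }
  spikes <- do.call(rbind, spikes)

  # ---- behaviour proxy -----------------------------------------------------
  behavior <- with_seed(derive_seed(gt$rng_seed, "behavior"), {
    awake <- gt$hypnogram$label == "W" & stats::runif(n_ep) < 0.95
    data.frame(epoch_start_s = gt$hypnogram$epoch_start_s,
               awake_evidence = awake, quiescent = !awake)
  })

  structure(list(recording = recording, spikes = spikes,
                 trial_table = trial_table, hypnogram = gt$hypnogram,
                 behavior = behavior, ground_truth = gt, stimuli = stimuli,
                 injected = injected),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %.0f s, %d channel(s), %d cluster(s), %d trial(s)\n",
              ncol(x$recording$signal) / x$recording$rate,
              nrow(x$ground_truth$channels), nrow(x$ground_truth$clusters),
              nrow(x$trial_table)))
  invisible(x)
}
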