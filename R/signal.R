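#' Canonical frequency band definitions
#'
#' The five bands used throughout: low gamma (40--80 Hz), high gamma
#' (80--200 Hz, a proxy for local firing), alpha--beta (10--30 Hz, the band
#' showing stimulus-induced desynchronization), slow-wave activity
#' (0.5--4 Hz) and sigma / spindle (10--16 Hz).
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz)
#' @export
band_definitions <- function() {
  data.frame(
    name = c("low_gamma", "high_gamma", "alpha_beta", "delta_swa", "sigma"),
    low  = c(40, 80, 10, 0.5, 10),
    high = c(80, 200, 30, 4, 16),
    stringsAsFactors = FALSE)
}

band_edges <- function(band) {
  bd <- band_definitions()
  i <- match(band, bd$name)
  if (is.na(i)) stop("unknown band: ", band, call. = FALSE)
  c(bd$low[i], bd$high[i])
}

# ---- zero-phase frequency-domain filtering ---------------------------------
# Filtering is done by masking the FFT with raised-cosine band edges after
# mirror padding. This is exactly zero-phase (no group delay to bias latency
# estimates) and has effectively unbounded stopband attenuation away from
# the transition region; transition half-widths are kept at <= 25% of the
# band edge so that neighbouring canonical bands do not leak.

fft_mask <- function(n, rate, low, high) {
  f <- abs(seq(0, rate, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, rate - f)                      # fold to [0, rate/2]
  twl <- min(2, low * 0.25)
  twh <- min(2, high * 0.25)
  m <- numeric(n)
  m[f >= low + twl & f <= high - twh] <- 1
  lo <- f > low - twl & f < low + twl
  m[lo] <- (1 - cos(pi * (f[lo] - (low - twl)) / (2 * twl))) / 2
  hi <- f > high - twh & f < high + twh
  m[hi] <- (1 + cos(pi * (f[hi] - (high - twh)) / (2 * twh))) / 2
  m
}

mirror_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
}

#' Zero-phase band-pass filter (frequency-domain)
#'
#' @param x numeric signal
#' @param rate sampling rate Hz
#' @param low,high band edges in Hz; `high` must be below Nyquist
#' @return filtered signal, same length as `x`
#' @export
bandpass_filter <- function(x, rate, low, high) {
  if (high >= rate / 2) {
    stop(sprintf("band edge %g Hz is at/above Nyquist (%g Hz)", high, rate / 2),
         call. = FALSE)
  }
  n <- length(x)
  p <- min(n - 1L, as.integer(rate))
  xp <- mirror_pad(x, p)
  np <- length(xp)
  X <- stats::fft(xp) * fft_mask(np, rate, low, high)
  Re(stats::fft(X, inverse = TRUE))[(p + 1L):(p + n)] / np
}

#' Analytic-signal amplitude envelope (Hilbert transform via FFT)
#' @param x numeric signal (real)
#' @return non-negative instantaneous amplitude, same length
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  p <- min(n - 1L, 1024L)
  xp <- mirror_pad(x, p)
  Mod(analytic_signal(xp))[(p + 1L):(p + n)]
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Down-sample a signal with mandatory anti-aliasing
#'
#' Low-passes at 0.4 x target rate, then decimates by the (integer) factor.
#'
#' @param x numeric signal
#' @param rate source rate Hz
#' @param target target rate Hz; `rate` must be an integer multiple
#' @return list with `x` (down-sampled signal) and `rate`
#' @export
downsample_signal <- function(x, rate, target = 1000) {
  if (rate == target) return(list(x = x, rate = rate))
  if (rate %% target != 0) {
    stop("source rate must be an integer multiple of the target rate",
         call. = FALSE)
  }
  xf <- bandpass_filter(x, rate, 0, 0.4 * target)
  k <- rate %/% target
  list(x = xf[seq(1, length(x), by = k)], rate = target)
}

#' Band-limited instantaneous power envelope, in dB
#'
#' Down-samples each channel to 1 kHz (anti-aliased), band-pass filters,
#' Hilbert-transforms to the instantaneous amplitude envelope and converts
#' to dB as `20*log10(amplitude)`. The dB convention (amplitude, not power)
#' cancels in all downstream comparisons, which are baseline differences.
#'
#' @param recording a [continuous_recording()]
#' @param band a band name from [band_definitions()], or `c(low, high)` Hz
#' @return channels x samples matrix of envelope in dB, with attributes
#'   `rate` (1000) and `band`
#' @export
band_power_envelope <- function(recording, band) {
  edges <- if (is.character(band)) band_edges(band) else as.numeric(band)
  out <- NULL
  for (i in seq_len(nrow(recording$signal))) {
    ds <- downsample_signal(recording$signal[i, ], recording$rate, 1000)
    env <- hilbert_envelope(bandpass_filter(ds$x, ds$rate, edges[1], edges[2]))
    if (is.null(out)) out <- matrix(0, nrow(recording$signal), length(env))
    out[i, ] <- 20 * log10(env + 1e-12)
  }
  rownames(out) <- recording$channel_ids
  attr(out, "rate") <- 1000
  attr(out, "band") <- edges
  out
}

# ---- trial epoching --------------------------------------------------------

#' Trial-aligned response matrix
#'
#' Internal constructor for the trial matrix container used by all
#' detection and statistics stages: a trials x time matrix on a uniform
#' (1-ms) grid relative to stimulus onset, with per-trial baseline means,
#' exclusion flags (trials are flagged, never deleted) and metadata.
#'
#' @keywords internal
new_trial_matrix <- function(values, time_ms, baseline_window, baseline_mean,
                             baselined, excluded, meta = list()) {
  structure(list(values = values, time_ms = time_ms,
                 baseline_window = baseline_window,
                 baseline_mean = baseline_mean, baselined = baselined,
                 excluded = excluded, meta = meta),
            class = "trial_matrix")
}

#' @export
print.trial_matrix <- function(x, ...) {
  cat(sprintf("<trial_matrix> %d trial(s) x %d ms [%d..%d), %d excluded%s\n",
              nrow(x$values), ncol(x$values), min(x$time_ms),
              max(x$time_ms) + 1L, sum(x$excluded),
              if (x$baselined) ", baselined" else ""))
  invisible(x)
}

#' Usable (non-excluded) trial values of a trial matrix
#' @param tm a trial matrix
#' @param baselined return baseline-subtracted values?
#' @keywords internal
tm_values <- function(tm, baselined = TRUE) {
  v <- tm$values[!tm$excluded, , drop = FALSE]
  b <- tm$baseline_mean[!tm$excluded]
  if (baselined && !tm$baselined) v <- v - b
  if (!baselined && tm$baselined) v <- v + b
  v
}

#' Epoch a continuous trace into a baselined trial matrix
#'
#' Cuts `window_ms` around each onset and subtracts each trial's own mean
#' over the baseline window (default the 500 ms preceding onset). Trials
#' extending past the recording bounds are flagged (not dropped) and
#' reported via a message.
#'
#' @param x single-channel numeric trace (e.g. dB band power)
#' @param rate sampling rate of `x` in Hz (1000 gives the 1-ms grid)
#' @param onsets_s stimulus onsets in seconds
#' @param window_ms `c(start, end)` of the epoch in ms relative to onset,
#'   half-open; must cover the baseline window
#' @param baseline_ms baseline window, default `c(-500, 0)`
#' @param baselined subtract the per-trial baseline mean? (default TRUE;
#'   spike-rate matrices keep raw rates so that traces integrate to counts)
#' @param meta metadata list stored on the result
#' @return a `trial_matrix`
#' @export
epoch_trials <- function(x, rate, onsets_s, window_ms,
                         baseline_ms = c(-500, 0), baselined = TRUE,
                         meta = list()) {
  step <- 1000 / rate
  if (step != round(step) && step != 1) {
    stopifnot(abs(step - round(step)) < 1e-9)
  }
  if (window_ms[1] > baseline_ms[1] || window_ms[2] < baseline_ms[2]) {
    stop("epoch window must cover the baseline window", call. = FALSE)
  }
  time_ms <- seq(window_ms[1], window_ms[2] - step, by = step)
  nt <- length(onsets_s)
  vals <- matrix(NA_real_, nt, length(time_ms))
  excluded <- logical(nt)
  bl_cols <- time_ms >= baseline_ms[1] & time_ms < baseline_ms[2]
  for (j in seq_len(nt)) {
    idx <- round(onsets_s[j] * rate) + round(time_ms / step) + 1L
    if (idx[1] < 1L || idx[length(idx)] > length(x)) {
      excluded[j] <- TRUE
      message(sprintf("trial %d extends past recording bounds; flagged", j))
      next
    }
    vals[j, ] <- x[idx]
  }
  bmean <- rowMeans(vals[, bl_cols, drop = FALSE])
  if (baselined) vals <- vals - bmean
  new_trial_matrix(vals, time_ms, baseline_ms, bmean, baselined, excluded,
                   meta)
}

#' Flag outlier trials (mean power beyond 5 s.d. of the trial mean)
#'
#' The statistic is each trial's mean value across the whole epoch; trials
#' above `mean + threshold * s.d.` (computed over currently usable trials)
#' are flagged excluded. Flags only; nothing is deleted.
#'
#' @param tm a `trial_matrix`
#' @param threshold s.d. multiple, default 5
#' @return the trial matrix with updated exclusion flags and an
#'   `n_outliers` entry in `meta`
#' @export
exclude_outlier_trials <- function(tm, threshold = 5) {
  tmean <- rowMeans(tm$values)
  ok <- !tm$excluded
  m <- mean(tmean[ok]); s <- stats::sd(tmean[ok])
  out <- ok & !is.na(tmean) & s > 0 & tmean > m + threshold * s
  tm$excluded <- tm$excluded | out
  tm$meta$n_outliers <- sum(out)
  tm
}

#' Smoothed single-trial spike-rate traces
#'
#' Bins each trial's spikes on a 1-ms grid and convolves with a unit-area
#' Gaussian kernel (sigma = 10 ms by default), giving instantaneous rate in
#' spikes/s; each trial trace integrates back to its spike count (up to
#' kernel mass lost at the epoch edges). Values are kept as raw rates (not
#' baseline-subtracted); the per-trial baseline means are stored alongside.
#'
#' @param spike_times_s spike times of one cluster, seconds
#' @param onsets_s trial onsets, seconds
#' @param window_ms epoch window `c(start, end)` ms relative to onset
#' @param sigma_ms Gaussian kernel s.d. in ms (default 10)
#' @param baseline_ms baseline window, default `c(-500, 0)`
#' @param meta metadata list
#' @return a `trial_matrix` of rates in spikes/s
#' @export
smooth_spike_trains <- function(spike_times_s, onsets_s, window_ms,
                                sigma_ms = 10, baseline_ms = c(-500, 0),
                                meta = list()) {
  if (length(spike_times_s) == 0) {
    warning("empty cluster: all-zero rate matrix", call. = FALSE)
  }
  time_ms <- seq(window_ms[1], window_ms[2] - 1)
  half <- ceiling(4 * sigma_ms)
  kern <- stats::dnorm(seq(-half, half), sd = sigma_ms) * 1000  # spikes/s
  nt <- length(onsets_s)
  vals <- matrix(0, nt, length(time_ms))
  pad_lo <- window_ms[1] - half
  pad_n <- length(time_ms) + 2L * half
  for (j in seq_len(nt)) {
    rel <- floor((spike_times_s - onsets_s[j]) * 1000)
    rel <- rel[rel >= pad_lo & rel < pad_lo + pad_n]
    if (length(rel)) {
      counts <- tabulate(rel - pad_lo + 1L, nbins = pad_n)
      sm <- stats::convolve(counts, rev(kern), type = "open")
      vals[j, ] <- sm[(2L * half + 1L):(2L * half + length(time_ms))]
    }
  }
  bl_cols <- time_ms >= baseline_ms[1] & time_ms < baseline_ms[2]
  bmean <- rowMeans(vals[, bl_cols, drop = FALSE])
  new_trial_matrix(vals, time_ms, baseline_ms, bmean, baselined = FALSE,
                   excluded = logical(nt), meta = meta)
}

#' Sound intensity envelope on a 5-ms grid
#'
#' Running average of the squared amplitude in non-overlapping 5-ms
#' windows (a trailing partial window is averaged over its samples).
#'
#' @param waveform numeric sound pressure sequence
#' @param rate audio sampling rate, >= 8 kHz
#' @param step_ms window length, default 5 ms
#' @return an object of class `sound_envelope`: numeric vector with
#'   attribute `step_ms`
#' @export
sound_envelope <- function(waveform, rate, step_ms = 5) {
  if (length(waveform) == 0) stop("empty waveform", call. = FALSE)
  if (rate < 8000) stop("audio rate must be >= 8 kHz", call. = FALSE)
  w <- rate * step_ms / 1000
  nb <- ceiling(length(waveform) / w)
  blk <- factor(rep(seq_len(nb), each = w)[seq_along(waveform)],
                levels = seq_len(nb))
  env <- as.numeric(tapply(waveform^2, blk, mean))
  structure(env, step_ms = step_ms, class = "sound_envelope")
}

#' Block-average a 1-kHz trace onto a coarser grid (e.g. 200 Hz)
#'
#' Used to bring high-gamma response traces onto the sound envelope's 5-ms
#' grid before computing their correlation.
#'
#' @param x numeric trace at `rate` Hz
#' @param rate source rate (Hz)
#' @param step_ms target step in ms (5 ms gives 200 Hz)
#' @return block means, one per full step
#' @export
downsample_to_step <- function(x, rate = 1000, step_ms = 5) {
  w <- rate * step_ms / 1000
  nb <- floor(length(x) / w)
  colMeans(matrix(x[seq_len(nb * w)], nrow = w))
}

# ---- 30-s spectrogram ------------------------------------------------------

#' Power spectra in non-overlapping 30-s epochs, 0--40 Hz
#'
#' One periodogram per epoch per channel (epoch demeaned first), expressed
#' as power spectral density. A trailing partial epoch is dropped with a
#' message. Delta power per epoch is the mean density over 0.5--4 Hz.
#'
#' @param recording a [continuous_recording()]
#' @param epoch_s epoch length, default 30 s
#' @param fmax highest frequency retained, default 40 Hz
#' @return object of class `spectrogram30s`: list with `power`
#'   (epochs x freqs x channels array), `freq`, `epoch_start_s`,
#'   `channel_ids`, `channel_roles`
#' @export
spectrogram_30s <- function(recording, epoch_s = 30, fmax = 40) {
  rate <- recording$rate
  npe <- round(epoch_s * rate)
  n <- ncol(recording$signal)
  n_ep <- n %/% npe
  if (n_ep < 1) stop("recording shorter than one epoch", call. = FALSE)
  if (n %% npe != 0) {
    message(sprintf("dropping trailing partial epoch (%.1f s)",
                    (n - n_ep * npe) / rate))
  }
  freq <- (0:(npe %/% 2)) * rate / npe
  keep <- freq <= fmax
  freq <- freq[keep]
  pw <- array(0, c(n_ep, length(freq), nrow(recording$signal)))
  for (ch in seq_len(nrow(recording$signal))) {
    for (e in seq_len(n_ep)) {
      seg <- recording$signal[ch, ((e - 1L) * npe + 1L):(e * npe)]
      seg <- seg - mean(seg)
      X <- stats::fft(seg)[seq_along(freq)]
      psd <- (Mod(X)^2) / (npe * rate)
      psd[-1] <- 2 * psd[-1]
      pw[e, , ch] <- psd
    }
  }
  structure(list(power = pw, freq = freq,
                 epoch_start_s = (seq_len(n_ep) - 1) * epoch_s,
                 channel_ids = recording$channel_ids,
                 channel_roles = recording$channel_roles),
            class = "spectrogram30s")
}

#' Per-epoch band power from a 30-s spectrogram
#'
#' @param spect a `spectrogram30s`
#' @param low,high band edges Hz (default delta/SWA, 0.5--4)
#' @param channels indices or ids to average over (default: iEEG channels
#'   when any are present, else all)
#' @return numeric vector, one mean band power per epoch
#' @export
epoch_band_power <- function(spect, low = 0.5, high = 4, channels = NULL) {
  if (is.null(channels)) {
    channels <- if (any(spect$channel_roles == "ieeg")) {
      which(spect$channel_roles == "ieeg")
    } else {
      seq_along(spect$channel_ids)
    }
  } else if (is.character(channels)) {
    channels <- match(channels, spect$channel_ids)
  }
  fi <- spect$freq >= low & spect$freq <= high
  apply(spect$power[, fi, channels, drop = FALSE], 1, mean)
}
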