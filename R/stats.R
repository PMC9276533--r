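#' Cross-state response gain
#'
#' Bounded percent change of the sleep response relative to wakefulness:
#' `100 * (R_sleep - R_awake) / max(|R_sleep|, |R_awake|)`, where the R's
#' are baselined response magnitudes measured in the same units over the
#' same intervals. Always in [-100, 100]; -100 means a fully abolished
#' response, 0 identical magnitudes.
#'
#' When the two magnitudes have opposite signs the raw ratio can reach
#' +/-200; such sign-flipped responses saturate the scale at +/-100 so that
#' every emitted gain lies in the stated range (the pipeline's magnitudes
#' share the sign of the tested tail, so saturation is rare).
#'
#' @param r_sleep,r_awake baselined response magnitudes
#' @return list of class `gain_value` with `gain`, `r_sleep`, `r_awake`;
#'   `gain` is `NA` when both magnitudes are zero
#' @examples
#' compute_gain(7.2, 10)$gain   # -28
#' @export
compute_gain <- function(r_sleep, r_awake) {
  denom <- max(abs(r_sleep), abs(r_awake))
  g <- if (is.na(denom) || denom == 0) NA_real_ else
    max(-100, min(100, 100 * (r_sleep - r_awake) / denom))
  structure(list(gain = g, r_sleep = r_sleep, r_awake = r_awake),
            class = "gain_value")
}

# ---- mutual information ----------------------------------------------------

#' Spike counts per 50-ms stimulus bin, one observation per (trial, bin)
#'
#' Divides each stimulus into consecutive `bin_width_ms` bins (partial
#' trailing bins are dropped: a 450-ms stimulus yields 9 bins of 50 ms) and
#' counts spikes per bin per trial. Bin identity is global across stimuli,
#' so pooling the rows of the result gives the (response, bin) sample the
#' mutual-information estimator needs.
#'
#' @param spike_times_s spike times of one cluster (seconds)
#' @param trial_table trial table rows to use (`onset_s`, `duration_s`,
#'   `stimulus_id`, `trial_id`, `state`)
#' @param bin_width_ms bin width in ms, default 50
#' @return data.frame with columns `trial_id`, `stimulus_id`, `state`,
#'   `bin_id`, `count`
#' @export
spike_counts_by_bin <- function(spike_times_s, trial_table,
                                bin_width_ms = 50) {
  out <- vector("list", nrow(trial_table))
  bw <- bin_width_ms / 1000
  for (i in seq_len(nrow(trial_table))) {
    nb <- floor(trial_table$duration_s[i] / bw)
    if (nb < 1) next
    edges <- trial_table$onset_s[i] + (0:nb) * bw
    cnt <- rep(0L, nb)
    if (length(spike_times_s)) {
      # bin k covers [edges[k], edges[k+1])
      inb <- findInterval(spike_times_s, edges)
      inb <- inb[inb >= 1 & inb <= nb]
      cnt <- tabulate(inb, nbins = nb)
    }
    out[[i]] <- data.frame(
      trial_id = trial_table$trial_id[i],
      stimulus_id = trial_table$stimulus_id[i],
      state = trial_table$state[i],
      bin_id = paste0(trial_table$stimulus_id[i], ":", seq_len(nb)),
      count = cnt, stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Plug-in mutual information between spike count and bin identity
#'
#' `MI(r; s) = sum_r sum_s p(r,s) log2(p(r,s) / (p(r) p(s)))` in bits,
#' estimated from the empirical joint distribution of the pooled
#' (count, bin) observations.
#'
#' @param count spike counts (discrete response variable r)
#' @param bin_id bin identities (discrete stimulus variable s), same length
#' @return list of class `mi_estimate`: `mi` (bits), `n_bins`, `n_levels`,
#'   `n_obs`
#' @export
estimate_mi <- function(count, bin_id) {
  stopifnot(length(count) == length(bin_id))
  if (!length(count)) stop("no observations", call. = FALSE)
  if (!is.factor(bin_id)) bin_id <- factor(as.character(bin_id))
  tab <- table(factor(count), bin_id)
  if (any(colSums(tab) == 0)) {
    stop("bin with zero observations", call. = FALSE)
  }
  n <- sum(tab)
  pj <- tab / n
  pr <- rowSums(pj)
  ps <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log2(pj[nz] / outer(pr, ps)[nz]))
  structure(list(mi = max(0, mi), n_bins = ncol(tab), n_levels = nrow(tab),
                 n_obs = n), class = "mi_estimate")
}

#' State-wise mutual information with trial equalization
#'
#' When comparing MI across vigilance states, the number of trials per
#' stimulus is equalized across states by seeded random subsampling; the
#' subsample is redrawn `n_reps` times (default 10) and the median MI per
#' state reported.
#'
#' @param counts_df output of [spike_counts_by_bin()]
#' @param states states to compare (default all present)
#' @param n_reps subsampling repetitions, default 10
#' @param seed integer seed for the subsampling
#' @return named numeric vector of median MI (bits) per state
#' @export
estimate_mi_by_state <- function(counts_df, states = NULL, n_reps = 10,
                                 seed = 1) {
  states <- states %||% unique(counts_df$state)
  counts_df <- counts_df[counts_df$state %in% states, ]
  key <- interaction(counts_df$stimulus_id, counts_df$state, drop = TRUE)
  trials_per <- tapply(counts_df$trial_id, key,
                       function(x) length(unique(x)))
  # minimum trial count per stimulus across states
  reps <- with_seed(seed, {
    sapply(seq_len(n_reps), function(rep) {
      vapply(states, function(st) {
        keep <- rep(FALSE, nrow(counts_df))
        for (sid in unique(counts_df$stimulus_id)) {
          n_min <- min(vapply(states, function(s2) {
            length(unique(counts_df$trial_id[
              counts_df$stimulus_id == sid & counts_df$state == s2]))
          }, numeric(1)))
          ids <- unique(counts_df$trial_id[
            counts_df$stimulus_id == sid & counts_df$state == st])
          take <- if (length(ids) > n_min) sample(ids, n_min) else ids
          keep <- keep | (counts_df$stimulus_id == sid &
                            counts_df$trial_id %in% take &
                            counts_df$state == st)
        }
        estimate_mi(counts_df$count[keep], counts_df$bin_id[keep])$mi
      }, numeric(1))
    })
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = length(states))
  out <- apply(reps, 1, stats::median)
  names(out) <- states
  out
}

# ---- inter-trial phase coherence -------------------------------------------

#' ITPC from per-trial phases
#'
#' Resultant length of the unit phasors: `|mean_k exp(i phi_k)|`, between 0
#' (random phases) and 1 (perfect phase locking).
#'
#' @param phases per-trial phases in radians
#' @return ITPC in [0, 1]
#' @export
itpc_from_phases <- function(phases) {
  Mod(mean(exp(1i * phases)))
}

#' Inter-trial phase coherence of 40-Hz click-train responses
#'
#' Extracts each trial's phase at the stimulation frequency from a
#' single-taper (Hann) Fourier coefficient over the full stimulus window,
#' then computes the resultant length across trials. Trials with missing
#' samples (boundary-flagged) are dropped with a message.
#'
#' @param tm a `trial_matrix` of raw field-potential traces (not power),
#'   on a 1-ms grid
#' @param stimulus_duration_ms analysis window length (full stimulus)
#' @param frequency stimulation frequency, default 40 Hz
#' @param min_trials minimum trials, default 6
#' @return list of class `itpc_value`: `itpc`, `frequency`, `n`, `phases`
#' @export
compute_itpc <- function(tm, stimulus_duration_ms, frequency = 40,
                         min_trials = 6L) {
  cols <- which(tm$time_ms >= 0 & tm$time_ms < stimulus_duration_ms)
  if (length(cols) < 1000 / frequency) {
    stop("analysis window shorter than one stimulation cycle", call. = FALSE)
  }
  v <- tm$values[!tm$excluded, cols, drop = FALSE]
  ok <- stats::complete.cases(v)
  if (any(!ok)) message(sprintf("dropping %d incomplete trial(s)", sum(!ok)))
  v <- v[ok, , drop = FALSE]
  if (nrow(v) < min_trials) {
    stop(sprintf("ITPC refused: %d trials < minimum of %d", nrow(v),
                 min_trials), call. = FALSE)
  }
  t_s <- tm$time_ms[cols] / 1000
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_along(cols) / (length(cols) + 1))
  basis <- exp(-2i * pi * frequency * t_s)
  coefs <- as.vector((v * rep(taper, each = nrow(v))) %*% basis)
  phases <- Arg(coefs)
  structure(list(itpc = itpc_from_phases(phases), frequency = frequency,
                 n = length(phases), phases = phases),
            class = "itpc_value")
}

# ---- sound-envelope coupling -----------------------------------------------

#' Correlation between a high-gamma response and the sound envelope
#'
#' Both sequences must share the 5-ms grid (the high-gamma trace is
#' down-sampled to 200 Hz beforehand, e.g. via block means). The lag is
#' found as the cross-correlation argmax within `lag_range_ms` (response
#' lagging the sound); the Pearson correlation at that lag is reported with
#' a circular-shift permutation p-value (shifts preserve autocorrelation).
#'
#' @param trace response sequence on the 5-ms grid
#' @param envelope sound envelope on the same grid ([sound_envelope()])
#' @param step_ms grid step, default 5 ms
#' @param lag_range_ms lag search window, default `c(0, 250)` ms
#' @param n_perm circular-shift permutations, default 1000
#' @param seed integer seed for the permutation draws
#' @return list of class `envelope_correlation`: `r`, `lag_ms`, `perm_p`;
#'   `r` is `NA` when the envelope is constant
#' @export
correlate_with_envelope <- function(trace, envelope, step_ms = 5,
                                    lag_range_ms = c(0, 250),
                                    n_perm = 1000, seed = 1) {
  env <- as.numeric(envelope)
  L <- min(length(trace), length(env))
  trace <- trace[seq_len(L)]; env <- env[seq_len(L)]
  if (stats::sd(env) == 0) {
    message("constant envelope: correlation undefined")
    return(structure(list(r = NA_real_, lag_ms = NA_real_,
                          perm_p = NA_real_), class = "envelope_correlation"))
  }
  lags <- seq(lag_range_ms[1] %/% step_ms, lag_range_ms[2] %/% step_ms)
  lags <- lags[lags < L - 2]
  best_r_over_lags <- function(tr) {
    rs <- vapply(lags, function(k) {
      a <- env[seq_len(L - k)]
      b <- tr[(1 + k):L]
      if (stats::sd(b) == 0) return(-Inf)
      stats::cor(a, b)
    }, numeric(1))
    rs
  }
  rs <- best_r_over_lags(trace)
  i <- which.max(rs)
  r_obs <- rs[i]
  # shifts drawn over the full cycle: restricting them to "well-separated"
  # offsets breaks the group structure the permutation test relies on and
  # makes the null anti-conservative
  perm_r <- with_seed(seed, {
    shifts <- sample(L - 1L, n_perm, replace = TRUE)
    vapply(shifts, function(s) {
      max(best_r_over_lags(c(trace[(s + 1):L], trace[1:s])))
    }, numeric(1))
  })
  perm_p <- (1 + sum(perm_r >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, lag_ms = lags[i] * step_ms, perm_p = perm_p),
            class = "envelope_correlation")
}

# ---- SWA stratification ----------------------------------------------------

#' Pre-stimulus band power per trial (e.g. SWA in the 2 s before onset)
#'
#' Mean power spectral density of the given band in the `pre_s`-second
#' window preceding each onset, from a demeaned periodogram per window.
#'
#' @param x single-channel trace
#' @param rate sampling rate Hz
#' @param onsets_s trial onsets (s)
#' @param low,high band edges Hz (default SWA: 0.5--4)
#' @param pre_s pre-stimulus window length, default 2 s
#' @return numeric vector, one power value per trial (`NA` when the window
#'   falls outside the recording)
#' @export
pre_stimulus_power <- function(x, rate, onsets_s, low = 0.5, high = 4,
                               pre_s = 2) {
  npw <- round(pre_s * rate)
  freq <- (0:(npw %/% 2)) * rate / npw
  fi <- freq >= low & freq <= high
  vapply(onsets_s, function(o) {
    i1 <- round(o * rate)
    i0 <- i1 - npw + 1L
    if (i0 < 1L || i1 > length(x)) return(NA_real_)
    seg <- x[i0:i1]
    seg <- seg - mean(seg)
    X <- stats::fft(seg)[seq_along(freq)]
    mean((Mod(X)^2 / (npw * rate))[fi])
  }, numeric(1))
}

#' Stratify trials by pre-stimulus slow-wave (or sigma) activity
#'
#' Splits trials into low (below the 20th percentile) and high (above the
#' 80th percentile) pre-stimulus power groups and compares response
#' magnitudes between the two tails with a two-sample Mann--Whitney test.
#' At least `min_n` trials are required in each tail; a constant power
#' vector makes the split degenerate and is refused.
#'
#' @param power per-trial pre-stimulus band power (see
#'   [pre_stimulus_power()])
#' @param magnitudes per-trial response magnitudes, same length
#' @param probs percentile cutoffs, default `c(0.2, 0.8)`
#' @param min_n minimum trials per tail, default 6
#' @return list with `low_idx`, `high_idx`, `p`, `median_low`,
#'   `median_high`; `p` is `NA` (comparison skipped, message logged) when a
#'   tail has fewer than `min_n` trials
#' @export
stratify_by_swa <- function(power, magnitudes, probs = c(0.2, 0.8),
                            min_n = 6L) {
  stopifnot(length(power) == length(magnitudes))
  ok <- !is.na(power) & !is.na(magnitudes)
  qs <- pctl(power[ok], probs)
  if (qs[1] >= qs[2]) {
    stop("degenerate SWA split: percentile cutoffs coincide", call. = FALSE)
  }
  low_idx <- which(ok & power < qs[1])
  high_idx <- which(ok & power > qs[2])
  if (length(low_idx) < min_n || length(high_idx) < min_n) {
    message(sprintf("SWA comparison skipped: %d/%d trials per tail < %d",
                    length(low_idx), length(high_idx), min_n))
    p <- NA_real_
  } else {
    p <- stats::wilcox.test(magnitudes[high_idx], magnitudes[low_idx],
                            exact = FALSE)$p.value
  }
  list(low_idx = low_idx, high_idx = high_idx, p = p,
       median_low = stats::median(magnitudes[low_idx]),
       median_high = stats::median(magnitudes[high_idx]))
}

#' Correlation between response latency and sleep gain across channels
#'
#' Pearson correlation with a label-permutation p-value (default 10,000
#' permutations, two-sided on |r|). Requires at least 5 channels with both
#' quantities.
#'
#' @param latency_ms per-channel response latencies (ms)
#' @param gain per-channel gains (percent)
#' @param n_perm permutations, default 10000
#' @param seed integer seed
#' @return list with `r`, `perm_p`, `n`
#' @export
correlate_latency_gain <- function(latency_ms, gain, n_perm = 10000,
                                   seed = 1) {
  ok <- !is.na(latency_ms) & !is.na(gain)
  x <- latency_ms[ok]; y <- gain[ok]
  if (length(x) < 5) {
    stop("latency-gain correlation refused: fewer than 5 channels",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(x, sample(y))
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(r))) / (n_perm + 1)
  list(r = r, perm_p = p, n = length(x))
}
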