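# shared fixtures, all generated in code

# build a trial_matrix directly from a values matrix (1-ms grid)
tm_from_matrix <- function(values, time_ms, baseline_ms = c(-500, 0),
                           baselined = FALSE) {
  bl <- time_ms >= baseline_ms[1] & time_ms < baseline_ms[2]
  bmean <- rowMeans(values[, bl, drop = FALSE])
  v <- if (baselined) values - bmean else values
  audsleep:::new_trial_matrix(v, time_ms, baseline_ms, bmean, baselined,
                              excluded = logical(nrow(values)))
}

# homogeneous/step Poisson spike trains around regularly spaced onsets:
# rate = base outside [0, dur), base * mult inside (relative to each onset)
sim_step_trials <- function(n_tr, base, mult, dur_s = 1, gap_s = 3) {
  onsets <- seq(2, by = dur_s + gap_s, length.out = n_tr)
  total <- max(onsets) + dur_s + 2
  spk <- sort(runif(rpois(1, base * total), 0, total))
  if (mult != 1) {
    extra <- unlist(lapply(onsets, function(o) {
      runif(rpois(1, base * (mult - 1) * dur_s), o, o + dur_s)
    }))
    spk <- sort(c(spk, extra))
  }
  list(spk = spk, onsets = onsets, total = total)
}

# small default stimulus set reused across tests
demo_stimuli <- function(seed = 3) {
  generate_stimulus_set(
    data.frame(stimulus_id = c("w1", "c1"),
               stim_type = c("word", "click_train_40hz"),
               duration = c(1.0, 1.0)),
    rng_seed = seed)
}

# a cached small synthetic session (600 s, W/N2/N3 blocks, 1 cluster)
demo_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      hyp <- hypnogram_blocks(c("W", "N2", "N3", "W", "N2"), c(4, 4, 4, 4, 4))
      gt <- session_ground_truth(hyp, rng_seed = 11)
      cache <<- generate_session(gt, demo_stimuli(), 600)
    }
    cache
  }
})
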