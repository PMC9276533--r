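test_that("identical ground truth and seed give bit-identical sessions", {
  st <- demo_stimuli()
  hyp <- hypnogram_blocks(c("W", "N2"), 10)
  gt <- session_ground_truth(hyp, rng_seed = 7)
  s1 <- generate_session(gt, st, 600)
  s2 <- generate_session(gt, st, 600)
  expect_identical(s1$recording$signal, s2$recording$signal)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trial_table, s2$trial_table)
  gt2 <- session_ground_truth(hyp, rng_seed = 8)
  s3 <- generate_session(gt2, st, 600)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("ground-truth validation rejects out-of-range parameters", {
  hyp <- hypnogram_blocks(c("W", "N2"), 10)
  cl <- data.frame(cluster_id = "u1", channel_id = "lfp1",
                   baseline_rate = 5, gain_w = 150, gain_nrem = 70,
                   gain_rem = 90, latency_ms = 30, swa_sensitivity = 0)
  expect_error(session_ground_truth(hyp, clusters = cl), "-100, 100")
  ch <- data.frame(channel_id = "lfp1", role = "lfp",
                   envelope_coupling_r = 0.5, envelope_lag_ms = 50,
                   itpc_jitter_w = -1, itpc_jitter_nrem = 0.5,
                   itpc_jitter_rem = 0.5, abd_w = 6, abd_nrem = 2,
                   abd_rem = 4)
  expect_error(session_ground_truth(hyp, channels = ch), "jitter")
  hyp_bad <- hyp; hyp_bad$epoch_start_s[3] <- 75
  expect_error(session_ground_truth(hyp_bad), "contiguous")
})

test_that("infeasible trial packing errors name the shortfall", {
  st <- demo_stimuli()
  # 600-s all-W session but sparse stimulation: NREM cells cannot reach 6
  hyp <- hypnogram_blocks(c("W", "N2"), c(19, 1))
  gt <- session_ground_truth(hyp, isi_range = c(200, 220), rng_seed = 1)
  expect_error(generate_session(gt, st, 600), "shortfall")
  expect_error(generate_session(gt, st, 500), ">= 600")
})

test_that("zero-gain clusters spike at baseline rate (Poisson sanity)", {
  st <- demo_stimuli()
  hyp <- hypnogram_blocks("W", 20)
  cl <- data.frame(cluster_id = "u0", channel_id = "lfp1",
                   baseline_rate = 8, gain_w = 0, gain_nrem = 0,
                   gain_rem = 0, latency_ms = 0, swa_sensitivity = 0)
  gt <- session_ground_truth(hyp, clusters = cl, rng_seed = 5)
  ses <- generate_session(gt, st, 600, check_trials = FALSE)
  counts <- tabulate(floor(ses$spikes$spike_time_s) + 1, nbins = 600)
  se <- sd(counts) / sqrt(600)
  expect_lt(abs(mean(counts) - 8), 3 * se)
  # spike times respect session bounds and ordering
  expect_true(all(ses$spikes$spike_time_s > 0 &
                    ses$spikes$spike_time_s < 600))
  expect_false(is.unsorted(ses$spikes$spike_time_s))
})

test_that("trial states match the hypnogram at onset and onsets increase", {
  ses <- demo_session()
  tt <- ses$trial_table
  expect_true(all(diff(tt$onset_s) > 0))
  ep <- floor(tt$onset_s / 30) + 1
  expect_identical(tt$state, ses$hypnogram$label[ep])
})

test_that("N3 epochs carry more slow-wave power than W epochs by construction", {
  st <- demo_stimuli()
  hyp <- hypnogram_blocks(c("W", "N3", "W", "N3"), 5)
  gt <- session_ground_truth(hyp, state_params = list(delta_epoch_sd = 0.05),
                             rng_seed = 9)
  ses <- generate_session(gt, st, 600, check_trials = FALSE)
  sp <- spectrogram_30s(ses$recording)
  delta <- epoch_band_power(sp, 0.5, 4)
  w_ep <- ses$hypnogram$label == "W"
  expect_gt(min(delta[!w_ep]), max(delta[w_ep]))
})

test_that("injected high-gamma modulation has exactly the target envelope correlation", {
  ses <- demo_session()
  gt <- ses$ground_truth
  for (ch in gt$channels$channel_id) {
    for (sid in names(ses$stimuli)) {
      env <- as.numeric(sound_envelope(ses$stimuli[[sid]]$waveform,
                                       ses$stimuli[[sid]]$rate))
      m <- ses$injected$hg_mod[[ch]][[sid]]
      r_target <- gt$channels$envelope_coupling_r[
        gt$channels$channel_id == ch]
      expect_equal(cor(m, env), r_target, tolerance = 0.05)
    }
  }
})

test_that("40-Hz steady-state phases are jittered per state as requested", {
  ses <- demo_session()
  tt <- ses$trial_table
  ph <- ses$injected$ssr_phase[["ieeg1"]]
  click <- tt$stim_type == "click_train_40hz"
  expect_true(all(is.na(ph[!click])))
  expect_true(all(!is.na(ph[click])))
  # NREM jitter (0.8 rad) wider than W jitter (0.3 rad)
  sd_w <- sd(ph[click & tt$state == "W"])
  sd_n <- sd(ph[click & tt$state %in% c("N2", "N3")])
  expect_gt(sd_n, sd_w)
})

test_that("behaviour proxy flags are mutually exclusive and track wakefulness", {
  ses <- demo_session()
  beh <- ses$behavior
  expect_true(all(xor(beh$awake_evidence, beh$quiescent)))
  w <- ses$hypnogram$label == "W"
  expect_gt(mean(beh$awake_evidence[w]), 0.6)
  expect_true(all(!beh$awake_evidence[!w]))
})
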