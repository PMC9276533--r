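rate <- 1000
t_s <- (0:9999) / rate

test_that("band power envelope: in-band sinusoid gives a flat envelope at 20*log10(a)", {
  for (a in c(1, 0.3)) {
    rec <- continuous_recording(matrix(a * sin(2 * pi * 100 * t_s), 1),
                                rate, "ch", "lfp")
    env <- band_power_envelope(rec, "high_gamma")
    mid <- env[1, 2000:8000]
    expect_equal(mean(mid), 20 * log10(a), tolerance = 0.05)
    # ripple below 5% (in amplitude terms ~0.42 dB)
    expect_lt(max(abs(mid - mean(mid))), 20 * log10(1.05))
  }
})

test_that("band power envelope: out-of-band energy is attenuated by >= 40 dB", {
  rec <- continuous_recording(matrix(sin(2 * pi * 5 * t_s), 1), rate,
                              "ch", "lfp")
  env <- band_power_envelope(rec, "high_gamma")
  expect_lt(mean(env[1, 2000:8000]), -40)
})

test_that("band power envelope: amplitude step a -> 2a shows as +6.02 dB", {
  x <- sin(2 * pi * 120 * t_s) * rep(c(1, 2), each = 5000)
  rec <- continuous_recording(matrix(x, 1), rate, "ch", "lfp")
  env <- band_power_envelope(rec, "high_gamma")
  step <- mean(env[1, 6000:9000]) - mean(env[1, 1000:4000])
  expect_equal(step, 20 * log10(2), tolerance = 0.05)
})

test_that("band edges above Nyquist are rejected", {
  rec <- continuous_recording(matrix(rnorm(2000), 1), rate, "ch", "lfp")
  expect_error(band_power_envelope(rec, c(400, 600)), "Nyquist")
})

test_that("epoching subtracts each trial's own baseline mean", {
  # constant trace -> all-zero baselined traces
  x <- rep(7, 5000)
  tm <- epoch_trials(x, rate, c(1, 2, 3), c(-500, 600))
  expect_true(all(tm$values == 0))
  # +3 dB step response after a baseline of b
  x2 <- rep(2, 5000); x2[3001:3500] <- 5
  tm2 <- epoch_trials(x2, rate, 3.0, c(-500, 600))
  expect_equal(unname(tm2$values[1, tm2$time_ms >= 0 & tm2$time_ms < 500]),
               rep(3, 500))
  expect_equal(tm2$baseline_mean[1], 2)
})

test_that("baselining is invariant to per-trial constant offsets", {
  set.seed(1)
  x <- rnorm(8000)
  tm1 <- epoch_trials(x, rate, c(1, 3, 5), c(-500, 1000))
  tm2 <- epoch_trials(x + 11.5, rate, c(1, 3, 5), c(-500, 1000))
  expect_equal(tm1$values, tm2$values)
})

test_that("trials extending past the recording are flagged, not dropped", {
  x <- rnorm(4000)
  expect_message(tm <- epoch_trials(x, rate, c(1, 3.6), c(-500, 600)),
                 "flagged")
  expect_equal(tm$excluded, c(FALSE, TRUE))
  expect_equal(nrow(tm$values), 2)
})

test_that("outlier exclusion flags exactly the trials beyond mean + 5 s.d.", {
  set.seed(2)
  v <- matrix(rnorm(50 * 100), 50)
  tmean <- rowMeans(v)
  v[7, ] <- v[7, ] + (mean(tmean) + 10 * sd(tmean))   # one extreme trial
  tm <- tm_from_matrix(v, -20:79, c(-20, 0))
  out <- exclude_outlier_trials(tm)
  expect_equal(which(out$excluded), 7L)
  # all-equal trials: no exclusions
  tm2 <- tm_from_matrix(matrix(1, 10, 100), -20:79, c(-20, 0))
  expect_equal(sum(exclude_outlier_trials(tm2)$excluded), 0)
})

test_that("5-s.d. exclusions are (essentially) absent for Gaussian trials", {
  set.seed(3)
  n_ex <- replicate(20, {
    tm <- tm_from_matrix(matrix(rnorm(1000 * 50), 1000), -20:29, c(-20, 0))
    sum(exclude_outlier_trials(tm)$excluded)
  })
  expect_lte(mean(n_ex), 0.1)   # P(|z| > 5) * 1000 << 1
})

test_that("smoothed spike trains: unit-area Gaussian kernel in spikes/s", {
  tm <- smooth_spike_trains(0.1, 0, c(-500, 600))
  # single spike at 100 ms: Gaussian bump, peak 1/(sigma*sqrt(2*pi))
  expect_equal(tm$time_ms[which.max(tm$values[1, ])], 100)
  expect_equal(max(tm$values[1, ]), 1000 / (10 * sqrt(2 * pi)),
               tolerance = 0.01)
  # integral returns the spike count (1), up to edge loss
  expect_equal(sum(tm$values[1, ]) / 1000, 1, tolerance = 0.01)
  # empty cluster: all-zero with a warning
  expect_warning(tm0 <- smooth_spike_trains(numeric(0), c(0, 5), c(-500, 600)),
                 "empty cluster")
  expect_true(all(tm0$values == 0))
})

test_that("smoothed rate of homogeneous Poisson spiking recovers the rate", {
  set.seed(4)
  s <- sim_step_trials(100, 10, 1)
  tm <- smooth_spike_trains(s$spk, s$onsets, c(-500, 1100))
  grand <- mean(tm$values)
  se <- sd(rowMeans(tm$values)) / sqrt(100)
  expect_lt(abs(grand - 10), 3 * se + 0.1)
  # integral-vs-count bookkeeping across trials
  n_in_epochs <- sum(sapply(s$onsets, function(o) {
    sum(s$spk >= o - 0.5 & s$spk < o + 1.1)
  }))
  expect_equal(sum(tm$values) / 1000, n_in_epochs, tolerance = 0.02)
})

test_that("sound envelope: squared-amplitude block means on the 5-ms grid", {
  # constant amplitude a -> constant a^2
  env <- sound_envelope(rep(0.5, 8000), 8000)
  expect_equal(as.numeric(env), rep(0.25, 200))
  # 1 s at 8 kHz -> 200 blocks
  expect_length(env, 200)
  # half silence, half amplitude a
  w <- c(rep(0, 4000), rep(0.8, 4000))
  env2 <- as.numeric(sound_envelope(w, 8000))
  expect_equal(env2[1:100], rep(0, 100))
  expect_equal(env2[101:200], rep(0.64, 100))
  expect_error(sound_envelope(numeric(0), 8000), "empty")
})

test_that("30-s spectrogram: epoch count, pure-tone delta dominance, white-noise flatness", {
  set.seed(5)
  rec <- continuous_recording(matrix(sin(2 * pi * 2 * (0:299999) / 1000), 1),
                              1000, "d", "ieeg")
  sp <- spectrogram_30s(rec)
  expect_length(sp$epoch_start_s, 10)   # 300 s -> 10 epochs
  delta <- epoch_band_power(sp, 0.5, 4)
  high <- epoch_band_power(sp, 10, 40)
  expect_gt(10 * log10(mean(delta) / mean(high)), 20)
  # white noise: flat density within 3 dB
  recw <- continuous_recording(matrix(rnorm(300000), 1), 1000, "d", "ieeg")
  spw <- spectrogram_30s(recw)
  dw <- epoch_band_power(spw, 0.5, 4); hw <- epoch_band_power(spw, 10, 40)
  expect_lt(abs(10 * log10(mean(dw) / mean(hw))), 3)
})

test_that("narrowband Hilbert envelope^2 equals twice the mean power", {
  set.seed(6)
  x <- bandpass_filter(rnorm(20000), 1000, 80, 120)
  env <- hilbert_envelope(x)
  mid <- 2000:18000
  expect_equal(mean(env[mid]^2), 2 * mean(x[mid]^2), tolerance = 0.05)
})

test_that("down-sampling to 1 kHz before filtering matches filtering at source rate", {
  set.seed(7)
  x4k <- rnorm(40000)   # 10 s at 4 kHz
  ds <- downsample_signal(x4k, 4000, 1000)
  env_ds <- hilbert_envelope(bandpass_filter(ds$x, 1000, 80, 200))
  env_src <- hilbert_envelope(bandpass_filter(x4k, 4000, 80, 200))
  env_src_1k <- env_src[seq(1, 40000, by = 4)]
  mid <- 1000:9000
  expect_gt(cor(env_ds[mid], env_src_1k[mid]), 0.99)
})
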