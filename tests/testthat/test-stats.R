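test_that("gain formula: identities, bounds and antisymmetry", {
  expect_equal(compute_gain(5, 5)$gain, 0)
  expect_equal(compute_gain(0, 10)$gain, -100)
  expect_equal(compute_gain(7.2, 10)$gain, -28)
  expect_true(is.na(compute_gain(0, 0)$gain))
  # bounds and antisymmetry over random magnitudes (including negatives)
  set.seed(20)
  for (i in 1:200) {
    rs <- runif(1, -20, 20); ra <- runif(1, -20, 20)
    g <- compute_gain(rs, ra)$gain
    expect_gte(g, -100); expect_lte(g, 100)
    expect_equal(compute_gain(ra, rs)$gain, -g)
  }
})

# brute-force MI oracle: explicit double sum over all (r, s) pairs
mi_oracle <- function(count, bin_id) {
  rs <- unique(count); ss <- unique(bin_id)
  N <- length(count)
  mi <- 0
  for (r in rs) {
    for (s in ss) {
      prs <- sum(count == r & bin_id == s) / N
      if (prs > 0) {
        mi <- mi + prs * log2(prs / (sum(count == r) / N * sum(bin_id == s) / N))
      }
    }
  }
  mi
}

test_that("plug-in MI: exact hand values and brute-force oracle agreement", {
  # counts independent of bin identity -> 0 bits
  expect_equal(estimate_mi(rep(c(0, 3), 10), rep(c("a", "b"), each = 10))$mi, 0)
  # two equiprobable bins with deterministic 0 vs 3 counts -> 1 bit
  expect_equal(estimate_mi(rep(c(0, 3), each = 6),
                           rep(c("a", "b"), each = 6))$mi, 1)
  # random 4-bin tables match the brute-force double sum to 1e-12
  set.seed(21)
  for (i in 1:20) {
    s <- sample(letters[1:4], 120, replace = TRUE)
    r <- rpois(120, 1 + 2 * (s %in% c("a", "b")))
    expect_equal(estimate_mi(r, s)$mi, mi_oracle(r, s), tolerance = 1e-12)
  }
  expect_error(estimate_mi(integer(0), character(0)))
})

test_that("MI is bounded by log2(n_bins) and errors on empty bins", {
  set.seed(22)
  s <- rep(letters[1:8], each = 30)
  r <- rpois(length(s), 2)
  est <- estimate_mi(r, s)
  expect_lte(est$mi, log2(est$n_bins))
  expect_error(estimate_mi(c(1, 2), factor(c("a", "a"), levels = c("a", "b"))),
               "zero")
})

test_that("plug-in MI bias on independent data stays below the analytic bound", {
  set.seed(23)
  excess <- replicate(30, {
    s <- rep(as.character(1:9), each = 40)   # 9 bins, 360 observations
    r <- rpois(length(s), 2)                 # independent of s
    est <- estimate_mi(r, s)
    bound <- (est$n_bins - 1) * (est$n_levels - 1) / (2 * est$n_obs * log(2))
    est$mi <= 3 * bound
  })
  expect_gte(mean(excess), 0.9)
})

test_that("spike binning reproduces the 450-ms-word = 9-bins example", {
  tt <- data.frame(trial_id = "t1", stimulus_id = "w", onset_s = 10,
                   duration_s = 0.45, state = "W")
  cb <- spike_counts_by_bin(c(10.02, 10.03, 10.21, 10.44, 10.46), tt)
  expect_equal(nrow(cb), 9)
  expect_equal(sum(cb$count), 4)   # spike at 10.46 falls past the last bin
  expect_equal(cb$count[1], 2)
})

test_that("state-wise MI equalizes trials and detects rate modulation", {
  set.seed(24)
  # 3 'word' stimuli with distinct 4-bin rate profiles in W, flat in NREM
  mk <- function(profile, n_tr, state, sid, t0) {
    tt <- data.frame(trial_id = sprintf("%s_%s_%d", sid, state, 1:n_tr),
                     stimulus_id = sid, onset_s = t0 + (1:n_tr) * 2,
                     duration_s = 0.2, state = state)
    spk <- unlist(lapply(seq_len(n_tr), function(j) {
      unlist(lapply(1:4, function(b) {
        n <- rpois(1, profile[b])
        runif(n, tt$onset_s[j] + (b - 1) * 0.05, tt$onset_s[j] + b * 0.05)
      }))
    }))
    list(tt = tt, spk = spk)
  }
  parts <- list(
    mk(c(8, 0, 0, 0), 20, "W", "s1", 0), mk(c(0, 8, 0, 8), 20, "W", "s2", 100),
    mk(c(0, 0, 8, 0), 20, "W", "s3", 200),
    mk(c(2, 2, 2, 2), 30, "NREM", "s1", 300),
    mk(c(2, 2, 2, 2), 30, "NREM", "s2", 400),
    mk(c(2, 2, 2, 2), 30, "NREM", "s3", 500))
  tt <- do.call(rbind, lapply(parts, `[[`, "tt"))
  tt <- tt[order(tt$onset_s), ]
  spk <- sort(unlist(lapply(parts, `[[`, "spk")))
  cb <- spike_counts_by_bin(spk, tt)
  mi <- estimate_mi_by_state(cb, states = c("W", "NREM"), seed = 9)
  expect_gt(mi[["W"]], mi[["NREM"]] + 0.15)
  expect_gt(mi[["W"]], 0.3)
  expect_lt(mi[["NREM"]], 0.25)   # plug-in bias keeps flat profiles above 0
})

test_that("ITPC: exact values on hand-computable phase sets", {
  expect_equal(itpc_from_phases(rep(1.3, 8)), 1)
  expect_equal(itpc_from_phases(rep(c(0, pi), 5)), 0, tolerance = 1e-12)
  expect_equal(itpc_from_phases(c(0, pi / 2)), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("ITPC null level matches the Rayleigh expectation sqrt(pi/4)/sqrt(N)", {
  set.seed(25)
  for (N in c(10, 40)) {
    vals <- replicate(1000, itpc_from_phases(runif(N, 0, 2 * pi)))
    expect_lt(abs(mean(vals) - sqrt(pi / 4) / sqrt(N)),
              0.2 * sqrt(pi / 4) / sqrt(N))
  }
})

test_that("spectral phase extraction recovers locked vs jittered 40-Hz trials", {
  set.seed(26)
  mk_trials <- function(jit_sd, n_tr = 30) {
    v <- t(sapply(seq_len(n_tr), function(k) {
      ph <- rnorm(1, 0, jit_sd)
      tt <- seq(-0.5, 1.099, by = 0.001)
      s <- numeric(length(tt))
      on <- tt >= 0 & tt < 1
      s[on] <- 3 * cos(2 * pi * 40 * tt[on] + ph)
      s + rnorm(length(tt), sd = 0.5)
    }))
    tm_from_matrix(v, -500:1099, c(-500, 0))
  }
  it0 <- compute_itpc(mk_trials(0), 1000)
  expect_gt(it0$itpc, 0.99)
  it_j <- compute_itpc(mk_trials(1.0), 1000)
  expect_lt(it_j$itpc, it0$itpc - 0.2)
  expect_error(compute_itpc(mk_trials(0, 4), 1000), "ITPC refused")
})

test_that("envelope correlation: exact recovery on a shifted copy", {
  set.seed(27)
  env <- abs(rnorm(400))
  trace <- c(rep(0, 10), env)[1:400]    # copy delayed by 10 samples = 50 ms
  ec <- correlate_with_envelope(trace, env)
  expect_equal(ec$lag_ms, 50)
  expect_gt(ec$r, 0.99)
  # full-cycle shifts keep the null exact at the cost of a p floor from
  # shifts that re-align the copy within the lag window (~51/400 here)
  expect_lt(ec$perm_p, 0.15)
})

test_that("envelope correlation: constant envelope is refused, noise is non-significant", {
  expect_message(ec <- correlate_with_envelope(rnorm(100), rep(1, 100)),
                 "constant")
  expect_true(is.na(ec$r))
  set.seed(28)
  ps <- replicate(40, {
    correlate_with_envelope(rnorm(300), abs(rnorm(300)), n_perm = 200,
                            seed = sample.int(1e6, 1))$perm_p
  })
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("SWA stratification: percentile arithmetic, degenerate input, minimum trials", {
  set.seed(29)
  swa <- runif(50); mag <- rnorm(50)
  st <- stratify_by_swa(swa, mag)
  expect_lte(length(st$low_idx), 10)    # 20th percentile of 50 trials
  expect_lte(length(st$high_idx), 10)
  expect_error(stratify_by_swa(rep(1, 50), mag), "degenerate")
  expect_message(st2 <- stratify_by_swa(runif(20), rnorm(20)), "skipped")
  expect_true(is.na(st2$p))
})

test_that("SWA-dependent attenuation is detected by the stratified comparison", {
  set.seed(30)
  hits <- replicate(20, {
    swa <- runif(60)
    mag <- 10 * (1 - 0.8 * swa) + rnorm(60, sd = 1)
    st <- stratify_by_swa(swa, mag)
    st$median_high < st$median_low && st$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("latency-gain correlation: exact linear relation and sample-size gate", {
  lat <- c(20, 50, 80, 120, 160, 190)
  g <- 0.5 * lat - 60
  res <- correlate_latency_gain(lat, g, n_perm = 500)
  expect_equal(res$r, 1)
  expect_lt(res$perm_p, 0.05)
  expect_error(correlate_latency_gain(lat[1:4], g[1:4]), "fewer than 5")
})

test_that("latency-gain permutation p is well-behaved under the null", {
  set.seed(31)
  ps <- replicate(40, {
    correlate_latency_gain(rnorm(20), rnorm(20), n_perm = 200,
                           seed = sample.int(1e6, 1))$perm_p
  })
  expect_gt(mean(ps > 0.05), 0.8)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.25)
})
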