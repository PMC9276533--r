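# brute-force Mann-Whitney oracle: full enumeration of group assignments
mw_oracle <- function(x, y, tail = "increase") {
  if (tail == "decrease") { x <- -x; y <- -y }
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mean(u_all >= u_obs - 1e-9)
}

test_that("pointwise rank test equals exact Mann-Whitney enumeration for groups <= 8", {
  set.seed(10)
  for (n in c(3, 6, 8)) {
    for (m in c(3, 6, 8)) {
      # continuous values
      x <- rnorm(n, 1); y <- rnorm(m)
      expect_equal(audsleep:::mw_p_one(x, y), mw_oracle(x, y),
                   tolerance = 1e-12)
      # heavily tied, zero-inflated values (spike-rate-like)
      x2 <- sample(c(0, 0, 0, 2.5, 39.9), n, replace = TRUE)
      y2 <- sample(c(0, 0, 2.5), m, replace = TRUE)
      expect_equal(audsleep:::mw_p_one(x2, y2), mw_oracle(x2, y2),
                   tolerance = 1e-12)
    }
  }
})

test_that("public rank test exercises the exact path end to end (6 vs 6)", {
  # all response values above all baseline values: p = 1/C(12,6)
  v <- cbind(matrix(0:5, 6, 100), matrix(10 + 0:5, 6, 200))
  tm <- tm_from_matrix(v, -100:199, c(-100, 0))
  p <- pointwise_rank_test(tm, 100, baseline = "per_trial_mean",
                           baseline_stride_ms = 100)
  expect_equal(unname(p[1]), 1 / choose(12, 6), tolerance = 1e-12)
  # wrong tail: p ~= 1 everywhere
  p_dec <- pointwise_rank_test(tm, 100, tail = "decrease",
                               baseline = "per_trial_mean")
  expect_true(all(p_dec > 0.99))
})

test_that("rank-test p-values are uniform under the null", {
  # within one channel the columns share the baseline pool, so marginal
  # calibration is assessed by pooling across independent channels
  set.seed(11)
  p <- unlist(lapply(1:30, function(i) {
    v <- matrix(rnorm(15 * 650), 15)
    tm <- tm_from_matrix(v, -500:149, c(-500, 0))
    pointwise_rank_test(tm, 50)
  }))
  expect_lt(abs(mean(p < 0.01) - 0.01), 0.008)
  expect_lt(abs(mean(p < 0.5) - 0.5), 0.05)
  expect_lt(abs(mean(p) - 0.5), 0.03)
})

test_that("detection is refused below six usable trials", {
  v <- matrix(rnorm(5 * 700), 5)
  tm <- tm_from_matrix(v, -500:199, c(-500, 0))
  expect_error(pointwise_rank_test(tm, 100), "refused")
})

test_that("BH correction matches a hand computation and a brute-force oracle", {
  # hand case at alpha 0.05: q = (0.003, 0.03, 0.9) -> first two pass
  f <- fdr_correct(c(0.001, 0.02, 0.9), base_alpha = 0.05)
  expect_equal(unname(f$q), c(0.003, 0.03, 0.9))
  expect_equal(unname(f$mask), c(TRUE, TRUE, FALSE))
  # brute-force BH oracle on random vectors
  bh_oracle <- function(p, alpha) {
    m <- length(p); o <- order(p)
    k <- which(p[o] <= alpha * seq_len(m) / m)
    mask <- rep(FALSE, m)
    if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
    mask
  }
  set.seed(12)
  for (i in 1:20) {
    p <- runif(50)^3
    expect_identical(unname(fdr_correct(p, 0.01)$mask), bh_oracle(p, 0.01))
  }
  # boundary case: m identical p-values at alpha * k / m
  p_b <- rep(0.01 * 3 / 5, 5)
  expect_identical(unname(fdr_correct(p_b, 0.01)$mask), bh_oracle(p_b, 0.01))
})

test_that("interval assembly bridges short gaps then drops short components", {
  params <- detection_params("spike")
  # runs [100,150) and [151,153): 1-ms gap -> bridged into [100,153)
  mask <- rep(FALSE, 1100); names(mask) <- 0:1099
  mask[101:150] <- TRUE   # [100, 150)
  mask[152:153] <- TRUE   # [151, 153)
  iset <- assemble_intervals(mask, params, 1000)
  expect_equal(iset$intervals$start_ms, 100)
  expect_equal(iset$intervals$end_ms, 153)
  # isolated 4-ms run: shorter than the 5-ms minimum -> removed
  mask2 <- rep(FALSE, 1100); names(mask2) <- 0:1099
  mask2[201:204] <- TRUE
  mask2[301:350] <- TRUE
  iset2 <- assemble_intervals(mask2, params, 1000)
  expect_equal(iset2$intervals$start_ms, 300)
  # 10 ms of total significance on a 1000-ms stimulus: below the 1.5% gate
  mask3 <- rep(FALSE, 1100); names(mask3) <- 0:1099
  mask3[501:510] <- TRUE
  expect_equal(nrow(assemble_intervals(mask3, params, 1000)$intervals), 0)
  # power params carry no total gate: a 10-ms component survives
  iset4 <- assemble_intervals(mask3, detection_params("power", "high_gamma"),
                              1000)
  expect_equal(nrow(iset4$intervals), 1)
})

test_that("latency is the first significant millisecond, gated at 200 ms", {
  params <- detection_params("power", "high_gamma")
  mask <- rep(FALSE, 600); names(mask) <- 0:599
  mask[39:100] <- TRUE     # first significant ms = 38
  iset <- assemble_intervals(mask, params, 500)
  expect_equal(extract_latency(iset), 38)
  mask2 <- rep(FALSE, 600); names(mask2) <- 0:599
  mask2[251:400] <- TRUE   # earliest significance at 250 ms -> absent
  expect_true(is.na(extract_latency(assemble_intervals(mask2, params, 500))))
})

test_that("an injected step response is detected with accurate onset latency", {
  set.seed(13)
  lat <- replicate(10, {
    s <- sim_step_trials(40, 30, 3, dur_s = 0.5)
    shifted <- s$onsets - 0.05          # response begins 50 ms after onset
    tm <- smooth_spike_trains(s$spk, shifted, c(-500, 700))
    d <- detect_responses(tm, detection_params("spike"), 600)
    d$latency_ms
  })
  expect_true(all(!is.na(lat)))
  # the 10-ms smoothing kernel advances the detected onset by ~1 sigma,
  # so recovery is accurate to about 2 sigma
  expect_true(all(abs(lat - 50) <= 20))
  expect_lt(abs(mean(lat) - 50) , 15)
})

test_that("replicating the response distribution with more trials never removes intervals", {
  set.seed(14)
  v <- matrix(rnorm(12 * 700), 12)
  v[, 550:650] <- v[, 550:650] + 2.5    # response at [49,150) ms
  tm1 <- tm_from_matrix(v, -500:199, c(-500, 0))
  d1 <- detect_responses(tm1, detection_params("power", "high_gamma"), 100)
  tm2 <- tm_from_matrix(rbind(v, v), -500:199, c(-500, 0))
  d2 <- detect_responses(tm2, detection_params("power", "high_gamma"), 100)
  expect_gte(nrow(d2$intervals), nrow(d1$intervals))
  if (nrow(d1$intervals)) {
    # every ms significant with n trials stays significant with 2n
    ms1 <- unlist(mapply(seq, d1$intervals$start_ms, d1$intervals$end_ms - 1,
                         SIMPLIFY = FALSE))
    ms2 <- unlist(mapply(seq, d2$intervals$start_ms, d2$intervals$end_ms - 1,
                         SIMPLIFY = FALSE))
    expect_true(all(ms1 %in% ms2))
  }
})

test_that("magnitude sign follows the tested tail for desynchronization", {
  set.seed(15)
  v <- matrix(rnorm(20 * 700), 20)
  v[, 501:700] <- v[, 501:700] - 3   # sustained decrease from onset
  tm <- tm_from_matrix(v, -500:199, c(-500, 0))
  d <- detect_responses(tm, detection_params("power", "alpha_beta"), 100)
  expect_gt(nrow(d$intervals), 0)
  expect_lt(d$magnitude, 0)
  expect_lt(d$peak, 0)
})
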