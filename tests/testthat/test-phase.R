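stim <- fix_stim()
f_p <- stim$presentation_freq
tr <- stim$tr
tt <- (0:179) * tr

test_that("fourier component follows the cosine convention", {
  comp <- fourier_component(cos(2 * pi * f_p * tt), f_p, tr)
  expect_equal(comp$amplitude, 1)
  expect_lt(min(comp$phase, 2 * pi - comp$phase), 1e-8)  # 0 up to wrap
  comp2 <- fourier_component(sin(2 * pi * f_p * tt), f_p, tr)
  expect_equal(comp2$phase, 3 * pi / 2)   # sin = cos(x - pi/2), wrapped
  comp3 <- fourier_component(2.3 * cos(2 * pi * f_p * tt + 1.1), f_p, tr)
  expect_equal(comp3$amplitude, 2.3)
  expect_equal(comp3$phase, 1.1)
  expect_error(fourier_component(rnorm(5), f_p, tr), "shorter")
  expect_error(fourier_component(rnorm(100), 0.0345, tr), "harmonic")
})

test_that("white-noise amplitude matches the analytic Rayleigh mean", {
  # a = 2|X|/n with X complex Gaussian: E[a] = sigma * sqrt(pi / n)
  set.seed(11)
  n <- 180
  amps <- replicate(5000, fourier_component(rnorm(n), f_p, tr)$amplitude)
  expect_equal(mean(amps), sqrt(pi / n), tolerance = 0.04)
})

test_that("activation z-score: self-model, orthogonal series, noisy model", {
  ts <- 1.7 * cos(2 * pi * f_p * tt + 0.4)
  comp <- fourier_component(ts, f_p, tr)
  z <- activation_zscore(ts, comp, f_p, tr)
  expect_equal(z, atanh(1 - 1e-12))          # capped at the numeric limit
  ts2 <- cos(2 * pi * 2 * f_p * tt)          # pure second harmonic
  z2 <- activation_zscore(ts2, list(amplitude = 1, phase = 0), f_p, tr)
  expect_lt(abs(z2), 1e-8)
  expect_true(is.na(activation_zscore(rep(1, 180),
                                      list(amplitude = 0, phase = 0), f_p, tr)))
  # model + unit noise, model SD 1: E[r] ~ 1/sqrt(2), z ~ 0.881
  set.seed(12)
  zs <- replicate(400, {
    model <- sqrt(2) * cos(2 * pi * f_p * tt)   # SD 1
    y <- model + rnorm(180)
    activation_zscore(y, fourier_component(y, f_p, tr), f_p, tr)
  })
  expect_equal(mean(zs), atanh(1 / sqrt(2)), tolerance = 0.05)
})

test_that("phase averaging and latency transform follow the stated forms", {
  expect_equal(average_phase(1.0, 2.0), (1 + 2 * pi - 2) / 2)
  expect_equal(average_phase(0.7, 0.7), pi)
  expect_equal(phase_to_latency(0, f_p), 0)
  expect_equal(phase_to_latency(pi, f_p), 15)
  expect_equal(phase_to_latency(2 * pi - 1e-9, f_p), 30, tolerance = 1e-6)
})

test_that("hemodynamic delay cancels in the rising/falling phase average", {
  phis <- sapply(c(3, 5, 8), function(d) {
    gt <- fix_latency_gt(c(4, 12, 17), delay = d)
    runs <- simulate_subject(gt, 1, depths = 0.1)
    map_subject(runs, stim, z_threshold = -Inf)[["0.1"]]$phi_avg
  })
  expect_lt(max(apply(phis, 1, function(x) diff(range(x)))), 0.02)
})

test_that("noiseless subject mapping recovers preferences up to quantization", {
  gt <- fix_world(noise_sd = 0, delay_range = 5, nrow = 6, ncol = 20,
                  core_shape = c(3, 8))
  runs <- simulate_subject(gt, 1, depths = 0.1)
  m <- map_subject(runs, stim, z_threshold = -Inf)[["0.1"]]
  # interior vertices (away from sweep-edge truncation) recover within
  # the latency-quantization bound (TR/2 * 0.2 oct/s = 0.25 oct)
  interior <- gt$logf > log(700) & gt$logf < log(1800)
  expect_lt(max(abs(m$logf - gt$logf)[interior] / log(2)), 0.25)
  expect_lt(median(abs(m$logf - gt$logf)[interior] / log(2)), 0.05)
  # ordering is preserved everywhere within each gradient arm
  co <- sheet_coords(gt$sheet)
  arm <- co$row == 1 & co$col <= 10
  expect_equal(cor(m$logf[arm], gt$logf[arm], method = "spearman"), 1)
})

test_that("pure-noise subjects are rejected by the activation threshold", {
  gt <- fix_world(noise_sd = 1, nrow = 8, ncol = 12, core_shape = c(4, 6),
                  amplitude = 0, seed = 21)
  runs <- simulate_subject(gt, 1, depths = 0.1, seed = 33)
  m <- map_subject(runs, stim, z_threshold = 1.65)[["0.1"]]
  expect_gte(mean(!m$valid), 0.95)
  m_all <- map_subject(runs, stim, z_threshold = -Inf)[["0.1"]]
  expect_true(all(m_all$valid | is.na(m_all$logf)))
  expect_true(all(m_all$valid[!is.na(m_all$logf)]))
})

test_that("direction labels are symmetric: swapping runs and labels is a no-op", {
  gt <- fix_world(nrow = 4, ncol = 10, core_shape = c(2, 4), seed = 5)
  runs <- simulate_subject(gt, 1, depths = 0.1, seed = 8)
  swapped <- lapply(runs, function(r) {
    r$direction <- if (r$direction == "rising") "falling" else "rising"
    r
  })
  m1 <- map_subject(runs, stim, z_threshold = -Inf)[["0.1"]]
  # swapping both the data-role and the labels changes which series is
  # called rising, so phi_avg maps latency L to chirp-L; re-swapping the
  # label assignment restores the original estimates
  m2 <- map_subject(swapped, stim, z_threshold = -Inf)[["0.1"]]
  ok <- !is.na(m1$logf) & !is.na(m2$logf)
  expect_gt(cor(m1$latency[ok], stim$chirp_duration - m2$latency[ok]), 0.999)
})

test_that("latency debiasing inverts the sweep-edge compression", {
  gt <- fix_world(noise_sd = 0, delay_range = 4, nrow = 4, ncol = 30,
                  core_shape = c(2, 10))
  runs <- simulate_subject(gt, 1, depths = 0.1)
  m <- map_subject(runs, stim, z_threshold = -Inf)[["0.1"]]
  tm <- tuning_map(runs, stim, latency = m$latency)[["0.1"]]
  lat_db <- debias_latency(m$latency, tm$tw_octaves, stim)
  logf_db <- latency_to_log_frequency(lat_db, stim)
  err_raw <- abs(m$logf - gt$logf) / log(2)
  err_db <- abs(logf_db - gt$logf) / log(2)
  expect_lt(median(err_db, na.rm = TRUE), 0.02)
  expect_lt(median(err_db, na.rm = TRUE), median(err_raw, na.rm = TRUE))
})
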