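stim <- fix_stim()

test_that("ground truth geometry is as configured", {
  sheet <- cortical_sheet(40, 60)
  gt <- make_ground_truth(sheet, stim, core_shape = c(8, 10))
  expect_equal(sum(gt$core_mask), 80)
  # column-wise gradient: every row carries the identical tonotopy profile
  M <- matrix(gt$logf, 40, 60, byrow = TRUE)
  expect_true(all(apply(M, 2, function(cl) all(cl == cl[1]))))
  # mirror symmetric, spanning the full chirp range
  expect_equal(M[1, ], rev(M[1, ]))
  expect_equal(range(gt$logf), c(log(250), log(4000)))
  # lambda table stored verbatim
  lt <- default_lambda_table(sheet$depths)
  expect_identical(gt$lambda_table, lt)
  expect_equal(true_lambda(gt, 0.1, "core"), 2.0)
  expect_error(make_ground_truth(cortical_sheet(4, 6), stim,
                                 core_shape = c(8, 10)), "larger than sheet")
})

test_that("noiseless evoked response peaks when the chirp crosses the preference", {
  gt <- fix_latency_gt(c(10, 10), delay = 0)
  run <- simulate_run(gt, "rising", depth = 0.1)
  blk <- block_average(run$data, stim, "rising")
  tt <- (0:(ncol(blk) - 1)) * stim$tr
  expect_equal(tt[which.max(blk[1, ])], 10)   # chirp passes 1000 Hz at t = 10
  gt5 <- fix_latency_gt(c(10, 10), delay = 5)
  blk5 <- block_average(simulate_run(gt5, "rising", depth = 0.1)$data,
                        stim, "rising")
  expect_equal(tt[which.max(blk5[1, ])], 15)  # a delay is a pure shift
})

test_that("runs are bit-reproducible under a fixed seed", {
  gt <- fix_world(noise_sd = 0.2, nrow = 4, ncol = 8, core_shape = c(2, 4))
  a <- simulate_run(gt, "rising", depth = 0.1, seed = 9)
  b <- simulate_run(gt, "rising", depth = 0.1, seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$nuisance, b$nuisance)
  c <- simulate_run(gt, "rising", depth = 0.1, seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("run dimensions and nuisance records match the paradigm", {
  gt <- fix_world(nrow = 3, ncol = 6, core_shape = c(2, 3))
  run <- simulate_run(gt, "falling", depth = 0.1)
  expect_equal(ncol(run$data), 180)   # 15 blocks x 30 s / 2.5 s
  expect_equal(nrow(run$data), 18)
  expect_equal(dim(run$nuisance), c(180, 7))
  runs <- simulate_subject(gt, 1, depths = 0.1)
  expect_equal(vapply(runs, `[[`, character(1), "direction"),
               c("rising", "falling", "rising", "falling"))
})

test_that("sample residual correlations converge to the exponential covariance", {
  # two same-region vertices at 1 octave, lambda 1, rho0 0.8:
  # correlation must approach 0.8 * exp(-1) ~ 0.294
  sheet <- cortical_sheet(1, 3, depths = 0.1)
  lt <- rbind(data.frame(depth = 0.1, region = "core", lambda = 1),
              data.frame(depth = 0.1, region = "noncore", lambda = 1))
  gt <- make_ground_truth(sheet, stim, core_shape = c(1, 1), rho0 = 0.8,
                          noise_sd = 1, lambda_table = lt)
  gt$core_mask <- rep(FALSE, 3)
  gt$logf <- log(2^(c(0, 1, 2))) + log(250)   # 0, 1, 2 octaves apart
  L <- laminarifc:::noise_chol(gt, 0.1)
  set.seed(1)
  X <- t(L) %*% matrix(rnorm(3 * 1e5), 3)
  R <- cor(t(X))
  expect_equal(R[1, 2], 0.8 * exp(-1), tolerance = 0.02)
  expect_equal(R[1, 3], 0.8 * exp(-2), tolerance = 0.02)
  expect_equal(R[2, 3], 0.8 * exp(-1), tolerance = 0.02)
  # cross-region covariance is zero
  gt2 <- make_ground_truth(sheet, stim, core_shape = c(1, 1), rho0 = 0.8,
                           noise_sd = 1, lambda_table = lt)
  gt2$core_mask <- c(TRUE, FALSE, FALSE)
  gt2$logf <- gt$logf
  L2 <- laminarifc:::noise_chol(gt2, 0.1)
  C2 <- t(L2) %*% L2
  expect_equal(C2[1, 2], 0)
  expect_equal(C2[1, 3], 0)
})

test_that("subject SNR truth scales inversely with noise SD", {
  gt1 <- fix_world(noise_sd = 0.1, nrow = 4, ncol = 8, core_shape = c(2, 4))
  gt2 <- fix_world(noise_sd = 0.2, nrow = 4, ncol = 8, core_shape = c(2, 4))
  expect_equal(gt1$snr, 2 * gt2$snr)
  expect_true(all(gt1$snr > 0))
})
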