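stim <- fix_stim()
f_p <- stim$presentation_freq
tr <- stim$tr

test_that("regression removes the model exactly and orthogonalizes residuals", {
  tt <- (0:179) * tr
  model <- 1.3 * cos(2 * pi * f_p * tt + 0.7)
  res <- regress_out(rbind(model, model * 2), tr, f_p)
  expect_lt(max(abs(res$data)), 1e-10)
  set.seed(8)
  y <- matrix(rnorm(3 * 180), 3)
  r2 <- regress_out(y, tr, f_p)
  for (v in 1:3)
    expect_lt(abs(cor(r2$data[v, ], model)), 1e-10)
  # confound regression: WM-coupled signal is removed
  wm <- as.vector(arima.sim(list(ar = 0.9), 180))
  y3 <- y + rbind(0.5 * wm, 0.3 * wm, -0.4 * wm)
  r3 <- regress_out(y3, tr, f_p, confounds = cbind(wm = wm))
  for (v in 1:3)
    expect_lt(abs(cor(r3$data[v, ], wm)), 1e-10)
  expect_error(regress_out(y, tr, f_p, confounds = cbind(dup = model)),
               "collinear")
})

test_that("full-harmonic regression removes any block-periodic response", {
  gt <- fix_latency_gt(c(3, 9, 16), delay = 6)
  run <- simulate_run(gt, "rising", depth = 0.1)
  res <- regress_out(run$data, tr, f_p, n_harmonics = Inf)
  expect_lt(max(abs(res$data)), 1e-8)
  res1 <- regress_out(run$data, tr, f_p, n_harmonics = 1)
  expect_gt(max(abs(res1$data)), 0.01)   # harmonics survive the f_p-only model
})

test_that("bandpass keeps the presentation frequency and removes drift", {
  tt <- (0:719) * tr
  s_fp <- cos(2 * pi * f_p * tt)
  out <- bandpass(s_fp, tr)
  expect_equal(sd(out) / sd(s_fp), 1, tolerance = 0.05)
  drift <- cos(2 * pi * 0.001 * tt)
  expect_lt(sd(bandpass(drift, tr)) / sd(drift), 0.1)
  expect_error(bandpass(s_fp, tr, low = 0.05, high = 0.3), "Nyquist")
  # white-noise variance matches the spectral gain integral
  set.seed(10)
  n <- 720
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)
  gain <- ifelse(f == 0, 0, 1 / (1 + ((f^2 - 0.01 * 0.1) /
                                        (f * (0.1 - 0.01)))^(12)))
  frac <- mean(gain^2)
  v <- mean(replicate(60, var(bandpass(rnorm(n), tr))))
  expect_equal(v, frac, tolerance = 0.1)
})

test_that("pairwise iFC enumerates within-region pairs with octave deltas", {
  res <- diag(4) %*% matrix(rnorm(4 * 100), 4)
  feat <- log(c(500, 2000, 250, 4000))
  p <- pairwise_ifc(res, 1:4, feat)
  # pairs at >= 3 octaves (two at 3, one at 4) are dropped
  expect_equal(nrow(p), 3)
  expect_equal(p$delta[p$i == 1 & p$j == 2], 2)
  expect_true(all(p$delta < 3))
  # identical residual series correlate at one
  res2 <- rbind(res[1, ], res[1, ])
  p2 <- pairwise_ifc(res2, 1:2, c(6, 6.2))
  expect_equal(p2$r, 1)
  expect_error(pairwise_ifc(res, 2, feat), "two vertices")
})

test_that("binned curve averages through Fisher z and flags empty bins", {
  p1 <- data.frame(i = 1, j = 2, delta = 0.2, r = 0.5)
  c1 <- bin_curve(p1)
  expect_equal(c1$r[2], 0.5)
  expect_equal(c1$n_pairs, c(0, 1, 0, 0, 0))
  # tanh((atanh(0) + atanh(0.8)) / 2) = 0.5 exactly
  p2 <- data.frame(i = c(1, 1), j = c(2, 3), delta = c(0.2, 0.21),
                   r = c(0, 0.8))
  expect_equal(bin_curve(p2)$r[2], 0.5)
  # a bin of identical r returns exactly r (Fisher round trip)
  p3 <- data.frame(i = 1:3, j = 4:6, delta = c(1, 1.2, 1.4), r = 0.37)
  expect_equal(bin_curve(p3)$r[4], 0.37)
  expect_equal(bin_curve(p3, x_mode = "midpoint")$x[4], 1.125)
  expect_equal(bin_curve(p3)$x[4], 1.2)
})

test_that("exponential decay fit recovers generating parameters", {
  cv <- data.frame(x = c(0, 1, 2), r = 0.8 * exp(-1.5 * c(0, 1, 2)))
  fit <- fit_selectivity(cv)
  expect_equal(fit$R0, 0.8, tolerance = 1e-6)
  expect_equal(fit$lambda, 1.5, tolerance = 1e-6)
  flat <- data.frame(x = c(0, 0.5, 1, 2), r = rep(0.3, 4))
  ffit <- fit_selectivity(flat)
  expect_equal(ffit$lambda, 0, tolerance = 1e-8)
  expect_equal(ffit$R0, 0.3, tolerance = 1e-8)
  expect_error(fit_selectivity(data.frame(x = c(0, 1), r = c(1, 0.5))),
               "3 non-empty")
  # negative binned correlations are allowed
  neg <- data.frame(x = c(0, 1, 2, 3), r = c(0.4, 0.1, -0.05, -0.02))
  expect_true(fit_selectivity(neg)$converged)
})

test_that("Page L statistic: maximum, ties, and small-N exact p", {
  X <- matrix(rep(c(5, 4, 3, 2, 1), each = 20), 20)   # perfectly decreasing
  out <- pages_trend_test(X)
  expect_equal(out$L, 20 * sum((1:5)^2))
  expect_lt(out$p, 1e-10)
  tied <- matrix(1, 20, 5)
  out_t <- pages_trend_test(tied)
  expect_equal(out_t$L, 20 * 3 * 15)
  expect_equal(out_t$p, 0.5, tolerance = 0.01)
  expect_error(pages_trend_test(matrix(c(1, NA, 2, 3, 4, 5), 2)), "missing")
  # N = 3, k = 3: exact enumeration against a brute-force oracle
  set.seed(19)
  Y <- matrix(rnorm(9), 3, 3)
  out_e <- pages_trend_test(Y)
  expect_equal(out_e$method, "exact permutation")
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  cc <- 3:1
  ranks <- t(apply(Y, 1, rank))
  Ls <- c()
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    Ls <- c(Ls, sum(ranks[1, perms[i, ]] * cc) +
                 sum(ranks[2, perms[j, ]] * cc) +
                 sum(ranks[3, perms[k, ]] * cc))
  }
  expect_equal(out_e$p, mean(Ls >= out_e$L))
})

test_that("robustness preprocessing leaves clean-data selectivity unchanged", {
  lt <- rbind(data.frame(depth = 0.1, region = "core", lambda = 2),
              data.frame(depth = 0.1, region = "noncore", lambda = 1))
  gt <- fix_world(noise_sd = 0.1, lambda_table = lt, seed = 91,
                  nrow = 10, ncol = 20, core_shape = c(6, 10))
  runs <- simulate_subject(gt, 1, depths = 0.1, seed = 92)
  labels <- factor(ifelse(gt$core_mask, "core", "noncore"),
                   levels = c("core", "noncore", "outside"))
  a <- ifc_analysis(runs, stim, labels, feature = gt$logf)
  b <- ifc_analysis(runs, stim, labels, feature = gt$logf, preproc = "fig9")
  # single-subject comparison: same lambda up to the extra sampling noise
  # the bandpass dof reduction introduces
  expect_equal(b$core$fit$lambda, a$core$fit$lambda, tolerance = 0.3)
  expect_equal(b$noncore$fit$lambda, a$noncore$fit$lambda, tolerance = 0.3)
  expect_true(b$core$fit$converged && b$noncore$fit$converged)
})
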