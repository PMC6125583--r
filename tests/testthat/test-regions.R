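test_that("BH adjustment matches step-up enumeration and p.adjust", {
  p <- c(0.001, 0.02, 0.03, 0.8)
  adj <- adjust_fdr(p)
  expect_equal(adj, p.adjust(p, "BH"))
  expect_equal(sum(adj <= 0.05), 3)         # step-up rejects the first three
  expect_equal(adjust_fdr(0.03), 0.03)      # single p unchanged
  expect_equal(adjust_fdr(rep(0.2, 6)), rep(0.2, 6))
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  pr <- runif(50)
  expect_equal(adjust_fdr(pr), p.adjust(pr, "BH"))
})

test_that("Bonferroni adjustment caps at one", {
  expect_equal(adjust_bonferroni(0.01, 5), 0.05)
  expect_equal(adjust_bonferroni(0.5, 5), 1.0)
  expect_equal(adjust_bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
})

test_that("functional ROI thresholds mean z maps by one-tailed FDR", {
  z <- c(6, 5, 4, 0.2, -1, 0.1)
  roi <- functional_roi(z, q = 0.01)
  expect_equal(roi, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_warning(roi0 <- functional_roi(rep(-5, 4), q = 0.01), "empty")
  expect_equal(sum(roi0), 0)
  roi_all <- functional_roi(rep(50, 4), q = 0.01)
  expect_true(all(roi_all))
  # mask limits the family
  zm <- c(2.6, 2.6, 2.6, 2.6)
  expect_equal(functional_roi(zm, q = 0.01, mask = c(TRUE, TRUE, TRUE, FALSE)),
               c(adjust_fdr(rep(pnorm(2.6, lower.tail = FALSE), 3)) <= 0.01,
                 FALSE))
})

test_that("core definition keeps the largest connected sub-threshold patch", {
  sh <- cortical_sheet(9, 9)
  tw <- rep(1.9, 81)
  co <- sheet_coords(sh)
  patch <- co$row %in% 2:4 & co$col %in% 2:4
  tw[patch] <- 1.4
  lab <- define_core(tw, sh, threshold = 1.7)
  expect_equal(sum(lab == "core"), 9)
  expect_true(all(lab[patch] == "core"))
  # two patches: only the larger becomes core
  tw2 <- tw
  small <- co$row %in% 7:8 & co$col %in% 7:8
  tw2[small] <- 1.3
  lab2 <- define_core(tw2, sh, threshold = 1.7)
  expect_equal(sum(lab2 == "core"), 9)
  expect_true(all(lab2[small] == "noncore"))
  expect_error(define_core(rep(2, 81), sh), "below the tuning width threshold")
  # labels identical across depths by construction (single labeling reused)
  expect_s3_class(lab, "region_labels")
})

test_that("SNR-matched control ROI picks the nearest noncore vertices", {
  lab <- factor(c("core", "core", "core", rep("noncore", 5)),
                levels = c("core", "noncore", "outside"))
  snr <- c(100, 100, 100, 10, 90, 100, 110, 200)
  mask <- snr_matched_roi(lab, snr)
  expect_equal(which(mask), c(5, 6, 7))     # {90, 100, 110} around mean 100
  expect_equal(sum(mask), 3)
  # ties broken by vertex index
  snr2 <- c(100, 100, 100, rep(100, 5))
  expect_equal(which(snr_matched_roi(lab, snr2)), 4:6)
  expect_error(snr_matched_roi(lab, snr[-1]), "mismatch")
  expect_error(snr_matched_roi(lab, replace(snr, 5, NA)), "missing")
})

test_that("group core recovers the generative strip", {
  gt <- fix_world(n_subjects = 2, noise_sd = 0.1, delay_range = 5, seed = 31)
  stim <- fix_stim()
  tw_maps <- lapply(1:2, function(s) {
    runs <- simulate_subject(gt, s, depths = 0.1, seed = 300 + s)
    m <- map_subject(runs, stim)[["0.1"]]
    tuning_map(runs, stim, latency = m$latency)[["0.1"]]$tw_octaves
  })
  tw_mean <- smooth_on_sheet(rowMeans(do.call(cbind, tw_maps)), 5, gt$sheet)
  lab <- define_core(tw_mean, gt$sheet)
  jac <- sum(lab == "core" & gt$core_mask) /
    sum(lab == "core" | gt$core_mask)
  expect_gte(jac, 0.8)
})
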