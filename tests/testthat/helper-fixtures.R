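# shared fixtures, built in code (no stored data)

fix_stim <- function() chirp_stimulus()

# tiny noiseless world with chosen latencies on a 1 x n strip
fix_latency_gt <- function(latencies, delay, tw = 1, noise_sd = 0) {
  stim <- fix_stim()
  sheet <- cortical_sheet(1, length(latencies), depths = 0.1)
  gt <- make_ground_truth(sheet, stim, core_shape = c(1, 1),
                          noise_sd = noise_sd, delay_range = delay, seed = 1)
  gt$logf <- latency_to_log_frequency(latencies, stim)
  gt$tuning_width <- rep(tw, length(latencies))
  gt
}

# default-world ground truth at selected depths
fix_world <- function(n_subjects = 1, depths = 0.1, noise_sd = 0.1,
                      lambda_table = NULL, seed = 42, nrow = 20, ncol = 30,
                      ...) {
  stim <- fix_stim()
  sheet <- cortical_sheet(nrow, ncol, depths = depths)
  if (is.null(lambda_table)) lambda_table <- default_lambda_table(depths)
  make_ground_truth(sheet, stim, n_subjects = n_subjects,
                    lambda_table = lambda_table, noise_sd = noise_sd,
                    seed = seed, ...)
}
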