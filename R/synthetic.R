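#' Default per-depth, per-region iFC decay constants for the generator
#'
#' The generative lambda table emulates the qualitative finding the
#' pipeline is designed to detect: selectivity that is strongest in the
#' deep core and flat across depths in the noncore region.
#'
#' @param depths normalized depths.
#' @return data.frame with columns `depth`, `region`, `lambda` (1/octave).
#' @export
default_lambda_table <- function(depths = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  core <- approx(x = c(0.1, 0.9), y = c(2.0, 1.2), xout = depths)$y
  rbind(
    data.frame(depth = depths, region = "core", lambda = core),
    data.frame(depth = depths, region = "noncore", lambda = 1.0)
  )
}

#' Ground truth for a synthetic laminar experiment
#'
#' Builds the known truth every downstream stage is tested against:
#' a mirror-symmetric tonotopic gradient (a low-frequency band flanked
#' by two high-frequency bands along the column axis, spanning the full
#' chirp range), a contiguous narrowly tuned core strip, per-depth and
#' per-region residual decay constants, per-subject hemodynamic delays,
#' and the residual-noise model (SD, baseline correlation `rho0`).
#'
#' @param sheet a [cortical_sheet()].
#' @param stim a [chirp_stimulus()]; fixes the frequency range.
#' @param n_subjects number of synthetic subjects the truth serves.
#' @param core_shape `c(rows, cols)` of the centred core strip.
#' @param tw_core,tw_noncore true tuning widths (octaves FWHM) inside and
#'   outside the core strip.  `tw_core` must stay below the parcellation
#'   threshold (1.7 octaves) and `tw_noncore` above it.
#' @param lambda_table data.frame(depth, region, lambda): generative
#'   residual decay constants (1/octave).
#' @param noise_sd residual noise SD in units of the evoked peak amplitude.
#' @param rho0 baseline residual correlation at zero feature difference.
#' @param amplitude evoked peak amplitude (arbitrary signal units).
#' @param delay_range range (s) from which subject hemodynamic delays are
#'   drawn uniformly; a scalar fixes all delays.
#' @param seed integer seed (subject delays are the only random element).
#' @return An object of class `ground_truth`.
#' @export
make_ground_truth <- function(sheet, stim = chirp_stimulus(),
                              n_subjects = 1,
                              core_shape = c(10, 16),
                              tw_core = 1.4, tw_noncore = 1.9,
                              lambda_table = default_lambda_table(sheet$depths),
                              noise_sd = 0.1, rho0 = 0.6,
                              amplitude = 1, delay_range = c(3, 7),
                              seed = 1L) {
  stopifnot(tw_core > 0, tw_noncore > 0, noise_sd >= 0,
            rho0 > 0, rho0 <= 1, all(lambda_table$lambda > 0))
  if (core_shape[1] > sheet$n_rows || core_shape[2] > sheet$n_cols)
    stop("core strip larger than sheet")
  need <- expand.grid(depth = sheet$depths, region = c("core", "noncore"))
  have <- paste(lambda_table$depth, lambda_table$region)
  if (!all(paste(need$depth, need$region) %in% have))
    stop("lambda_table must cover every depth x region")

  co <- sheet_coords(sheet)
  # mirror-symmetric tonotopy: ln f is a V along columns, low at the centre
  centre <- (sheet$n_cols + 1) / 2
  dist <- abs(co$col - centre)
  # rescale so the gradient spans exactly [f_start, f_end] on any grid
  frac <- (dist - min(dist)) / (max(dist) - min(dist))
  logf <- log(stim$f_start) + frac * log(stim$f_end / stim$f_start)

  row0 <- floor((sheet$n_rows - core_shape[1]) / 2)
  col0 <- floor((sheet$n_cols - core_shape[2]) / 2)
  core <- co$row > row0 & co$row <= row0 + core_shape[1] &
          co$col > col0 & co$col <= col0 + core_shape[2]

  tw <- ifelse(core, tw_core, tw_noncore)

  set.seed(seed)
  delays <- if (length(delay_range) == 1) rep(delay_range, n_subjects)
            else runif(n_subjects, delay_range[1], delay_range[2])

  # per-vertex SNR truth: temporal mean of the evoked response over noise SD
  tt <- seq(0, stim$block_duration - stim$tr, by = stim$tr)
  fb <- chirp_frequency_at(tt, "rising", stim)
  sig2 <- (tw / (2 * sqrt(2 * log(2))))^2
  resp <- vapply(seq_along(tt), function(k) {
    if (is.na(fb[k])) return(rep(0, length(logf)))
    amplitude * exp(-(log2(fb[k]) - logf / log(2))^2 / (2 * sig2))
  }, numeric(length(logf)))
  snr <- if (noise_sd > 0) rowMeans(resp) / noise_sd else rep(Inf, length(logf))

  structure(list(
    sheet = sheet, stim = stim,
    logf = logf, tuning_width = tw, core_mask = core,
    lambda_table = lambda_table,
    n_subjects = n_subjects, delays = delays,
    noise_sd = noise_sd, rho0 = rho0, amplitude = amplitude,
    snr = snr, seed = seed,
    .cache = new.env(parent = emptyenv())
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d vertices (%d core), %d subjects, noise SD %g, rho0 %g\n",
              x$sheet$n_vertices, sum(x$core_mask), x$n_subjects,
              x$noise_sd, x$rho0))
  invisible(x)
}

#' Generative residual decay constant for a depth/region
#' @param gt a [make_ground_truth()] object.
#' @param depth normalized depth.
#' @param region `"core"` or `"noncore"`.
#' @return lambda (1/octave).
#' @export
true_lambda <- function(gt, depth, region) {
  lt <- gt$lambda_table
  hit <- abs(lt$depth - depth) < 1e-9 & lt$region == region
  if (!any(hit)) stop("no lambda for depth ", depth, " region ", region)
  lt$lambda[hit][1]
}

# Cholesky factor of the residual covariance at one depth.
# Cov(v, w) = sd^2 * rho0 * exp(-lambda(depth, region) * |dlog2 f|) within a
# region, sd^2 on the diagonal, 0 across regions.  Cached per depth on gt.
noise_chol <- function(gt, depth) {
  key <- sprintf("chol_%g", depth)
  if (!is.null(gt$.cache[[key]])) return(gt$.cache[[key]])
  n <- gt$sheet$n_vertices
  L <- matrix(0, n, n)
  oct <- gt$logf / log(2)
  for (reg in c("core", "noncore")) {
    idx <- which(if (reg == "core") gt$core_mask else !gt$core_mask)
    if (!length(idx)) next
    lam <- true_lambda(gt, depth, reg)
    D <- abs(outer(oct[idx], oct[idx], "-"))
    C <- gt$rho0 * exp(-lam * D)
    diag(C) <- 1
    Cc <- tryCatch(chol(C), error = function(e) {
      warning("covariance not positive definite; jittering diagonal by 1e-8")
      chol(C + diag(1e-8, length(idx)))
    })
    L[idx, idx] <- Cc
  }
  L <- gt$noise_sd * L
  gt$.cache[[key]] <- L
  L
}

# Noise-free evoked response matrix (vertices x timepoints) for one run.
# Gaussian tuning in log2 frequency around each vertex's preference,
# FWHM = its tuning width; zero during silence; delayed by a circular
# temporal shift of d seconds (the paradigm is periodic).
evoked_matrix <- function(gt, direction, delay, n_t = NULL) {
  stim <- gt$stim
  if (is.null(n_t))
    n_t <- round(stim$n_blocks_per_run * stim$block_duration / stim$tr)
  tt <- ((0:(n_t - 1)) * stim$tr - delay) %% stim$block_duration
  f <- chirp_frequency_at(tt, direction, stim)
  p_oct <- gt$logf / log(2)
  sig <- gt$tuning_width / (2 * sqrt(2 * log(2)))
  E <- matrix(0, gt$sheet$n_vertices, n_t)
  on <- which(!is.na(f))
  lf <- log2(f[on])
  for (k in seq_along(on))
    E[, on[k]] <- gt$amplitude * exp(-(lf[k] - p_oct)^2 / (2 * sig^2))
  E
}

# Nuisance series for one run: 6 slow "motion" random walks and one
# "white matter" series, unit-SD, smoothed white noise.
make_nuisance <- function(n_t) {
  sm <- function() {
    x <- cumsum(rnorm(n_t))
    x <- x - mean(x)
    x / max(stats::sd(x), 1e-12)
  }
  nu <- vapply(1:7, function(i) sm(), numeric(n_t))
  colnames(nu) <- c(paste0("motion", 1:6), "wm")
  nu
}

#' Simulate one BOLD run on the synthetic sheet
#'
#' Forward model: evoked Gaussian tuning response to the chirp (delayed
#' by the subject's hemodynamic delay, zero in silence, sampled at TR)
#' plus residual noise drawn i.i.d. over time from a zero-mean
#' multivariate normal whose vertex covariance decays exponentially with
#' the octave difference in preferred frequency, with region- and
#' depth-specific decay constants (zero across regions).  Optionally a
#' low-frequency drift and scaled copies of the nuisance series are
#' added; the nuisance records are always returned.
#'
#' @param gt a [make_ground_truth()] object.
#' @param direction `"rising"` or `"falling"`.
#' @param subject subject index in `1..gt$n_subjects`.
#' @param depth one of `gt$sheet$depths`.
#' @param run_id run label.
#' @param seed integer seed for noise, nuisance, drift.
#' @param drift_amp amplitude of an added low-frequency drift (0 = none).
#' @param nuisance_gain coupling of the motion/WM series into the data
#'   (0 = nuisance recorded but not injected).
#' @return An object of class `depth_run_series`: list with `data`
#'   (vertices x timepoints), `nuisance` (timepoints x 7), and metadata.
#' @export
simulate_run <- function(gt, direction, subject = 1, depth = gt$sheet$depths[1],
                         run_id = 1L, seed = 1L,
                         drift_amp = 0, nuisance_gain = 0) {
  stopifnot(subject >= 1, subject <= gt$n_subjects)
  if (!any(abs(gt$sheet$depths - depth) < 1e-9)) stop("unknown depth")
  stim <- gt$stim
  n_t <- round(stim$n_blocks_per_run * stim$block_duration / stim$tr)
  E <- evoked_matrix(gt, direction, gt$delays[subject], n_t)

  set.seed(seed)
  X <- if (gt$noise_sd > 0) {
    L <- noise_chol(gt, depth)
    E + t(L) %*% matrix(rnorm(gt$sheet$n_vertices * n_t), gt$sheet$n_vertices)
  } else E
  nu <- make_nuisance(n_t)
  tt <- (0:(n_t - 1)) * stim$tr
  if (drift_amp > 0) {
    ph <- runif(gt$sheet$n_vertices, 0, 2 * pi)
    sl <- rnorm(gt$sheet$n_vertices, 0, 1)
    dr <- outer(ph, 2 * pi * 0.002 * tt, function(p, w) cos(w + p)) +
      sl %o% (tt / max(tt) - 0.5)
    X <- X + drift_amp * dr
  }
  if (nuisance_gain > 0) {
    cf <- matrix(rnorm(gt$sheet$n_vertices * 7, 0, 1), ncol = 7)
    X <- X + nuisance_gain * (cf %*% t(nu))
  }
  structure(list(
    subject = subject, depth = depth, run_id = run_id,
    direction = direction, data = X, tr = stim$tr,
    nuisance = nu, stim = stim
  ), class = "depth_run_series")
}

#' Simulate the full 4-run session of one subject
#'
#' Two rising- and two falling-chirp runs at each requested depth,
#' following the block paradigm of `gt$stim`.
#'
#' @param gt a [make_ground_truth()] object.
#' @param subject subject index.
#' @param depths depths to simulate (default all in the sheet).
#' @param seed integer seed; per-run child seeds are derived from it.
#' @param ... passed to [simulate_run()] (`drift_amp`, `nuisance_gain`).
#' @return list of `depth_run_series`, one per run x depth.
#' @export
simulate_subject <- function(gt, subject = 1, depths = gt$sheet$depths,
                             seed = 1L, ...) {
  dirs <- c("rising", "falling", "rising", "falling")
  out <- list()
  k <- 0L
  for (d in depths) for (r in seq_along(dirs)) {
    k <- k + 1L
    out[[k]] <- simulate_run(gt, dirs[r], subject, d, run_id = r,
                             seed = derive_seed(seed, sprintf("s%d_d%g_r%d", subject, d, r)),
                             ...)
  }
  out
}
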