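#' Fourier component at the presentation frequency
#'
#' Amplitude and phase of a time series at the stimulus presentation
#' frequency, in the cosine convention: the returned pair `(a, phi)`
#' is the least-squares fit of `a * cos(2 pi f_p t + phi)` with
#' `t = (0, tr, 2 tr, ...)`.  `f_p` must be a harmonic of the series
#' length so the single-frequency fit is exact.
#'
#' @param ts numeric time series (one vertex) or matrix (vertices x time).
#' @param f_p presentation frequency (Hz).
#' @param tr sampling interval (s).
#' @return For a vector: list with `amplitude`, `phase` (radians in
#'   `[0, 2 pi)`), `f_p`.  For a matrix: data.frame with one row per vertex.
#' @export
fourier_component <- function(ts, f_p, tr) {
  mat <- is.matrix(ts)
  X <- if (mat) ts else matrix(ts, nrow = 1)
  n <- ncol(X)
  if (n * tr < 1 / f_p) stop("series shorter than one stimulus block")
  cyc <- f_p * n * tr
  if (abs(cyc - round(cyc)) > 1e-8)
    stop("f_p is not an exact harmonic of the series length")
  tt <- (0:(n - 1)) * tr
  e <- exp(-2i * pi * f_p * tt)
  Z <- X %*% e
  amp <- 2 * Mod(Z) / n
  phase <- wrap_2pi(Arg(Z))
  if (!mat) list(amplitude = amp[1], phase = phase[1], f_p = f_p)
  else data.frame(amplitude = as.vector(amp), phase = as.vector(phase))
}

#' Fisher z activation score of the sinusoidal model
#'
#' Builds the sinusoidal activation model
#' `model(t) = a * cos(2 pi f_p t + phi)` from a spectral component,
#' correlates it with the time series, and Fisher-transforms the Pearson
#' correlation: `z = atanh(r)`.  Perfect correlation is capped at
#' `atanh(1 - 1e-12)` for numerical safety.  A zero-variance series has
#' no defined correlation and returns `NA`.
#'
#' @param ts numeric time series.
#' @param comp component from [fourier_component()] (list with
#'   `amplitude`, `phase`).
#' @param f_p presentation frequency (Hz).
#' @param tr sampling interval (s).
#' @return Fisher z (atanh of r), `NA` if undefined.
#' @export
activation_zscore <- function(ts, comp, f_p, tr) {
  if (stats::sd(ts) == 0 || comp$amplitude == 0) return(NA_real_)
  tt <- (0:(length(ts) - 1)) * tr
  model <- comp$amplitude * cos(2 * pi * f_p * tt + comp$phase)
  fisher_z(stats::cor(model, ts))
}

#' Delay-cancelling phase average
#'
#' Combines the phases measured from rising- and falling-chirp runs,
#' `phi_avg = (phi_rc + 2 pi - phi_fc) / 2`, wrapped to `[0, 2 pi)`.
#' A hemodynamic delay adds the same phase lag to both run directions
#' but with opposite sign relative to the stimulus frequency axis, so it
#' cancels in this average while the response latency is retained.
#'
#' @param phi_rc,phi_fc phases (radians, wrapped) from rising- and
#'   falling-chirp runs; vectorised.
#' @return `phi_avg` in `[0, 2 pi)`.
#' @export
average_phase <- function(phi_rc, phi_fc) {
  wrap_2pi((wrap_2pi(phi_rc) + 2 * pi - wrap_2pi(phi_fc)) / 2)
}

#' Convert an averaged phase to a response latency
#'
#' `latency = phi_avg / (2 pi f_p)`, the linear transform from phase to
#' seconds within one stimulus block.
#'
#' @param phi_avg averaged phase, `[0, 2 pi)`.
#' @param f_p presentation frequency (Hz).
#' @return latency in `[0, 1/f_p)` seconds.
#' @export
phase_to_latency <- function(phi_avg, f_p) phi_avg / (2 * pi * f_p)

# Shared phase-encoded estimator.  Takes direction-averaged series
# (vertices x time) for rising and falling runs and returns the raw
# per-vertex maps.  The raw Eq.-2 latency sits on a shifted axis: in the
# cosine convention the delay-cancelled average of a response at latency
# L equals (block + chirp)/2 - L, because the falling chirp reverses the
# 20-s sweep while the 2*pi term corresponds to the full 30-s block.
# The constant (silence-induced) offset is removed here.
phase_encoded_maps <- function(rc, fc, stim) {
  f_p <- stim$presentation_freq
  tr <- stim$tr
  comp_rc <- fourier_component(rc, f_p, tr)
  comp_fc <- fourier_component(fc, f_p, tr)
  n_v <- nrow(rc)
  z_rc <- vapply(seq_len(n_v), function(v)
    activation_zscore(rc[v, ], list(amplitude = comp_rc$amplitude[v],
                                    phase = comp_rc$phase[v]), f_p, tr),
    numeric(1))
  z_fc <- vapply(seq_len(n_v), function(v)
    activation_zscore(fc[v, ], list(amplitude = comp_fc$amplitude[v],
                                    phase = comp_fc$phase[v]), f_p, tr),
    numeric(1))
  phi_avg <- average_phase(comp_rc$phase, comp_fc$phase)
  # standard-normal score of each direction's fit: the sinusoid has two
  # fitted degrees of freedom, so under the null R^2 ~ Beta(1, (n-3)/2)
  # and P(R > r) = (1 - r^2)^((n-3)/2); its normal quantile makes
  # z > 1.65 one-tailed p < 0.05 exactly
  n <- ncol(rc)
  z_std <- function(z_fisher) {
    r <- tanh(z_fisher)
    logp <- (n - 3) / 2 * log1p(-r^2)
    pmin(stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE), 40)
  }
  raw <- phase_to_latency(phi_avg, f_p)
  latency <- ((stim$block_duration + stim$chirp_duration) / 2 - raw) %%
    stim$block_duration
  logf <- latency_to_log_frequency(latency, stim)
  data.frame(vertex = seq_len(n_v),
             z_rc = z_rc, z_fc = z_fc,
             z_std_rc = z_std(z_rc), z_std_fc = z_std(z_fc),
             phi_avg = phi_avg, latency = latency, logf = logf)
}

#' Correct the truncation bias of phase-encoded latencies
#'
#' The first-harmonic phase of a response bump that is truncated by the
#' sweep boundaries (the silent tail, or the edges of the frequency
#' range) is pulled toward the centre of the remaining mass, so
#' phase-encoded latencies are systematically compressed toward
#' mid-sweep -- by up to ~0.6 octaves at the extremes for typical tuning
#' widths.  Because the bias is a deterministic function of the true
#' latency and the tuning width under the stimulus model, it can be
#' inverted: this computes the forward latency -> biased-latency mapping
#' from the block paradigm (per tuning width) and interpolates its
#' inverse at the observed latencies.
#'
#' @param latency observed (biased) latencies (s), `NA` allowed.
#' @param tw_octaves per-vertex tuning width estimates (octaves); values
#'   are grouped to a 0.05-octave grid to share forward mappings.
#' @param stim a [chirp_stimulus()].
#' @return debiased latencies, clamped to `[0, chirp_duration)`;
#'   `NA` where the inputs are `NA`.
#' @export
debias_latency <- function(latency, tw_octaves, stim) {
  stopifnot(length(latency) == length(tw_octaves))
  blen <- round(stim$block_duration / stim$tr)
  tb <- (0:(blen - 1)) * stim$tr
  on <- tb < stim$chirp_duration
  rate <- stim$octaves_per_second
  forward <- function(w) {
    # biased latency as a function of true latency for width w
    sig_t <- w / (2 * sqrt(2 * log(2))) / rate
    Lg <- seq(0, stim$chirp_duration, by = 0.05)
    bump <- function(centre) t(vapply(centre, function(L)
      ifelse(on, exp(-(tb - L)^2 / (2 * sig_t^2)), 0), numeric(blen)))
    m <- phase_encoded_maps(bump(Lg), bump(stim$chirp_duration - Lg), stim)
    list(true = Lg, biased = m$latency)
  }
  out <- rep(NA_real_, length(latency))
  ok <- !is.na(latency) & !is.na(tw_octaves) & latency < stim$chirp_duration
  wkey <- round(tw_octaves / 0.05) * 0.05
  for (w in unique(wkey[ok])) {
    sel <- ok & wkey == w
    map <- forward(max(w, 0.05))
    # the forward map is monotone; invert by interpolation, clamping
    # observations outside its range to the sweep endpoints
    inv <- stats::approx(map$biased, map$true, xout = latency[sel],
                         rule = 2, ties = "ordered")$y
    out[sel] <- pmin(pmax(inv, 0), stim$chirp_duration - 1e-9)
  }
  out
}

#' Phase-encoded feature maps for one subject
#'
#' The full phase-encoded procedure: runs of equal direction are
#' averaged timepoint-wise, the spectral component at the presentation
#' frequency is extracted per vertex, activation is scored per direction
#' as the model--data correlation converted to a standard-normal score
#' through the exact null distribution of the two-parameter sinusoid fit
#' (directions averaged for thresholding),
#' the rising/falling phases are combined by the delay-cancelling
#' average, and the resulting latency is converted to a log frequency
#' preference.  Vertices failing `z > z_threshold`, or whose latency
#' falls in the silent tail, are marked invalid.
#'
#' @param runs list of `depth_run_series` (from [simulate_run()] or
#'   equivalent); must contain at least one rising and one falling run
#'   per depth.
#' @param stim a [chirp_stimulus()].
#' @param z_threshold activation threshold on the standard z-score
#'   (default 1.65, one-tailed p < 0.05); `-Inf` keeps all vertices.
#' @return list of `activation_map` data.frames, one per depth (named by
#'   depth), with columns `vertex`, `z` (standard z), `phi_avg`,
#'   `latency`, `logf`, `valid`.
#' @export
map_subject <- function(runs, stim, z_threshold = 1.65) {
  out <- list()
  for (d in run_depths(runs)) {
    rc_runs <- runs_at(runs, d, "rising")
    fc_runs <- runs_at(runs, d, "falling")
    if (!length(rc_runs) || !length(fc_runs))
      stop("need at least one rising and one falling run at depth ", d)
    rc <- Reduce(`+`, lapply(rc_runs, `[[`, "data")) / length(rc_runs)
    fc <- Reduce(`+`, lapply(fc_runs, `[[`, "data")) / length(fc_runs)
    m <- phase_encoded_maps(rc, fc, stim)
    z <- (m$z_std_rc + m$z_std_fc) / 2
    valid <- !is.na(z) & z > z_threshold & !is.na(m$logf)
    am <- data.frame(vertex = m$vertex, z = z, phi_avg = m$phi_avg,
                     latency = m$latency, logf = m$logf, valid = valid)
    class(am) <- c("activation_map", class(am))
    out[[sprintf("%g", d)]] <- am
  }
  out
}
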