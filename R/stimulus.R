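#' Chirp stimulus paradigm
#'
#' Describes the block design used throughout the pipeline: a logarithmic
#' tone chirp sweeping `f_start` to `f_end` over `chirp_duration` seconds,
#' followed by `silence_duration` seconds of silence, repeated
#' `n_blocks_per_run` times per imaging run and sampled at `tr`.
#' The default is the four-octave 250--4000 Hz chirp: 20 s sweep + 10 s
#' silence, 15 blocks per run, TR = 2.5 s, giving a presentation
#' frequency of 1/30 Hz (printed as 0.033 Hz).
#'
#' @param f_start,f_end chirp start and end frequencies (Hz).
#' @param chirp_duration duration of the frequency sweep (s).
#' @param silence_duration duration of the silent tail (s).
#' @param n_blocks_per_run number of stimulus blocks per run.
#' @param tr repetition time of the BOLD sampling (s).
#' @return An object of class `chirp_stimulus`.
#' @examples
#' stim <- chirp_stimulus()
#' stim$presentation_freq   # 1/30 Hz
#' @export
chirp_stimulus <- function(f_start = 250, f_end = 4000,
                           chirp_duration = 20, silence_duration = 10,
                           n_blocks_per_run = 15, tr = 2.5) {
  stopifnot(f_start > 0, f_end > f_start, chirp_duration > 0,
            silence_duration >= 0, n_blocks_per_run >= 1, tr > 0)
  block <- chirp_duration + silence_duration
  structure(list(
    f_start = f_start, f_end = f_end,
    chirp_duration = chirp_duration, silence_duration = silence_duration,
    block_duration = block,
    n_blocks_per_run = n_blocks_per_run,
    tr = tr,
    presentation_freq = 1 / block,
    octave_span = log2(f_end / f_start),
    # octaves swept per second; the constant used for every
    # time <-> octave conversion in the package
    octaves_per_second = log2(f_end / f_start) / chirp_duration
  ), class = "chirp_stimulus")
}

#' @export
print.chirp_stimulus <- function(x, ...) {
  cat(sprintf(
    "chirp_stimulus: %g-%g Hz (%g oct) over %g s + %g s silence, %d blocks/run, TR %g s, f_p = %.4f Hz\n",
    x$f_start, x$f_end, x$octave_span, x$chirp_duration,
    x$silence_duration, x$n_blocks_per_run, x$tr, x$presentation_freq))
  invisible(x)
}

#' Instantaneous chirp frequency
#'
#' Frequency of the chirp at time `t` within a stimulus block.  The sweep
#' is logarithmic: rising chirps follow
#' `f(t) = f_start * (f_end/f_start)^(t/chirp_duration)`; falling chirps
#' are the time reverse of the rising sweep over the chirp window.  Times
#' in the silent tail return `NA` (the silence marker).
#'
#' @param t time within the block, in `[0, block_duration)` (s); vectorised.
#' @param direction `"rising"` or `"falling"`.
#' @param stim a [chirp_stimulus()].
#' @return Frequency in Hz, `NA` during silence.
#' @export
chirp_frequency_at <- function(t, direction = c("rising", "falling"),
                               stim = chirp_stimulus()) {
  direction <- match.arg(direction)
  if (any(t < 0 | t >= stim$block_duration))
    stop("t must lie in [0, block_duration)")
  tc <- if (direction == "rising") t else stim$chirp_duration - t
  f <- stim$f_start * (stim$f_end / stim$f_start)^(tc / stim$chirp_duration)
  f[t >= stim$chirp_duration] <- NA_real_
  f
}

#' Convert a response latency to a log frequency preference
#'
#' The phase-encoded analysis expresses frequency preference as the
#' response latency on the rising-chirp time axis.  This converts a
#' latency to the natural log of the chirp frequency presented at that
#' latency.  Latencies in the silent tail have no stimulus frequency and
#' are flagged invalid (`NA`), not raised as errors.
#'
#' @param latency response latency (s), in `[0, block_duration)`; vectorised.
#' @param stim a [chirp_stimulus()].
#' @return `ln(Hz)` preference, `NA` for silent-tail latencies.
#' @export
latency_to_log_frequency <- function(latency, stim = chirp_stimulus()) {
  if (any(latency < 0 | latency >= stim$block_duration, na.rm = TRUE))
    stop("latency must lie in [0, block_duration)")
  out <- rep(NA_real_, length(latency))
  ok <- !is.na(latency) & latency < stim$chirp_duration
  out[ok] <- log(stim$f_start) +
    (latency[ok] / stim$chirp_duration) * log(stim$f_end / stim$f_start)
  out
}
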