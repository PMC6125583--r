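#' Average a run into one stimulus block
#'
#' Segments a run into its stimulus blocks and averages them.  Falling
#' runs are reoriented onto the rising time axis by reversing each block
#' about the chirp window (`t -> chirp_duration - t`, modulo the block),
#' so that responses from both sweep directions line up on a common
#' frequency axis before any cross-direction averaging.
#'
#' @param ts numeric vector or matrix (vertices x time); length must be a
#'   multiple of the block length.
#' @param stim a [chirp_stimulus()]; `chirp_duration` must be a multiple
#'   of `tr` for the exact grid reversal.
#' @param direction `"rising"` or `"falling"`.
#' @return matrix (vertices x samples-per-block) of the averaged block,
#'   on the rising time axis.
#' @export
block_average <- function(ts, stim, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  X <- if (is.matrix(ts)) ts else matrix(ts, nrow = 1)
  blen <- round(stim$block_duration / stim$tr)
  if (ncol(X) %% blen != 0)
    stop("series length is not a multiple of the block length")
  nb <- ncol(X) %/% blen
  acc <- matrix(0, nrow(X), blen)
  for (b in seq_len(nb))
    acc <- acc + X[, ((b - 1) * blen + 1):(b * blen), drop = FALSE]
  avg <- acc / nb
  if (direction == "falling") {
    cd <- stim$chirp_duration / stim$tr
    if (abs(cd - round(cd)) > 1e-9)
      stop("chirp_duration must be a multiple of tr to reverse falling blocks")
    perm <- ((round(cd) - (0:(blen - 1))) %% blen) + 1
    avg <- avg[, perm, drop = FALSE]
  }
  avg
}

# robust 4-parameter Gaussian least squares: L-BFGS-B first, with a
# Nelder-Mead polish if the line search terminates abnormally
gauss_ls <- function(tt, y, p0, block_duration) {
  sse <- function(p) {
    g <- p[4] + p[1] * exp(-(tt - p[2])^2 / (2 * max(p[3], 1e-3)^2))
    sum((y - g)^2)
  }
  lower <- c(-Inf, -block_duration / 2, 1e-3, -Inf)
  upper <- c(Inf, 1.5 * block_duration, block_duration, Inf)
  fit <- tryCatch(
    stats::optim(p0, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    start <- if (!is.null(fit)) fit$par else p0
    fit <- tryCatch(
      stats::optim(start, sse, control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0) return(NULL)
    fit$par[3] <- min(max(fit$par[3], 1e-3), block_duration)
  }
  fit
}

#' Gaussian fit of a block-averaged response
#'
#' Least-squares fit of `b + A * exp(-(t - mu)^2 / (2 sigma^2))` to one
#' averaged block; the tuning width in seconds is the full width at half
#' maximum `2 sqrt(2 ln 2) * sigma`.  Because the block is one period of
#' a cyclic paradigm, the samples are first rotated so the peak sits at
#' the block centre (and the fitted centre rotated back), which keeps
#' responses wrapped across the block boundary fittable.
#' Initialisation is deterministic: `mu0` at the sample argmax,
#' `sigma0 = 2 tr`, `A0 = max - min`, `b0 = min`.
#'
#' @param block numeric vector, one averaged block (>= 6 samples).
#' @param tr sampling interval (s).
#' @param block_duration block length (s); defaults to `length(block) * tr`.
#' @param window_start,window_len optional response window (s): when
#'   given, only samples with `(t - window_start) mod block` inside
#'   `[0, window_len)` enter the fit.  Restricting the fit to the
#'   delay-shifted chirp window keeps silence samples (where no stimulus
#'   frequency exists) from being forced onto the Gaussian tails, which
#'   otherwise biases the width of edge-truncated responses.
#' @return list with `center` (s, in `[0, block_duration)`),
#'   `fwhm_seconds`, `r2`, `ok` (FALSE on non-convergence or a
#'   degenerate block).
#' @export
fit_gaussian_fwhm <- function(block, tr, block_duration = length(block) * tr,
                              window_start = NULL, window_len = NULL) {
  n <- length(block)
  if (n < 6) stop("need at least 6 samples")
  bad <- list(center = NA_real_, fwhm_seconds = NA_real_, r2 = NA_real_, ok = FALSE)
  if (stats::sd(block) == 0) return(bad)
  if (!is.null(window_start)) {
    if (is.null(window_len)) stop("window_len required with window_start")
    t_all <- (0:(n - 1)) * tr
    tau <- (t_all - window_start) %% block_duration
    keep <- tau < window_len
    if (sum(keep) < 6) keep <- rep(TRUE, n)  # window too short; fall back
    y <- block[keep][order(tau[keep])]
    tt <- sort(tau[keep])
    if (stats::sd(y) == 0) return(bad)
    mu0 <- tt[which.max(y)]
    p0 <- c(A = max(y) - min(y), mu = mu0, sigma = 2 * tr, b = min(y))
    fit <- gauss_ls(tt, y, p0, block_duration)
    if (is.null(fit)) return(bad)
    p <- fit$par
    return(list(center = (p[["mu"]] + window_start) %% block_duration,
                fwhm_seconds = 2 * sqrt(2 * log(2)) * p[["sigma"]],
                r2 = 1 - fit$value / sum((y - mean(y))^2), ok = TRUE))
  }
  rot <- which.max(block) - (n %/% 2 + 1)
  y <- block[((seq_len(n) - 1 + rot) %% n) + 1]  # peak moved to centre
  tt <- (0:(n - 1)) * tr
  mu0 <- tt[which.max(y)]
  p0 <- c(A = max(y) - min(y), mu = mu0, sigma = 2 * tr, b = min(y))
  fit <- gauss_ls(tt, y, p0, block_duration)
  if (is.null(fit)) return(bad)
  p <- fit$par
  r2 <- 1 - fit$value / sum((y - mean(y))^2)
  center <- (p[["mu"]] + rot * tr) %% block_duration
  list(center = center,
       fwhm_seconds = 2 * sqrt(2 * log(2)) * p[["sigma"]],
       r2 = r2, ok = TRUE)
}

#' Convert a temporal FWHM to octaves
#'
#' Under the logarithmic chirp, time within the sweep maps linearly to
#' octaves at the constant chirp rate (4 octaves / 20 s = 0.2 oct/s for
#' the default paradigm), so a temporal tuning width converts exactly.
#'
#' @param fwhm_seconds FWHM of the block-averaged response (s).
#' @param stim a [chirp_stimulus()].
#' @return tuning width in octaves.
#' @export
fwhm_to_octaves <- function(fwhm_seconds, stim = chirp_stimulus()) {
  stopifnot(all(fwhm_seconds >= 0, na.rm = TRUE))
  fwhm_seconds * stim$octaves_per_second
}

# Gaussian tuning fit for every vertex of a block-averaged matrix.
fit_tuning_block <- function(avg, stim, window_start = NULL) {
  out <- lapply(seq_len(nrow(avg)), function(v)
    fit_gaussian_fwhm(avg[v, ], stim$tr, stim$block_duration,
                      window_start = window_start,
                      window_len = if (is.null(window_start)) NULL
                                   else stim$chirp_duration))
  data.frame(
    vertex = seq_len(nrow(avg)),
    center = vapply(out, `[[`, numeric(1), "center"),
    fwhm_seconds = vapply(out, `[[`, numeric(1), "fwhm_seconds"),
    r2 = vapply(out, `[[`, numeric(1), "r2"),
    ok = vapply(out, `[[`, logical(1), "ok"))
}

#' Spectral tuning width map for one subject
#'
#' Per depth: blocks of each run direction are averaged (falling blocks
#' reoriented onto the rising axis), a Gaussian is fitted per vertex and
#' direction, and the FWHM in octaves is averaged across the two
#' directions.  Fitting per direction keeps the width estimate free of
#' the broadening that averaging the two delay-shifted directions
#' together would introduce.
#'
#' When `latency` (the delay-free phase-encoded latency map of the same
#' subject) is supplied, the subject's hemodynamic delay is estimated as
#' the circular average of (fitted center - latency) from a first-pass
#' fit, and the Gaussians are refitted inside the delay-shifted chirp
#' window so that silence samples do not bias edge-truncated responses.
#'
#' @param runs list of `depth_run_series`.
#' @param stim a [chirp_stimulus()].
#' @param latency optional per-vertex latency map (s) from
#'   [map_subject()], used for the response-window correction.
#' @return list of data.frames per depth with `vertex`, `tw_octaves`,
#'   `center`, `r2`, `valid`.
#' @export
tuning_map <- function(runs, stim, latency = NULL) {
  out <- list()
  for (d in run_depths(runs)) {
    avgs <- lapply(c(rising = "rising", falling = "falling"), function(dir) {
      rs <- runs_at(runs, d, dir)
      if (!length(rs)) stop("missing ", dir, " run at depth ", d)
      Reduce(`+`, lapply(rs, function(r)
        block_average(r$data, stim, dir))) / length(rs)
    })
    lat_d <- latency
    if (is.list(latency) && !is.data.frame(latency)) {
      lat_d <- latency[[sprintf("%g", d)]]
      if (is.data.frame(lat_d)) lat_d <- lat_d$latency
    }
    w0 <- list(rising = NULL, falling = NULL)
    if (!is.null(lat_d)) {
      latency_v <- lat_d
      first <- fit_tuning_block(avgs$rising, stim)
      ok <- first$ok & !is.na(latency_v)
      if (any(ok)) {
        # circular mean of center - latency on the block cycle
        ang <- 2 * pi * (first$center[ok] - latency_v[ok]) / stim$block_duration
        dhat <- (atan2(mean(sin(ang)), mean(cos(ang))) /
                   (2 * pi) * stim$block_duration) %% stim$block_duration
        w0$rising <- dhat
        # the reversed falling axis puts the chirp window at [-d, chirp - d]
        w0$falling <- (-dhat) %% stim$block_duration
      }
    }
    fits <- lapply(c("rising", "falling"), function(dir)
      fit_tuning_block(avgs[[dir]], stim, window_start = w0[[dir]]))
    ok <- fits[[1]]$ok & fits[[2]]$ok
    tw <- fwhm_to_octaves((fits[[1]]$fwhm_seconds + fits[[2]]$fwhm_seconds) / 2,
                          stim)
    out[[sprintf("%g", d)]] <- data.frame(
      vertex = fits[[1]]$vertex,
      tw_octaves = ifelse(ok, tw, NA_real_),
      center = fits[[1]]$center,
      r2 = (fits[[1]]$r2 + fits[[2]]$r2) / 2,
      valid = ok)
  }
  out
}
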