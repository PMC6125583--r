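#' Inter-subject variability map
#'
#' Vertex-wise standard deviation of a feature map across subjects,
#' using valid entries only; vertices with fewer than two valid subjects
#' are `NA`.
#'
#' @param maps list of per-subject data.frames holding the feature in
#'   column `value_col` and a logical `valid` column (as produced by
#'   [map_subject()] / [tuning_map()] for one depth).
#' @param value_col name of the feature column (e.g. `"logf"`,
#'   `"tw_octaves"`).
#' @return numeric vector of per-vertex SDs.
#' @export
inter_subject_sd <- function(maps, value_col) {
  stopifnot(length(maps) >= 2)
  M <- vapply(maps, function(m) {
    v <- m[[value_col]]
    v[!m$valid] <- NA_real_
    v
  }, numeric(nrow(maps[[1]])))
  apply(M, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x)
  })
}

# collect the individual stimulus blocks of every run of one direction:
# returns a 3-D array (vertices x samples-per-block x blocks), falling
# blocks reoriented onto the rising axis
collect_blocks <- function(runs, stim, direction) {
  rs <- runs_at(runs, direction = direction)
  if (!length(rs)) stop("no ", direction, " runs")
  blen <- round(stim$block_duration / stim$tr)
  pieces <- list()
  for (r in rs) {
    nb <- ncol(r$data) %/% blen
    for (b in seq_len(nb)) {
      blk <- r$data[, ((b - 1) * blen + 1):(b * blen), drop = FALSE]
      if (direction == "falling") {
        cd <- round(stim$chirp_duration / stim$tr)
        blk <- blk[, ((cd - (0:(blen - 1))) %% blen) + 1, drop = FALSE]
      }
      pieces[[length(pieces) + 1]] <- blk
    }
  }
  array(unlist(pieces), dim = c(nrow(pieces[[1]]), blen, length(pieces)))
}

# estimate preference and tuning width from one half-set of blocks.
# rc/fc: vertices x samples x blocks arrays already on the rising axis
# for tuning; the phase step needs the falling blocks in their original
# orientation, so those are passed separately.
estimate_half <- function(rc_orig, fc_orig, stim) {
  rc_avg <- apply(rc_orig, c(1, 2), mean)
  fc_avg <- apply(fc_orig, c(1, 2), mean)
  pm <- phase_encoded_maps(rc_avg, fc_avg, stim)
  cd <- round(stim$chirp_duration / stim$tr)
  blen <- ncol(rc_avg)
  fc_rev <- fc_avg[, ((cd - (0:(blen - 1))) %% blen) + 1, drop = FALSE]
  tw <- (fwhm_to_octaves(fit_tuning_block(rc_avg, stim)$fwhm_seconds, stim) +
         fwhm_to_octaves(fit_tuning_block(fc_rev, stim)$fwhm_seconds, stim)) / 2
  list(logf = pm$logf, tw = tw)
}

#' Intra-subject (split-half) variability maps
#'
#' Repeatedly splits one subject's stimulus blocks into two halves, each
#' holding half the rising and half the falling blocks, estimates the
#' frequency preference and tuning width in each half, and takes the
#' vertex-wise SD across the `2 * n_repeats` estimates.  Splits are over
#' block identity (complementary halves), so the measure is invariant to
#' block ordering.  Vertices with fewer than `min_valid` valid estimates
#' are `NA`.
#'
#' @param runs all runs of one subject at one depth (2 rising + 2
#'   falling for the standard session).
#' @param stim a [chirp_stimulus()].
#' @param n_repeats number of random splits (default 20).
#' @param seed integer seed for the splits.
#' @param min_valid minimum valid estimates out of `2 * n_repeats`
#'   (default three quarters, i.e. 30 of 40 at the standard 20 repeats).
#' @return list with per-vertex `logf_sd` (ln Hz) and `tw_sd` (octaves).
#' @export
intra_subject_sd <- function(runs, stim, n_repeats = 20, seed = 1L,
                             min_valid = ceiling(1.5 * n_repeats)) {
  rc <- collect_blocks(runs, stim, "rising")
  # falling blocks in original orientation for the phase estimate
  rs_fc <- runs_at(runs, direction = "falling")
  if (!length(rs_fc)) stop("no falling runs")
  blen <- round(stim$block_duration / stim$tr)
  fc_pieces <- list()
  for (r in rs_fc) {
    nb <- ncol(r$data) %/% blen
    for (b in seq_len(nb))
      fc_pieces[[length(fc_pieces) + 1]] <-
        r$data[, ((b - 1) * blen + 1):(b * blen), drop = FALSE]
  }
  fc <- array(unlist(fc_pieces), dim = c(nrow(fc_pieces[[1]]), blen,
                                         length(fc_pieces)))
  n_rc <- dim(rc)[3]; n_fc <- dim(fc)[3]
  if (n_rc < 2 || n_fc < 2) stop("not enough blocks for a split")
  set.seed(seed)
  est_logf <- list(); est_tw <- list()
  for (rep_i in seq_len(n_repeats)) {
    half_rc <- sample(n_rc, n_rc %/% 2)
    half_fc <- sample(n_fc, n_fc %/% 2)
    for (half in 1:2) {
      i_rc <- if (half == 1) half_rc else setdiff(seq_len(n_rc), half_rc)
      i_fc <- if (half == 1) half_fc else setdiff(seq_len(n_fc), half_fc)
      e <- estimate_half(rc[, , i_rc, drop = FALSE],
                         fc[, , i_fc, drop = FALSE], stim)
      est_logf[[length(est_logf) + 1]] <- e$logf
      est_tw[[length(est_tw) + 1]] <- e$tw
    }
  }
  sd_min <- function(lst) {
    M <- do.call(cbind, lst)
    apply(M, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < min_valid) NA_real_ else stats::sd(x)
    })
  }
  list(logf_sd = sd_min(est_logf), tw_sd = sd_min(est_tw))
}
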