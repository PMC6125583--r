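#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, the family size
#' being the length of `p` (the number of vertices in the anatomical
#' mask for map thresholding, or the number of comparison pairs for
#' post-hoc tests).
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Bonferroni adjusted p-values
#'
#' @param p raw p-values.
#' @param m family size (default `length(p)`).
#' @return `min(1, p * m)`.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Functional ROI from group activation maps
#'
#' Vertices whose across-subject mean standard z-score survives
#' one-tailed Benjamini-Hochberg FDR thresholding at level `q` within
#' the anatomical mask (which fixes the multiple-testing family size).
#'
#' @param z matrix (subjects x vertices) of standard z-scores, or a
#'   single mean z vector.
#' @param q FDR level (default 0.01).
#' @param mask logical vector: the anatomical mask (default all vertices).
#' @return logical vertex mask of the functional ROI.
#' @export
functional_roi <- function(z, q = 0.01, mask = NULL) {
  zb <- if (is.matrix(z)) colMeans(z, na.rm = TRUE) else z
  if (is.null(mask)) mask <- rep(TRUE, length(zb))
  stopifnot(length(mask) == length(zb))
  roi <- logical(length(zb))
  idx <- which(mask & !is.na(zb))
  if (length(idx)) {
    p <- stats::pnorm(zb[idx], lower.tail = FALSE)
    roi[idx] <- adjust_fdr(p) <= q
  }
  if (!any(roi)) warning("functional ROI is empty")
  roi
}

# label 4-connected components of a logical mask on the sheet grid;
# returns an integer vector (0 = background), components numbered
# arbitrarily but deterministically (scan order)
connected_components <- function(mask, sheet) {
  nr <- sheet$n_rows; nc <- sheet$n_cols
  m <- matrix(mask, nr, nc, byrow = TRUE)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue)) {
      q1 <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- q1[1] + dd[1]; nj <- q1[2] + dd[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  as.integer(t(lab))
}

#' Core/noncore parcellation from the mean tuning width map
#'
#' The core is the largest spatially continuous (4-connected) patch of
#' vertices whose mean tuning width falls below the threshold; the
#' noncore is the remainder of the functional ROI.  The parcellation is
#' defined once at group level (mean map across subjects and depths) and
#' applied identically at every depth.
#'
#' @param tw mean tuning width map (octaves), one value per vertex.
#' @param sheet a [cortical_sheet()].
#' @param threshold tuning width threshold in octaves (default 1.7).
#' @param roi logical functional-ROI mask (default all vertices).
#' @return An object of class `region_labels`: factor vector with levels
#'   `core`, `noncore`, `outside`, plus provenance attributes.
#' @export
define_core <- function(tw, sheet, threshold = 1.7, roi = NULL) {
  stopifnot(length(tw) == sheet$n_vertices)
  if (is.null(roi)) roi <- rep(TRUE, sheet$n_vertices)
  narrow <- !is.na(tw) & tw < threshold & roi
  if (!any(narrow)) stop("no vertex below the tuning width threshold")
  cc <- connected_components(narrow, sheet)
  sizes <- tabulate(cc)
  biggest <- which.max(sizes)  # ties: lowest label = first in scan order
  core <- cc == biggest
  lab <- factor(ifelse(core, "core", ifelse(roi, "noncore", "outside")),
                levels = c("core", "noncore", "outside"))
  structure(lab, class = c("region_labels", "factor"),
            threshold = threshold, core_size = sizes[biggest])
}

#' SNR-matched noncore control ROI
#'
#' Selects exactly as many noncore vertices as there are core vertices,
#' greedily minimising the distance between each vertex's SNR and the
#' mean core SNR (ties broken by vertex index).  Used to check that
#' core/noncore iFC differences are not an SNR artefact.
#'
#' @param labels a `region_labels` vector from [define_core()].
#' @param snr per-vertex SNR values.
#' @return logical vertex mask with `sum(mask) == #core`.
#' @export
snr_matched_roi <- function(labels, snr) {
  if (length(snr) != length(labels)) stop("SNR vector length mismatch")
  core <- which(labels == "core")
  noncore <- which(labels == "noncore")
  if (any(is.na(snr[c(core, noncore)]))) stop("SNR missing for ROI vertices")
  if (length(noncore) < length(core)) stop("fewer noncore than core vertices")
  target <- mean(snr[core])
  ord <- noncore[order(abs(snr[noncore] - target), noncore)]
  mask <- logical(length(labels))
  mask[ord[seq_along(core)]] <- TRUE
  mask
}
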