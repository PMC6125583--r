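#' Synthetic cortical sheet
#'
#' A regular 2-D vertex grid standing in for a flattened cortical patch,
#' replicated (with identical vertex indexing) at a set of normalized
#' cortical depths.  Vertices are indexed row-major:
#' `v = (row - 1) * n_cols + col`.  Neighbourhood structure is the
#' 4-neighbourhood of the grid; spacing is isotropic in mm.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param spacing_mm distance between neighbouring vertices (mm).
#'   Default 1.5 mm, matching a typical high-resolution EPI voxel.
#' @param depths normalized cortical depths (0 = white matter boundary,
#'   1 = pial surface).
#' @return An object of class `cortical_sheet`.
#' @export
cortical_sheet <- function(n_rows = 20, n_cols = 30, spacing_mm = 1.5,
                           depths = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  stopifnot(n_rows >= 1, n_cols >= 1, spacing_mm > 0,
            all(depths > 0 & depths < 1))
  structure(list(
    n_rows = n_rows, n_cols = n_cols,
    n_vertices = n_rows * n_cols,
    spacing_mm = spacing_mm,
    depths = depths
  ), class = "cortical_sheet")
}

#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("cortical_sheet: %d x %d grid (%d vertices), %g mm spacing, depths {%s}\n",
              x$n_rows, x$n_cols, x$n_vertices, x$spacing_mm,
              paste(x$depths, collapse = ", ")))
  invisible(x)
}

#' Row/column coordinates of sheet vertices
#'
#' @param sheet a [cortical_sheet()].
#' @param v vertex indices (default all).
#' @return data.frame with columns `vertex`, `row`, `col`.
#' @export
sheet_coords <- function(sheet, v = seq_len(sheet$n_vertices)) {
  data.frame(vertex = v,
             row = (v - 1L) %/% sheet$n_cols + 1L,
             col = (v - 1L) %% sheet$n_cols + 1L)
}

#' 4-neighbourhood edge list of the sheet
#'
#' @param sheet a [cortical_sheet()].
#' @return two-column integer matrix of undirected edges (i < j),
#'   symmetric by construction, no self-edges.
#' @export
sheet_adjacency <- function(sheet) {
  nr <- sheet$n_rows; nc <- sheet$n_cols
  idx <- matrix(seq_len(nr * nc), nrow = nr, ncol = nc, byrow = TRUE)
  horiz <- cbind(as.vector(idx[, -nc, drop = FALSE]),
                 as.vector(idx[, -1, drop = FALSE]))
  vert <- cbind(as.vector(idx[-nr, , drop = FALSE]),
                as.vector(idx[-1, , drop = FALSE]))
  edges <- rbind(horiz, vert)
  edges[edges[, 1] > edges[, 2], ] <- edges[edges[, 1] > edges[, 2], 2:1]
  storage.mode(edges) <- "integer"
  edges
}

#' Gaussian smoothing of a vertex map along the sheet
#'
#' 2-D Gaussian convolution on the grid with
#' `sigma = fwhm / (2 sqrt(2 ln 2))`, the discrete analogue of
#' surface-based smoothing of cortical maps.  At the sheet boundary the
#' truncated kernel is rebalanced by a symmetric (Sinkhorn) scaling so
#' that the smoothing matrix is doubly stochastic: constants map to the
#' same constant and the total mass (hence the mean) of a complete map
#' is preserved exactly.  `NA` vertices are excluded from the kernel
#' support; their value does not leak into neighbours and they stay `NA`.
#'
#' @param x numeric vector of length `sheet$n_vertices` (may contain `NA`).
#' @param fwhm_mm kernel full width at half maximum (mm); 0 is the identity.
#' @param sheet a [cortical_sheet()].
#' @return smoothed map, same length and `NA` pattern as `x`.
#' @export
smooth_on_sheet <- function(x, fwhm_mm, sheet) {
  stopifnot(fwhm_mm >= 0, length(x) == sheet$n_vertices)
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / sheet$spacing_mm  # in grid units
  rad <- max(1L, ceiling(3 * sigma))
  off <- -rad:rad
  k1 <- exp(-off^2 / (2 * sigma^2))
  K <- outer(k1, k1)  # separable 2-D kernel, unnormalized

  nr <- sheet$n_rows; nc <- sheet$n_cols
  m <- matrix(x, nrow = nr, ncol = nc, byrow = TRUE)
  w <- !is.na(m)
  mf <- m; mf[!w] <- 0

  # masked convolution: (K * (valid-restricted y)) at every vertex
  convK <- function(y) {
    out <- matrix(0, nr, nc)
    for (di in off) for (dj in off) {
      kw <- K[di + rad + 1, dj + rad + 1]
      si <- max(1, 1 - di):min(nr, nr - di)  # target rows
      sj <- max(1, 1 - dj):min(nc, nc - dj)
      out[si, sj] <- out[si, sj] + kw * y[si + di, sj + dj]
    }
    out
  }

  # symmetric Sinkhorn balancing of the valid-vertex kernel matrix
  u <- matrix(0, nr, nc)
  u[w] <- 1 / sqrt(sum(K))
  for (it in seq_len(200)) {
    Ku <- convK(u)
    resid <- max(abs(u[w] * Ku[w] - 1))
    if (resid < 1e-13) break
    u[w] <- sqrt(u[w] / Ku[w])
  }
  out <- u * convK(u * mf)
  out[!w] <- NA_real_
  as.vector(t(out))
}
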