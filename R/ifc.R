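#' Regress the activation model (and confounds) out of a run
#'
#' Ordinary least-squares residuals of every vertex time series on an
#' intercept, the sinusoidal activation model at the presentation
#' frequency (spanned phase-free by a cosine/sine pair, so one design
#' serves all vertices), and any confound columns (e.g. six motion
#' regressors and a white-matter regressor).  Residuals are exactly
#' orthogonal to every regressor.
#'
#' With `n_harmonics = 1` only the fundamental (the sinusoidal model
#' itself) is removed; `n_harmonics = Inf` removes every harmonic of
#' `f_p` up to Nyquist, i.e. the entire block-periodic evoked response.
#' The iFC stage uses the full harmonic set by default: residuals then
#' contain no stimulus-locked component, so their correlation reflects
#' intrinsic covariance rather than shared response shape.
#'
#' @param ts matrix (vertices x time).
#' @param tr sampling interval (s).
#' @param f_p presentation frequency (Hz); `NULL` omits the activation pair.
#' @param confounds optional matrix (time x k) of confound series.
#' @param n_harmonics number of harmonics of `f_p` in the design
#'   (default 1 = the sinusoidal model only; `Inf` = all up to Nyquist).
#' @return list of class `residual_series`: `data` (vertices x time),
#'   `design`, `provenance`.
#' @export
regress_out <- function(ts, tr, f_p, confounds = NULL, n_harmonics = 1) {
  n <- ncol(ts)
  tt <- (0:(n - 1)) * tr
  harm <- NULL
  if (!is.null(f_p)) {
    kmax <- min(n_harmonics, floor(1 / (2 * tr) / f_p))
    for (k in seq_len(kmax)) {
      pair <- cbind(cos(2 * pi * k * f_p * tt), sin(2 * pi * k * f_p * tt))
      colnames(pair) <- paste0(c("act_cos", "act_sin"), k)
      pair <- pair[, sqrt(colSums(pair^2)) > 1e-8, drop = FALSE]  # sin at Nyquist
      harm <- cbind(harm, pair)
    }
  }
  X <- cbind(intercept = 1, harm, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; collinear columns: ", paste(drop, collapse = ", "))
  }
  Q <- qr.Q(qrX)
  res <- ts - (ts %*% Q) %*% t(Q)
  structure(list(data = res, design = X,
                 provenance = list(f_p = f_p,
                                   n_confounds = if (is.null(confounds)) 0
                                                 else ncol(confounds))),
            class = "residual_series")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Frequency-domain implementation of a forward-backward (zero-phase)
#' Butterworth bandpass: each series is multiplied in the Fourier domain
#' by the squared magnitude response of an order-`order` Butterworth
#' bandpass, which is exactly the net gain of filtfilt-style
#' forward-backward application (effective order doubled, phase zero).
#'
#' @param ts matrix (vertices x time) or vector.
#' @param tr sampling interval (s).
#' @param low,high band edges (Hz); must satisfy
#'   `0 < low < high < 1/(2 tr)`.
#' @param order filter order (default 6).
#' @return filtered series, same shape as `ts`.
#' @export
bandpass <- function(ts, tr, low = 0.01, high = 0.1, order = 6) {
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq))
    stop("band must satisfy 0 < low < high < Nyquist")
  X <- if (is.matrix(ts)) ts else matrix(ts, nrow = 1)
  n <- ncol(X)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)
  gain <- ifelse(f == 0, 0,
                 1 / (1 + ((f^2 - low * high) / (f * (high - low)))^(2 * order)))
  Y <- stats::mvfft(t(X)) * gain
  out <- t(Re(stats::mvfft(Y, inverse = TRUE)) / n)
  if (is.matrix(ts)) out else as.vector(out)
}

#' Within-region residual correlation pairs
#'
#' All unordered pairs of valid vertices inside one region at one depth,
#' with the Pearson correlation of their residual series and their
#' feature difference in octaves: `|log2(f1/f2)|` for frequency
#' preference (features given in ln Hz) or `|log2(w1/w2)|` for tuning
#' width (features given in octaves).  Pairs at or beyond `max_delta`
#' octaves are dropped.
#'
#' @param res matrix (vertices x time) of residuals (runs concatenated),
#'   or a `residual_series`.
#' @param vertices integer indices of the region's valid vertices.
#' @param feature per-vertex feature values (full-length vector).
#' @param feature_scale `"ln"` (feature in ln Hz) or `"log2"` (feature
#'   already a log2-scale quantity, e.g. tuning width passed as
#'   `log2(tw)`), controlling the octave conversion.
#' @param max_delta pairs with `delta >= max_delta` octaves are excluded
#'   (default 3).
#' @return data.frame with `i`, `j`, `delta` (octaves), `r`.
#' @export
pairwise_ifc <- function(res, vertices, feature, feature_scale = c("ln", "log2"),
                         max_delta = 3) {
  feature_scale <- match.arg(feature_scale)
  if (inherits(res, "residual_series")) res <- res$data
  if (length(vertices) < 2) stop("need at least two vertices in the region")
  fv <- feature[vertices]
  if (any(is.na(fv))) stop("feature missing for some region vertices")
  oct <- if (feature_scale == "ln") fv / log(2) else fv
  R <- stats::cor(t(res[vertices, , drop = FALSE]))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  delta <- abs(oct[ut[, 1]] - oct[ut[, 2]])
  keep <- delta < max_delta
  data.frame(i = vertices[ut[keep, 1]], j = vertices[ut[keep, 2]],
             delta = delta[keep], r = R[ut[keep, , drop = FALSE]])
}

#' Default iFC bin edges (octaves)
#' @return the five-bin edge vector `c(0, 0.1875, 0.375, 0.75, 1.5, 3)`.
#' @export
ifc_bin_edges <- function() c(0, 0.1875, 0.375, 0.75, 1.5, 3)

#' Bin a pair list into a feature-difference iFC curve
#'
#' Half-open bins `[e_i, e_{i+1})`; per-bin correlations are averaged
#' through the Fisher z transform (transform, mean, back-transform).
#' Empty bins are flagged and later excluded from the decay fit.
#'
#' @param pairs data.frame from [pairwise_ifc()].
#' @param edges bin edges in octaves (default [ifc_bin_edges()]).
#' @param x_mode bin representative for fitting: `"pair_mean"`, the mean
#'   delta of the pairs in the bin (default; unbiased when the within-bin
#'   delta mass is uneven, as on a locally quantized tonotopy), or
#'   `"midpoint"` of the bin.
#' @return object of class `ifc_curve`: data.frame with `bin`, `x`,
#'   `r`, `n_pairs`.
#' @export
bin_curve <- function(pairs, edges = ifc_bin_edges(),
                      x_mode = c("pair_mean", "midpoint")) {
  x_mode <- match.arg(x_mode)
  if (!nrow(pairs)) stop("no pairs to bin")
  bin <- cut(pairs$delta, edges, right = FALSE, labels = FALSE)
  nb <- length(edges) - 1
  r <- n_pairs <- xm <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    sel <- which(bin == b)
    n_pairs[b] <- length(sel)
    if (length(sel)) {
      r[b] <- fisher_z_inv(mean(fisher_z(pairs$r[sel])))
      xm[b] <- mean(pairs$delta[sel])
    }
  }
  x <- if (x_mode == "midpoint") (edges[-length(edges)] + edges[-1]) / 2 else xm
  structure(data.frame(bin = seq_len(nb), x = x, r = r, n_pairs = n_pairs),
            class = c("ifc_curve", "data.frame"), edges = edges, x_mode = x_mode)
}

#' Fit the exponential decay selectivity model
#'
#' Nonlinear least squares of `y = R0 * exp(-lambda * x)` to the binned
#' curve, `lambda` constrained non-negative.  Fitting starts from the
#' log-linear solution where the curve is positive, else from a flat
#' initialisation, with an `optim` fallback if `nls` fails to converge.
#'
#' @param curve an `ifc_curve` (or data.frame with `x`, `r`); at least 3
#'   non-empty bins required.
#' @return list with `R0`, `lambda`, `converged`, and `diagnostic` when
#'   not converged.
#' @export
fit_selectivity <- function(curve) {
  ok <- !is.na(curve$r) & !is.na(curve$x)
  x <- curve$x[ok]; y <- curve$r[ok]
  if (length(x) < 3) stop("need at least 3 non-empty bins")
  init <- if (all(y > 0)) {
    cf <- stats::coef(stats::lm(log(y) ~ x))
    c(R0 = exp(unname(cf[1])), lambda = max(0, -unname(cf[2])))
  } else c(R0 = y[1], lambda = 0.5)
  fit <- tryCatch(
    stats::nls(y ~ R0 * exp(-lambda * x),
               start = as.list(init), algorithm = "port",
               lower = c(R0 = -Inf, lambda = 0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    return(list(R0 = unname(p["R0"]), lambda = unname(p["lambda"]),
                converged = TRUE))
  }
  sse <- function(p) sum((y - p[1] * exp(-p[2] * x))^2)
  o <- stats::optim(init, sse, method = "L-BFGS-B", lower = c(-Inf, 0),
                    control = list(factr = 1e4, maxit = 1000))
  if (o$convergence == 0)
    list(R0 = unname(o$par[1]), lambda = unname(o$par[2]), converged = TRUE)
  else
    list(R0 = NA_real_, lambda = NA_real_, converged = FALSE,
         diagnostic = o$message)
}

#' Page's trend test for a monotone ordering of related conditions
#'
#' Rank-based test of a hypothesized monotone trend across `k` related
#' conditions (bins) measured in `N` subjects.  Values are ranked within
#' each subject (ties get average ranks) and
#' `L = sum_j c_j R_j`, with `c_j` the hypothesized rank of condition
#' `j` (`k..1` for a decreasing trend).  For `N >= 12` the one-sided p
#' comes from the normal approximation
#' `L ~ N(N k (k+1)^2 / 4, N k^2 (k+1)^2 (k-1) / 144)`; for smaller `N`
#' from exact enumeration of within-subject permutations when feasible
#' (`(k!)^N <= 2e5`), otherwise from seeded Monte-Carlo permutation.
#'
#' @param X matrix (subjects x conditions), no missing cells.
#' @param decreasing TRUE tests for a decreasing trend over columns.
#' @param n_perm Monte-Carlo permutations for small N (default 10000).
#' @param seed seed for the Monte-Carlo branch.
#' @return list with `L`, `p`, `method`.
#' @export
pages_trend_test <- function(X, decreasing = TRUE, n_perm = 10000, seed = 1L) {
  X <- as.matrix(X)
  if (any(is.na(X))) stop("missing cells are not allowed")
  N <- nrow(X); k <- ncol(X)
  if (k < 3) stop("need at least 3 conditions")
  cc <- if (decreasing) k:1 else 1:k
  Lstat <- function(M) sum(t(apply(M, 1, rank)) %*% cc)
  L <- Lstat(X)
  if (N >= 12) {
    mu <- N * k * (k + 1)^2 / 4
    v <- N * k^2 * (k + 1)^2 * (k - 1) / 144
    p <- stats::pnorm((L - mu) / sqrt(v), lower.tail = FALSE)
    return(list(L = L, p = p, method = "normal approximation"))
  }
  if (factorial(k)^N <= 2e5) {
    perms <- all_permutations(k)
    idx <- rep(1L, N)
    total <- nrow(perms)^N
    count <- 0L
    # enumerate all assignments of a permutation per subject
    grid <- expand.grid(rep(list(seq_len(nrow(perms))), N))
    ranks <- t(apply(X, 1, rank))
    for (g in seq_len(nrow(grid))) {
      Lg <- sum(vapply(seq_len(N), function(s)
        sum(ranks[s, perms[grid[g, s], ]] * cc), numeric(1)))
      if (Lg >= L) count <- count + 1L
    }
    return(list(L = L, p = count / total, method = "exact permutation"))
  }
  set.seed(seed)
  ranks <- t(apply(X, 1, rank))
  ge <- 0L
  for (b in seq_len(n_perm)) {
    Lb <- sum(vapply(seq_len(N), function(s)
      sum(ranks[s, sample(k)] * cc), numeric(1)))
    if (Lb >= L) ge <- ge + 1L
  }
  list(L = L, p = (ge + 1) / (n_perm + 1), method = "Monte-Carlo permutation")
}

# all permutations of 1..k as rows
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1)))
  }))
  storage.mode(out) <- "integer"
  out
}

#' Subject-level feature-dependent iFC analysis at one depth
#'
#' The residual-connectivity stage end to end for one subject and depth:
#' per-run regression of the activation model (plus optional bandpass
#' and confound regression, the robustness-control preprocessing),
#' concatenation of the per-run residuals, within-region pairwise
#' correlations against the feature difference, binning, and the
#' exponential decay fit per region.
#'
#' @param runs the subject's runs at one depth.
#' @param stim a [chirp_stimulus()].
#' @param labels `region_labels` from [define_core()] (or any factor
#'   with levels core/noncore).
#' @param feature per-vertex feature (ln Hz preference, or `log2`
#'   tuning width with `feature_scale = "log2"`).
#' @param valid logical per-vertex validity mask.
#' @param feature_scale see [pairwise_ifc()].
#' @param preproc `"none"` or `"fig9"` (bandpass 0.01-0.1 Hz + motion/WM
#'   confound regression, the robustness-control pipeline).
#' @param n_harmonics harmonics of the activation model removed per run
#'   (default `Inf`: the full block-periodic evoked response).
#' @param edges,x_mode passed to [bin_curve()].
#' @return list per region: `curve` (`ifc_curve`), `fit` (R0, lambda).
#' @export
ifc_analysis <- function(runs, stim, labels, feature, valid = NULL,
                         feature_scale = "ln",
                         preproc = c("none", "fig9"),
                         edges = ifc_bin_edges(),
                         x_mode = "pair_mean", n_harmonics = Inf) {
  preproc <- match.arg(preproc)
  if (is.null(valid)) valid <- !is.na(feature)
  res_parts <- lapply(runs, function(r) {
    X <- r$data
    conf <- NULL
    if (preproc == "fig9") {
      X <- bandpass(X, r$tr)
      if (!is.null(r$nuisance))  # filter confounds like the data
        conf <- apply(r$nuisance, 2, function(cn) bandpass(cn, r$tr))
    }
    regress_out(X, r$tr, stim$presentation_freq, confounds = conf,
                n_harmonics = n_harmonics)$data
  })
  res <- do.call(cbind, res_parts)
  out <- list()
  for (reg in c("core", "noncore")) {
    vv <- which(labels == reg & valid)
    if (length(vv) < 2) stop("region ", reg, " has fewer than 2 valid vertices")
    pairs <- pairwise_ifc(res, vv, feature, feature_scale = feature_scale)
    curve <- bin_curve(pairs, edges = edges, x_mode = x_mode)
    out[[reg]] <- list(curve = curve, fit = fit_selectivity(curve))
  }
  out
}
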