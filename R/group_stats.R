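#' One-way ANOVA across cortical depths
#'
#' Classical one-way F test (`df = (k - 1, sum n_i - k)`), the form
#' whose degrees of freedom match pooled per-depth observations; a
#' subject-blocked repeated-measures form
#' (`df = (k - 1, (N - 1)(k - 1))`) is available for balanced
#' subject-by-depth tables.
#'
#' @param groups list of numeric vectors (one per depth), or, for
#'   `form = "repeated"`, a subjects x depths matrix.
#' @param form `"classical"` (default) or `"repeated"`.
#' @return list of class `stat_result`: `test`, `statistic`, `df`,
#'   `p`, plus `note` for degenerate input.
#' @export
one_way_anova <- function(groups, form = c("classical", "repeated")) {
  form <- match.arg(form)
  if (form == "repeated") {
    M <- as.matrix(groups)
    N <- nrow(M); k <- ncol(M)
    stopifnot(N >= 2, k >= 2)
    gm <- mean(M)
    ss_cond <- N * sum((colMeans(M) - gm)^2)
    ss_subj <- k * sum((rowMeans(M) - gm)^2)
    ss_tot <- sum((M - gm)^2)
    ss_err <- ss_tot - ss_cond - ss_subj
    df1 <- k - 1; df2 <- (N - 1) * (k - 1)
    F <- (ss_cond / df1) / (ss_err / df2)
    return(structure(list(test = "one-way repeated-measures ANOVA",
                          statistic = F, df = c(df1, df2),
                          p = stats::pf(F, df1, df2, lower.tail = FALSE)),
                     class = "stat_result"))
  }
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  vals <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  k <- length(groups); n <- length(vals)
  gm <- mean(vals)
  ss_b <- sum(vapply(groups, function(x) length(x) * (mean(x) - gm)^2, 1))
  ss_w <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  df1 <- k - 1; df2 <- n - k
  note <- NULL
  if (ss_w == 0) {
    if (ss_b == 0) { F <- 0; p <- 1 }
    else { F <- Inf; p <- 0; note <- "zero within-group variance with unequal means" }
  } else {
    F <- (ss_b / df1) / (ss_w / df2)
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  structure(list(test = "one-way ANOVA", statistic = F, df = c(df1, df2),
                 p = p, note = note), class = "stat_result")
}

#' One-tailed Student t test
#'
#' @param a,b samples; equal length required when `paired`.
#' @param paired paired test (default FALSE).
#' @param direction alternative: `"greater"` tests mean(a) > mean(b).
#' @return `stat_result` list with `statistic`, `df`, `p`.
#' @export
one_tailed_t <- function(a, b, paired = FALSE,
                         direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (paired && length(a) != length(b)) stop("paired samples must have equal length")
  degen <- if (paired) stats::sd(a - b) == 0 else stats::sd(a) == 0 && stats::sd(b) == 0
  if (degen) {
    d <- mean(a) - mean(b)
    if (d == 0)  # no effect, no variance: t = 0 by convention
      return(structure(list(test = "one-tailed t", statistic = 0,
                            df = length(a) - 1, p = 0.5),
                       class = "stat_result"))
    p <- if ((direction == "greater") == (d > 0)) 0 else 1
    return(structure(list(test = "one-tailed t", statistic = sign(d) * Inf,
                          df = length(a) - 1, p = p,
                          note = "zero variance with unequal means"),
                     class = "stat_result"))
  }
  tt <- stats::t.test(a, b, paired = paired, alternative = direction,
                      var.equal = FALSE)
  structure(list(test = paste0("one-tailed t (", direction,
                               if (paired) ", paired" else "", ")"),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, df = (%s), p = %.4g\n", x$test, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p))
  invisible(x)
}

#' The post-hoc depth comparison family
#'
#' The seven depth pairs over which post-hoc t-tests are FDR-corrected.
#'
#' @return two-column matrix of depth pairs.
#' @export
depth_posthoc_pairs <- function() {
  cbind(a = c(0.1, 0.1, 0.1, 0.1, 0.3, 0.5, 0.7),
        b = c(0.3, 0.5, 0.7, 0.9, 0.9, 0.9, 0.9))
}
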