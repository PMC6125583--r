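#' Pipeline run configuration
#'
#' Assembles (with defaults) the fully serializable configuration of an
#' end-to-end synthetic run.  A run is reproducible from its config plus
#' seed; every stage derives a child seed from the global one.
#'
#' @param n_subjects number of synthetic subjects.
#' @param grid `c(rows, cols)` sheet dimensions.
#' @param spacing_mm vertex spacing (mm).
#' @param depths normalized depths.
#' @param core_shape `c(rows, cols)` of the generative core strip.
#' @param tw_core,tw_noncore generative tuning widths (octaves).
#' @param lambda_table data.frame(depth, region, lambda) or NULL for
#'   [default_lambda_table()].
#' @param noise_sd,rho0,amplitude,delay_range generator noise model.
#' @param drift_amp,nuisance_gain confound injection (0 = clean).
#' @param preproc `"none"` or `"fig9"`.
#' @param z_threshold subject-level activation threshold (standard z).
#' @param fdr_q group functional-ROI FDR level.
#' @param tw_threshold core tuning width threshold (octaves).
#' @param smooth_fwhm_mm surface smoothing of group feature maps (mm);
#'   never applied on the iFC path.
#' @param x_mode bin representative for the decay fit.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_subjects = 5, grid = c(20, 30), spacing_mm = 1.5,
                       depths = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       core_shape = c(10, 16),
                       tw_core = 1.4, tw_noncore = 1.9,
                       lambda_table = NULL,
                       noise_sd = 0.1, rho0 = 0.6, amplitude = 1,
                       delay_range = c(3, 7),
                       drift_amp = 0, nuisance_gain = 0,
                       preproc = "none",
                       z_threshold = 1.65, fdr_q = 0.01,
                       tw_threshold = 1.7, smooth_fwhm_mm = 5,
                       x_mode = "pair_mean") {
  cfg <- as.list(environment())
  if (is.null(cfg$lambda_table)) cfg$lambda_table <- default_lambda_table(depths)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration
#'
#' JSON is the native config format; files ending in `.yaml`/`.yml` are
#' read with the yaml package when available.
#'
#' @param path file path.
#' @param cfg a [run_config()] (for writing).
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  raw$lambda_table <- as.data.frame(raw$lambda_table)
  cfg <- do.call(run_config, raw[setdiff(names(raw), character(0))])
  cfg
}

#' Run the full synthetic pipeline
#'
#' generate -> map -> tune -> parcellate -> (variability) -> iFC ->
#' group stats, with fixed seeds fanned out per stage.  Writes tidy CSV
#' tables when `out_dir` is given and returns the result bundle.
#'
#' @param cfg a [run_config()].
#' @param seed global integer seed.
#' @param out_dir output directory for CSV tables (NULL = no files).
#' @param variability also compute inter-/intra-subject variability
#'   (slower; default FALSE).
#' @param verbose print stage progress.
#' @return list with `gt`, `maps`, `tuning`, `roi`, `labels`, `lambda`
#'   (tidy data.frame), `curves`, `stats`, `variability` (or NULL).
#' @export
run_pipeline <- function(cfg = run_config(), seed = 1L, out_dir = NULL,
                         variability = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stim <- chirp_stimulus()
  sheet <- cortical_sheet(cfg$grid[1], cfg$grid[2], cfg$spacing_mm, cfg$depths)
  gt <- make_ground_truth(sheet, stim, n_subjects = cfg$n_subjects,
                          core_shape = cfg$core_shape,
                          tw_core = cfg$tw_core, tw_noncore = cfg$tw_noncore,
                          lambda_table = cfg$lambda_table,
                          noise_sd = cfg$noise_sd, rho0 = cfg$rho0,
                          amplitude = cfg$amplitude,
                          delay_range = cfg$delay_range,
                          seed = derive_seed(seed, "truth"))

  say("simulating %d subjects at %d depths ...", cfg$n_subjects,
      length(cfg$depths))
  subjects <- lapply(seq_len(cfg$n_subjects), function(s)
    simulate_subject(gt, s, depths = cfg$depths,
                     seed = derive_seed(seed, paste0("subject", s)),
                     drift_amp = cfg$drift_amp,
                     nuisance_gain = cfg$nuisance_gain))

  say("phase mapping ...")
  maps <- lapply(subjects, map_subject, stim = stim,
                 z_threshold = cfg$z_threshold)
  say("tuning width estimation ...")
  tuning <- lapply(seq_len(cfg$n_subjects), function(s)
    tuning_map(subjects[[s]], stim, latency = maps[[s]]))

  dk <- sprintf("%g", cfg$depths)
  zmat <- do.call(rbind, lapply(maps, function(m)
    rowMeans(vapply(dk, function(d) m[[d]]$z, numeric(sheet$n_vertices)))))
  roi <- functional_roi(zmat, q = cfg$fdr_q)

  # group tuning map: mean across subjects and depths, surface-smoothed
  tw_all <- vapply(tuning, function(tm)
    rowMeans(vapply(dk, function(d) {
      v <- tm[[d]]$tw_octaves; v
    }, numeric(sheet$n_vertices)), na.rm = TRUE), numeric(sheet$n_vertices))
  tw_group <- smooth_on_sheet(rowMeans(tw_all, na.rm = TRUE),
                              cfg$smooth_fwhm_mm, sheet)
  labels <- define_core(tw_group, sheet, threshold = cfg$tw_threshold,
                        roi = roi)

  say("feature-dependent iFC ...")
  lam <- list(); curves <- list()
  for (s in seq_len(cfg$n_subjects)) for (d in cfg$depths) {
    dkey <- sprintf("%g", d)
    am <- maps[[s]][[dkey]]
    # truncation-debiased preference is the iFC feature axis
    lat_db <- debias_latency(am$latency, tuning[[s]][[dkey]]$tw_octaves, stim)
    logf_db <- latency_to_log_frequency(lat_db, stim)
    res <- ifc_analysis(runs_at(subjects[[s]], depth = d), stim, labels,
                        feature = logf_db, valid = am$valid & !is.na(logf_db),
                        preproc = cfg$preproc, x_mode = cfg$x_mode)
    for (reg in names(res)) {
      lam[[length(lam) + 1]] <- data.frame(
        subject = s, depth = d, region = reg,
        R0 = res[[reg]]$fit$R0, lambda = res[[reg]]$fit$lambda)
      cv <- as.data.frame(res[[reg]]$curve)
      cv$subject <- s; cv$depth <- d; cv$region <- reg
      curves[[length(curves) + 1]] <- cv
    }
  }
  lam <- do.call(rbind, lam)
  curves <- do.call(rbind, curves)

  stats_out <- NULL
  if (cfg$n_subjects >= 2) {
    stats_out <- list()
    if (length(cfg$depths) >= 2) {
      for (reg in c("core", "noncore")) {
        g <- lapply(cfg$depths, function(d)
          lam$lambda[lam$region == reg & lam$depth == d])
        stats_out[[paste0("anova_", reg)]] <- one_way_anova(g)
      }
    }
    cmp <- lapply(cfg$depths, function(d)
      one_tailed_t(lam$lambda[lam$region == "core" & lam$depth == d],
                   lam$lambda[lam$region == "noncore" & lam$depth == d],
                   paired = TRUE, direction = "greater"))
    p_raw <- vapply(cmp, `[[`, numeric(1), "p")
    stats_out$core_gt_noncore <- data.frame(
      depth = cfg$depths, p = p_raw,
      p_bonferroni = adjust_bonferroni(p_raw))
    for (reg in c("core", "noncore")) {
      cb <- curves[curves$region == reg, ]
      M <- do.call(rbind, lapply(split(cb, list(cb$subject, cb$depth)),
                                 function(x) x$r[order(x$bin)]))
      # bins empty in some subject cannot enter the rank test
      M <- M[, colSums(is.na(M)) == 0, drop = FALSE]
      M <- M[stats::complete.cases(M), , drop = FALSE]
      stats_out[[paste0("page_", reg)]] <-
        if (ncol(M) >= 3 && nrow(M) >= 1) pages_trend_test(M)
        else list(L = NA, p = NA, method = "skipped: too few complete bins")
    }
  } else warning("n_subjects = 1: group statistics skipped")

  vr <- NULL
  if (variability) {
    say("variability ...")
    vr <- list()
    for (d in cfg$depths) {
      dkey <- sprintf("%g", d)
      vr[[dkey]] <- list(
        inter_logf = inter_subject_sd(lapply(maps, `[[`, dkey), "logf"),
        intra = lapply(seq_len(cfg$n_subjects), function(s)
          intra_subject_sd(runs_at(subjects[[s]], depth = d), stim,
                           seed = derive_seed(seed, paste0("split", s, dkey)))))
    }
  }

  out <- list(config = cfg, seed = seed, gt = gt, maps = maps,
              tuning = tuning, roi = roi, labels = labels,
              lambda = lam, curves = curves, stats = stats_out,
              variability = vr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(lam, file.path(out_dir, "lambda.csv"), row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "ifc_curves.csv"),
                     row.names = FALSE)
    co <- sheet_coords(sheet)
    utils::write.csv(data.frame(co, label = as.character(labels),
                                roi = roi),
                     file.path(out_dir, "regions.csv"), row.names = FALSE)
    write_run_config(cfg, file.path(out_dir, "config.json"))
  }
  invisible(out)
}
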