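#' Pipeline configuration
#'
#' Bundles every knob of the calibration pipeline.  The defaults are the
#' full calibration design: 32 replicate fBm surfaces of 1024 x 1024
#' pixels per Hurst value in \{0.1, 0.3, 0.5, 0.7\}, saturation levels
#' 1/5/10/20 percent, scale grid a0 = 7 px with 8 voices per octave,
#' moments -3..5 by 0.5, fit window 17-56 px, and the calibrated
#' per-H modulus filters with SF = 0.5.  Scale `size` and
#' `n_replicates` down for desk-scale runs.
#'
#' @param hurst Hurst exponents to calibrate.
#' @param size surface edge length (power of two).
#' @param n_replicates surfaces per ensemble.
#' @param seed ensemble seed; surface `r` of every ensemble uses
#'   `seed + r - 1`.
#' @param saturation saturation levels (fractions in (0, 1)).
#' @param a0,voices scale-grid parameters.
#' @param q moment grid.
#' @param fit_range fit window in pixels.
#' @param sf adjusted-slope threshold.
#' @param mf modulus-filter policy: `"recalibrate"` (default) aligns
#'   the modulus units with the reference calibration before applying
#'   the registry threshold — each Hurst ensemble's skeletons are
#'   rescaled by `kappa = mf_for_hurst(H) / q`, where `q` is the 1
#'   percent quantile of first-scale moduli over that ensemble's
#'   *unsaturated* skeletons, so that the registry MF removes about 1
#'   percent of clean lines (the quantile-matching rule); `"registry"`
#'   applies [mf_for_hurst()] directly to the raw [0, 255]-normalized
#'   moduli; or a named numeric vector of thresholds keyed by Hurst
#'   value (e.g. `c("0.7" = 16)`).
#' @param r2_min fit-quality threshold for the usable moment range.
#' @param out_dir optional directory; when set, per-cell reports and
#'   spectra are written there as CSV.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(hurst = c(0.1, 0.3, 0.5, 0.7), size = 1024,
                            n_replicates = 32L, seed = 1L,
                            saturation = c(0.01, 0.05, 0.10, 0.20),
                            a0 = 7, voices = 8L, q = moment_grid(),
                            fit_range = c(17, 56), sf = 0.5,
                            mf = "recalibrate",
                            r2_min = 0.99, out_dir = NULL) {
  stopifnot(all(hurst > 0 & hurst < 1),
            all(saturation > 0 & saturation < 1),
            n_replicates >= 1, length(fit_range) == 2L,
            fit_range[1L] < fit_range[2L])
  if (is.character(mf)) {
    mf <- match.arg(mf, c("recalibrate", "registry"))
  } else {
    stopifnot(is.numeric(mf), !is.null(names(mf)), all(mf > 0))
  }
  structure(list(hurst = hurst, size = as.integer(size),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), saturation = saturation,
                 a0 = a0, voices = as.integer(voices), q = q,
                 fit_range = fit_range, sf = sf, mf = mf,
                 r2_min = r2_min, out_dir = out_dir),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round trip with full numeric precision, so a stored
#' configuration reproduces a run exactly.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` invisibly (`write_config`); a `pipeline_config`
#'   (`read_config`).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1L))])
}

#' Run the calibration pipeline
#'
#' For every Hurst value: synthesize the replicate fBm surfaces, build
#' their skeletons, and analyze the unsaturated ensemble; then for every
#' saturation level, saturate the same surfaces, rebuild skeletons,
#' prune with the configured filters, and fit spectra before and after
#' pruning.  Everything is deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress lines.
#' @return An object of class `calibration_report`: list with
#'   * `cells`: data frame, one row per (H, saturation level), with
#'     ensemble removal percentages (`pct_MF`, `pct_SF`, `pct_kept`),
#'     the usable moment range before (`q_lo_raw`, `q_hi_raw`) and
#'     after (`q_lo_rescued`, `q_hi_rescued`) pruning, and the fitted
#'     `H_fit` (tau-slope) of the rescued ensemble;
#'   * `clean`: data frame, one row per H, with the unsaturated
#'     ensemble's `H_fit`, `tau_intercept`, usable range, monofractality
#'     width `h_spread`, and the pruning-neutrality deltas
#'     `max_dh` / `max_dD` over moments in [-1, 3];
#'   * `spectra`: named list of `mf_spectra` per cell;
#'   * `config`.
#' @export
run_pipeline <- function(config, verbose = interactive()) {
  stopifnot(inherits(config, "pipeline_config"))
  grid <- scale_grid(config$size, config$a0, config$voices,
                     fit_range = config$fit_range)
  say <- function(...) if (verbose) message(sprintf(...))
  cells <- list(); clean <- list(); spectra <- list()
  for (h in config$hurst) {
    mf_h <- if (is.character(config$mf)) {
      suppressWarnings(mf_for_hurst(h))
    } else {
      config$mf[[format(h)]] %||% suppressWarnings(mf_for_hurst(h))
    }
    say("H = %.2g: synthesizing %d surfaces (%d px)", h,
        config$n_replicates, config$size)
    surfaces <- lapply(seq_len(config$n_replicates), function(r) {
      fbm_surface(h, config$size, seed = config$seed + r - 1L)
    })
    say("H = %.2g: unsaturated skeletons", h)
    skels0 <- lapply(surfaces, function(s) wt_skeleton(s, grid))
    kappa_h <- 1
    if (identical(config$mf, "recalibrate")) {
      kappa_h <- mf_h / recalibrate_mf(skels0, keep_frac = 0.99)
      skels0 <- lapply(skels0, rescale_skeleton, kappa = kappa_h)
    }
    pf0 <- lapply(skels0, partition_functions, q = config$q)
    sp0 <- fit_spectra(ensemble_average(pf0), config$fit_range,
                       config$r2_min)
    pruned0 <- lapply(skels0, prune_skeleton, mf = mf_h, sf = config$sf)
    sp0p <- fit_spectra(
      ensemble_average(lapply(pruned0, function(p) {
        partition_functions(p$skeleton, q = config$q)
      })), config$fit_range, config$r2_min)
    neutral <- spectra_delta(sp0, sp0p, q_window = c(-1, 3))
    ts0 <- tau_slope(sp0)
    key0 <- sprintf("H%.2g_unsat", h)
    spectra[[key0]] <- sp0
    spectra[[paste0(key0, "_pruned")]] <- sp0p
    clean[[key0]] <- data.frame(
      hurst = h, H_fit = ts0[["H"]], tau_intercept = ts0[["intercept"]],
      q_lo = sp0$usable_q[1L], q_hi = sp0$usable_q[2L],
      h_spread = h_spread(sp0),
      max_dh = neutral[["max_dh"]], max_dD = neutral[["max_dD"]])
    for (lev in config$saturation) {
      say("H = %.2g, saturation %.0f%%: skeletons + rescue", h, 100 * lev)
      skels <- lapply(surfaces, function(s) {
        wt_skeleton(apply_saturation(s, lev), grid)
      })
      if (kappa_h != 1) skels <- lapply(skels, rescale_skeleton, kappa = kappa_h)
      pf_raw <- lapply(skels, partition_functions, q = config$q)
      sp_raw <- fit_spectra(ensemble_average(pf_raw), config$fit_range,
                            config$r2_min)
      pruned <- lapply(skels, prune_skeleton, mf = mf_h, sf = config$sf)
      rep_df <- removal_report(pruned)
      mean_row <- rep_df[nrow(rep_df), ]
      sp_resc <- fit_spectra(
        ensemble_average(lapply(pruned, function(p) {
          partition_functions(p$skeleton, q = config$q)
        })), config$fit_range, config$r2_min)
      key <- sprintf("H%.2g_sat%.2g", h, lev)
      spectra[[paste0(key, "_raw")]] <- sp_raw
      spectra[[paste0(key, "_rescued")]] <- sp_resc
      cells[[key]] <- data.frame(
        hurst = h, saturation = lev, mf = mf_h, kappa = kappa_h,
        sf = config$sf,
        n_surfaces = config$n_replicates,
        n_lines = mean_row$n_lines,
        pct_MF = mean_row$pct_MF, pct_SF = mean_row$pct_SF,
        pct_kept = mean_row$pct_kept,
        q_lo_raw = sp_raw$usable_q[1L], q_hi_raw = sp_raw$usable_q[2L],
        q_lo_rescued = sp_resc$usable_q[1L],
        q_hi_rescued = sp_resc$usable_q[2L],
        H_fit = tau_slope(sp_resc)[["H"]])
    }
  }
  out <- structure(list(cells = do.call(rbind, c(cells,
                                                 make.row.names = FALSE)),
                        clean = do.call(rbind, c(clean,
                                                 make.row.names = FALSE)),
                        spectra = spectra, config = config),
                   class = "calibration_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$cells, file.path(config$out_dir, "cells.csv"),
              row.names = FALSE)
    write.csv(out$clean, file.path(config$out_dir, "clean.csv"),
              row.names = FALSE)
    for (key in names(spectra)) {
      write.csv(spectra[[key]]$spectra,
                file.path(config$out_dir, paste0("spectra_", key, ".csv")),
                row.names = FALSE)
    }
    write_config(config, file.path(config$out_dir, "config.json"))
  }
  out
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("calibration_report\n\nUnsaturated ensembles:\n")
  print(x$clean, digits = 3)
  cat("\nSaturated cells:\n")
  print(x$cells, digits = 3)
  invisible(x)
}

# Width of h(q) over the usable moment range (monofractality check).
h_spread <- function(spectra) {
  u <- spectra$usable_q
  if (any(is.na(u))) return(NA_real_)
  s <- spectra$spectra
  sel <- s$q >= u[1L] & s$q <= u[2L]
  max(s$h[sel]) - min(s$h[sel])
}

# Largest |delta h| and |delta D| between two spectra over a q window.
spectra_delta <- function(sp_a, sp_b, q_window = c(-1, 3)) {
  qa <- sp_a$spectra$q
  stopifnot(isTRUE(all.equal(qa, sp_b$spectra$q)))
  sel <- qa >= q_window[1L] & qa <= q_window[2L]
  c(max_dh = max(abs(sp_a$spectra$h[sel] - sp_b$spectra$h[sel])),
    max_dD = max(abs(sp_a$spectra$D[sel] - sp_b$spectra$D[sel])))
}
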