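#' Adjusted slope of each maxima line
#'
#' The adjusted slope summarizes a line's modulus trend across scales:
#' `m_adj = (log2 M_first - log2 M_last) / log2 M_last`, where `M_first`
#' is the modulus at the line's first (smallest) skeleton scale and
#' `M_last` the modulus at its termination scale.  Extraneous lines
#' created by saturation plateaus typically start relatively high and
#' decay, giving large positive `m_adj`.
#'
#' @param skel a `wt_skeleton`.
#' @return numeric vector, one value per line; `NA` for single-scale
#'   lines (no trend) and for lines whose terminal modulus is at or
#'   below 1 (the log2 denominator degenerates; [prune_skeleton()]
#'   documents how such lines are classified).
#' @examples
#' # M_first = 2^6, M_last = 2^4  ->  (6 - 4) / 4 = 0.5
#' @export
adjusted_slope <- function(skel) {
  stopifnot(inherits(skel, "wt_skeleton"))
  m_first <- skel$m[, 1L]
  m_last <- skel$m[cbind(seq_len(n_lines(skel)), skel$jmax)]
  l2f <- log2(m_first)
  l2l <- log2(m_last)
  out <- (l2f - l2l) / l2l
  out[skel$jmax < 2L | l2l <= 0] <- NA_real_
  out
}

#' Default modulus-filter threshold for a given Hurst exponent
#'
#' Returns the calibrated modulus-filter value for surfaces normalized
#' to [0, 255]: MF = 16, 48, 96, 192 for H = 0.7, 0.5, 0.3, 0.1 (rougher
#' surfaces carry weaker gradients, so the cutoff rises as H falls).  At
#' intermediate H the threshold is interpolated geometrically
#' (linearly in `log2 MF` between the bracketing calibrated values),
#' with a warning that only the four calibrated values are backed by the
#' calibration study; outside [0.1, 0.7] the nearest calibrated value is
#' used, also with a warning.
#'
#' @param hurst Hurst exponent in (0, 1).
#' @return modulus threshold (height-response units, linear scale).
#' @export
mf_for_hurst <- function(hurst) {
  calib_h <- c(0.1, 0.3, 0.5, 0.7)
  calib_l2 <- log2(c(192, 96, 48, 16))
  if (hurst < min(calib_h) || hurst > max(calib_h)) {
    warning("H = ", hurst, " is outside the calibrated range [0.1, 0.7]; ",
            "using the nearest calibrated modulus filter")
    return(2^calib_l2[which.min(abs(calib_h - hurst))])
  }
  hit <- which(abs(calib_h - hurst) < 1e-9)
  if (length(hit)) return(2^calib_l2[hit])
  warning("H = ", hurst, " is not a calibrated value; interpolating the ",
          "modulus filter geometrically between calibrated neighbours")
  2^stats::approx(calib_h, calib_l2, xout = hurst)$y
}

#' Prune a skeleton with the modulus and adjusted-slope filters
#'
#' The rescue procedure removes the extraneous maxima lines that image
#' saturation injects into the skeleton, in two ordered stages:
#'
#' 1. **Modulus filter (MF):** every line whose modulus at its first
#'    scale is `<= mf` is labelled `removed_MF`.
#' 2. **Adjusted-slope filter (SF):** every survivor with
#'    `m_adj >= sf` (see [adjusted_slope()]) is labelled `removed_SF`.
#'
#' Both thresholds are inclusive, and a line meeting both criteria
#' counts under MF only, so the two removal percentages are additive.
#' Survivor lines whose terminal modulus is `<= 1` (degenerate log2
#' denominator) are labelled `removed_SF` when their modulus decays
#' from first to last scale — the weak negative-sloping artifact class —
#' and kept otherwise.  Single-scale lines are subject to the modulus
#' filter only.
#'
#' @param skel a `wt_skeleton` (left unmodified).
#' @param mf modulus threshold (> 0); `log2(16) = 4` is the calibrated
#'   value for H = 0.7 surfaces in [0, 255], see [mf_for_hurst()].
#' @param sf adjusted-slope threshold (dimensionless), calibrated 0.5.
#' @param mf_scale where to read the "first scale" modulus: `"first"`
#'   (default) uses each line's first skeleton scale; a number uses the
#'   modulus at the nearest grid scale in pixels (capped at each line's
#'   termination scale).
#' @return An object of class `pruned_skeleton`: list with `skeleton`
#'   (a new `wt_skeleton` holding only kept lines), `labels` (factor
#'   `kept` / `removed_MF` / `removed_SF` over the original lines),
#'   `counts`, `pct` (percentages summing to 100), and `params`.
#' @export
prune_skeleton <- function(skel, mf, sf = 0.5, mf_scale = "first") {
  stopifnot(inherits(skel, "wt_skeleton"))
  if (!is.numeric(mf) || mf <= 0) stop("mf must be positive, got ", mf)
  nl <- n_lines(skel)
  if (!nl) stop("skeleton has no maxima lines")
  m_first <- if (identical(mf_scale, "first")) {
    skel$m[, 1L]
  } else {
    j <- which.min(abs(skel$scales - mf_scale))
    skel$m[cbind(seq_len(nl), pmin(j, skel$jmax))]
  }
  m_last <- skel$m[cbind(seq_len(nl), skel$jmax)]
  labels <- rep("kept", nl)
  labels[m_first <= mf] <- "removed_MF"
  madj <- adjusted_slope(skel)
  surv <- labels == "kept"
  sf_hit <- surv & !is.na(madj) & madj >= sf
  # degenerate denominator: weak line, classify by its modulus trend
  degen <- surv & is.na(madj) & skel$jmax >= 2L & log2(m_last) <= 0
  sf_hit <- sf_hit | (degen & m_first > m_last)
  labels[sf_hit] <- "removed_SF"
  labels <- factor(labels, levels = c("kept", "removed_MF", "removed_SF"))
  counts <- table(labels)
  structure(list(skeleton = subset_skeleton(skel, labels == "kept"),
                 labels = labels,
                 counts = as.integer(counts),
                 pct = 100 * as.numeric(counts) / nl,
                 params = list(mf = mf, sf = sf, mf_scale = mf_scale)),
            class = "pruned_skeleton")
}

#' @export
print.pruned_skeleton <- function(x, ...) {
  cat(sprintf("pruned_skeleton: MF = %g, SF = %g\n", x$params$mf,
              x$params$sf))
  cat(sprintf("  kept %.1f%%, removed %.1f%% (modulus filter) + %.1f%% (slope filter) of %d lines\n",
              x$pct[1L], x$pct[2L], x$pct[3L], sum(x$counts)))
  invisible(x)
}

#' Removal percentages of a pruning (per surface and ensemble mean)
#'
#' @param x a `pruned_skeleton` or a list of them (one per ensemble
#'   surface).
#' @return data frame with columns `surface`, `n_lines`, `pct_MF`,
#'   `pct_SF`, `pct_kept`; for a list, a final row `mean` holds the
#'   ensemble averages of the percentage columns.
#' @export
removal_report <- function(x) {
  if (inherits(x, "pruned_skeleton")) x <- list(x)
  stopifnot(length(x) >= 1L,
            all(vapply(x, inherits, logical(1L), "pruned_skeleton")))
  rows <- do.call(rbind, lapply(seq_along(x), function(i) {
    p <- x[[i]]
    data.frame(surface = as.character(i), n_lines = sum(p$counts),
               pct_MF = p$pct[2L], pct_SF = p$pct[3L], pct_kept = p$pct[1L])
  }))
  if (length(x) > 1L) {
    rows <- rbind(rows, data.frame(surface = "mean",
                                   n_lines = mean(rows$n_lines),
                                   pct_MF = mean(rows$pct_MF),
                                   pct_SF = mean(rows$pct_SF),
                                   pct_kept = mean(rows$pct_kept)))
  }
  rownames(rows) <- NULL
  rows
}

#' Recalibrate the modulus filter against unsaturated skeletons
#'
#' The calibrated MF values assume heights in [0, 255].  For data on a
#' different amplitude convention this utility quantile-matches the
#' threshold: it returns the value below which a fraction
#' `1 - keep_frac` of the first-scale moduli of *unsaturated* reference
#' skeletons fall, so that pruning clean data removes under
#' `100 * (1 - keep_frac)` percent of lines by the modulus filter.
#'
#' @param skels a `wt_skeleton` or list of them, from unsaturated
#'   reference surfaces.
#' @param keep_frac target fraction of lines kept by MF on clean data
#'   (default 0.99).
#' @return modulus threshold on the data's own amplitude scale.
#' @export
recalibrate_mf <- function(skels, keep_frac = 0.99) {
  if (inherits(skels, "wt_skeleton")) skels <- list(skels)
  m_first <- sort(unlist(lapply(skels, function(s) s$m[, 1L])))
  # inverse-ECDF quantile, guarded against floating-point boundaries
  k <- max(1L, ceiling(length(m_first) * (1 - keep_frac) - 1e-9))
  m_first[k]
}

#' Rescale a skeleton's modulus values
#'
#' Multiplies every modulus record by `kappa`.  Because the wavelet
#' transform is linear, this is exactly equivalent to having scaled the
#' surface heights by `kappa` before analysis; it is how the package
#' aligns its modulus units with the reference calibration of the
#' filter thresholds (see [recalibrate_mf()] and the pipeline's
#' `mf = "recalibrate"` mode).  Slopes of all spectra are invariant.
#'
#' @param skel a `wt_skeleton`.
#' @param kappa positive scale factor.
#' @return the rescaled `wt_skeleton`.
#' @export
rescale_skeleton <- function(skel, kappa) {
  stopifnot(inherits(skel, "wt_skeleton"), is.numeric(kappa), kappa > 0)
  skel$m <- skel$m * kappa
  skel
}

#' Experimental outlier-based filter thresholds
#'
#' An automated alternative to the calibrated thresholds, off by
#' default in the pipeline: the modulus filter is set at the lower
#' Tukey fence (Q1 - 1.5 IQR) of the `log2` first-scale modulus
#' distribution, and the slope filter at the upper fence
#' (Q3 + 1.5 IQR) of the adjusted-slope distribution.  Exploratory
#' only; the values are not backed by the calibration study.
#'
#' @param skel a `wt_skeleton`.
#' @return list with `mf` and `sf`.
#' @export
auto_filter_params <- function(skel) {
  l2m <- log2(skel$m[, 1L])
  qs <- quantile(l2m, c(0.25, 0.75), na.rm = TRUE)
  mf <- 2^unname(qs[1L] - 1.5 * diff(qs))
  madj <- adjusted_slope(skel)
  qa <- quantile(madj, c(0.25, 0.75), na.rm = TRUE)
  sf <- unname(qa[2L] + 1.5 * diff(qa))
  list(mf = mf, sf = sf)
}
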