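#' Default statistical-order-moment grid
#'
#' @param qmin,qmax,step moment range and spacing; the default covers
#'   q = -3 to 5 in steps of 0.5, the span over which unsaturated fBm
#'   calibration surfaces admit good power-law fits.
#' @return strictly increasing numeric vector containing 0.
#' @export
moment_grid <- function(qmin = -3, qmax = 5, step = 0.5) {
  q <- seq(qmin, qmax, by = step)
  if (!any(q == 0)) stop("moment grid must contain q = 0")
  q
}

# Running supremum of each line's modulus over scales <= a (rows =
# lines, columns = scales; NA beyond a line's termination).
sup_matrix <- function(skel) {
  m <- skel$m
  S <- ncol(m)
  sup <- m
  for (j in seq_len(S)[-1L]) {
    sup[, j] <- pmax(sup[, j - 1L], m[, j])
  }
  sup
}

#' Running supremum of a line's modulus
#'
#' The quantity entering the partition function: the supremum of the
#' modulus along maxima line `line` over all scales up to `a`.
#'
#' @param skel a `wt_skeleton`.
#' @param line line index.
#' @param a scale in pixels; must not exceed the line's termination
#'   scale.
#' @return the prefix supremum as a single number.
#' @export
sup_modulus <- function(skel, line, a) {
  stopifnot(inherits(skel, "wt_skeleton"))
  j <- match_scale(skel$scales, a)
  if (j > skel$jmax[line]) {
    stop("line ", line, " terminates at scale ",
         skel$scales[skel$jmax[line]], " px, before a = ", a, " px")
  }
  max(skel$m[line, seq_len(j)])
}

match_scale <- function(scales, a) {
  j <- which.min(abs(scales - a))
  if (abs(scales[j] - a) > 1e-8 * a) {
    stop("a = ", a, " px is not a grid scale")
  }
  j
}

#' Partition functions over a skeleton
#'
#' Computes, for every moment `q` and grid scale `a`, the partition
#' function `Z(q, a)` (the sum over the maxima lines still present at
#' `a` of their prefix-supremum modulus raised to `q`), and the
#' canonical-ensemble numerators `h(q, a)` (Boltzmann-weighted mean of
#' `ln sup M`) and `D(q, a)` (weight entropy `sum W ln W`, always
#' `<= 0`).  All sums are evaluated in log space, so large `|q|` cannot
#' overflow.  A line belongs to `L(a)` while its termination scale is
#' `>= a`.
#'
#' @param skel a `wt_skeleton` (or the `skeleton` element of a
#'   [prune_skeleton()] result).
#' @param q moment grid, see [moment_grid()].
#' @return An object of class `partition_functions`: list with `q`,
#'   `scales`, matrices `log2_z`, `h_num`, `D_num` (moments by scales),
#'   `n_lines` per scale, and `n_surfaces = 1`.
#' @export
partition_functions <- function(skel, q = moment_grid()) {
  stopifnot(inherits(skel, "wt_skeleton"))
  if (is.unsorted(q, strictly = TRUE)) stop("q grid must be strictly increasing")
  S <- length(skel$scales)
  nq <- length(q)
  sup <- sup_matrix(skel)
  log2z <- hmat <- dmat <- matrix(NA_real_, nq, S)
  nl <- integer(S)
  for (j in seq_len(S)) {
    ls <- log(sup[skel$jmax >= j, j])
    ls <- ls[!is.na(ls)]
    nl[j] <- length(ls)
    if (!nl[j]) next
    for (iq in seq_len(nq)) {
      e <- q[iq] * ls
      lz <- log_sum_exp(e)
      w_log <- e - lz
      w <- exp(w_log)
      log2z[iq, j] <- lz / log(2)
      hmat[iq, j] <- sum(w * ls)
      dmat[iq, j] <- sum(w * w_log)
    }
  }
  structure(list(q = q, scales = skel$scales, log2_z = log2z,
                 h_num = hmat, D_num = dmat, n_lines = nl,
                 n_surfaces = 1L),
            class = "partition_functions")
}

#' @export
print.partition_functions <- function(x, ...) {
  cat(sprintf("partition_functions: %d moments (q in [%g, %g]), %d scales, %s\n",
              length(x$q), min(x$q), max(x$q), length(x$scales),
              if (x$n_surfaces > 1L)
                paste("ensemble of", x$n_surfaces, "surfaces")
              else "single surface"))
  invisible(x)
}

#' Partition-function value at one (q, a)
#'
#' @param skel a `wt_skeleton`.
#' @param q single moment.
#' @param a grid scale in pixels.
#' @return `Z(q, a)` as a number.
#' @export
partition_function <- function(skel, q, a) {
  j <- match_scale(skel$scales, a)
  sup <- sup_matrix(skel)
  ls <- log(sup[skel$jmax >= j, j])
  if (!length(ls)) stop("no maxima lines present at a = ", a, " px")
  exp(log_sum_exp(q * ls))
}

#' Boltzmann weights of the maxima lines at one (q, a)
#'
#' The canonical weights `W(q, l, a) = sup^q / Z(q, a)` over the lines
#' present at scale `a`, computed with log-sum-exp so they are finite
#' and sum to one for any `q`.
#'
#' @inheritParams partition_function
#' @return data frame with columns `line` (index into the skeleton) and
#'   `weight` (positive, summing to 1).
#' @export
boltzmann_weights <- function(skel, q, a) {
  j <- match_scale(skel$scales, a)
  lines <- which(skel$jmax >= j)
  if (!length(lines)) stop("no maxima lines present at a = ", a, " px")
  sup <- sup_matrix(skel)
  e <- q * log(sup[lines, j])
  data.frame(line = lines, weight = exp(e - log_sum_exp(e)))
}

#' Average partition functions over an ensemble of surfaces
#'
#' Combines per-surface partition functions into ensemble statistics.
#' `Z(q, a)` is always the arithmetic mean across surfaces (computed in
#' log space), whose log-slope equals that of the pooled sum.  For the
#' canonical averages two conventions are offered:
#'
#' * `pooled = FALSE` (default): plain arithmetic means of the
#'   per-surface `h(q, a)` and `D(q, a)`; the averaged curves combine
#'   independent realizations, which smooths the step-like single-line
#'   contributions that dominate extreme moments.
#' * `pooled = TRUE`: the surfaces form one canonical ensemble —
#'   Boltzmann weights are normalized by the pooled partition sum, so
#'   `h(q, a)` becomes the Z-weighted mean of the per-surface values
#'   and `D(q, a)` gains the corresponding mixture-entropy term
#'   (centred so that identical surfaces reproduce themselves).
#'
#' @param pf_list list of [partition_functions()] objects.
#' @param pooled combine surfaces into one canonical ensemble (see
#'   above).
#' @return a `partition_functions` object with `n_surfaces` set to the
#'   total number of surfaces averaged.
#' @export
ensemble_average <- function(pf_list, pooled = FALSE) {
  stopifnot(length(pf_list) >= 1L)
  ref <- pf_list[[1L]]
  for (pf in pf_list[-1L]) {
    if (!isTRUE(all.equal(pf$q, ref$q)) ||
        !isTRUE(all.equal(pf$scales, ref$scales))) {
      stop("ensemble members must share identical moment and scale grids")
    }
  }
  ns <- length(pf_list)
  dims <- c(length(ref$q), length(ref$scales))
  # mean of Z in log space: log2(mean Z) = LSE(log2 Z) - log2(n)
  l2z <- vapply(pf_list, function(p) p$log2_z, matrix(0, dims[1L], dims[2L]))
  mx <- apply(l2z, c(1L, 2L), max)
  log2_z <- mx + log2(apply(2^(l2z - rep(mx, ns)), c(1L, 2L), sum) / ns)
  if (pooled) {
    # surface weights w_s = Z_s / sum(Z_s) per (q, a) cell
    w <- 2^(l2z - rep(log2_z + log2(ns), ns))
    h3 <- vapply(pf_list, function(p) p$h_num, matrix(0, dims[1L], dims[2L]))
    d3 <- vapply(pf_list, function(p) p$D_num, matrix(0, dims[1L], dims[2L]))
    h_num <- apply(w * h3, c(1L, 2L), sum)
    # pooled entropy, centred by ln(ns) so identical inputs reproduce
    d3 <- w * (d3 + log(pmax(ns * w, 1e-300)))
    D_num <- apply(d3, c(1L, 2L), sum)
  } else {
    h_num <- Reduce(`+`, lapply(pf_list, `[[`, "h_num")) / ns
    D_num <- Reduce(`+`, lapply(pf_list, `[[`, "D_num")) / ns
  }
  structure(list(q = ref$q, scales = ref$scales, log2_z = log2_z,
                 h_num = h_num, D_num = D_num,
                 n_lines = Reduce(`+`, lapply(pf_list, `[[`,
                                              "n_lines")) / ns,
                 n_surfaces = sum(vapply(pf_list, `[[`, integer(1L),
                                         "n_surfaces"))),
            class = "partition_functions")
}

# Row-wise OLS of Y (rows) against x; returns slope and R^2 per row.
# A row with zero variance around its mean is a perfect zero-slope fit.
row_ols <- function(Y, x) {
  ok <- colSums(is.na(Y)) == 0
  x <- x[ok]; Y <- Y[, ok, drop = FALSE]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(Y %*% xc) / sxx
  fitted_c <- outer(slope, xc)
  Yc <- Y - rowMeans(Y)
  rss <- rowSums((Yc - fitted_c)^2)
  tss <- rowSums(Yc^2)
  r2 <- ifelse(tss < 1e-20, 1, 1 - rss / tss)
  list(slope = slope, r2 = pmin(pmax(r2, 0), 1), n = length(x),
       intercept = rowMeans(Y) - slope * mean(x))
}

#' Fit the multifractal spectra
#'
#' Least-squares fits over the scale window: `tau(q)` is the slope of
#' `log2 Z(q, a)` against `log2 a`; `h(q)` and `D(q)` are the slopes of
#' the canonical numerators `h(q, a)` and `D(q, a)` against `ln a`.
#' R-squared is recorded per moment, and the usable moment range is the
#' maximal contiguous run of `q` containing `q = 1` on which both the
#' `h` and `D` fits reach `r2_min`.
#'
#' @param pf a [partition_functions()] object (single surface or
#'   ensemble average).
#' @param fit_range scale window in pixels (default 17 to 56, the fixed
#'   calibration window).
#' @param r2_min power-law-quality threshold defining the usable range.
#' @return An object of class `mf_spectra`: list with `spectra` (data
#'   frame `q`, `tau`, `h`, `D`, `r2_tau`, `r2_h`, `r2_D`), `Dh` (data
#'   frame of `(h, D)` pairs), `usable_q` (length-2 vector, `NA` when
#'   even `q = 1` fails), `fit_range`, `n_scales`, `r2_min`.
#' @export
fit_spectra <- function(pf, fit_range = c(17, 56), r2_min = 0.99) {
  stopifnot(inherits(pf, "partition_functions"))
  sel <- which(pf$scales >= fit_range[1L] & pf$scales <= fit_range[2L] &
                 pf$n_lines > 0)
  if (length(sel) < 4L) {
    stop("need at least 4 scales with lines inside the fit window, have ",
         length(sel))
  }
  a <- pf$scales[sel]
  ft <- row_ols(pf$log2_z[, sel, drop = FALSE], log2(a))
  fh <- row_ols(pf$h_num[, sel, drop = FALSE], log(a))
  fd <- row_ols(pf$D_num[, sel, drop = FALSE], log(a))
  spectra <- data.frame(q = pf$q, tau = ft$slope, h = fh$slope,
                        D = fd$slope, r2_tau = ft$r2, r2_h = fh$r2,
                        r2_D = fd$r2)
  good <- spectra$r2_h >= r2_min & spectra$r2_D >= r2_min
  usable <- usable_range(pf$q, good, anchor = 1)
  structure(list(spectra = spectra,
                 Dh = data.frame(h = fh$slope, D = fd$slope),
                 usable_q = usable, fit_range = fit_range,
                 n_scales = length(sel), r2_min = r2_min),
            class = "mf_spectra")
}

# Maximal contiguous run of TRUE containing the grid point nearest to
# `anchor`; c(NA, NA) when that point itself fails.
usable_range <- function(q, good, anchor = 1) {
  i0 <- which.min(abs(q - anchor))
  if (!good[i0]) return(c(NA_real_, NA_real_))
  lo <- i0
  while (lo > 1L && good[lo - 1L]) lo <- lo - 1L
  hi <- i0
  while (hi < length(q) && good[hi + 1L]) hi <- hi + 1L
  c(q[lo], q[hi])
}

#' @export
print.mf_spectra <- function(x, ...) {
  cat(sprintf("mf_spectra: %d moments, fit window [%g, %g] px (%d scales)\n",
              nrow(x$spectra), x$fit_range[1L], x$fit_range[2L],
              x$n_scales))
  if (all(is.na(x$usable_q))) {
    cat("  usable q range: none (q = 1 fails the fit-quality rule)\n")
  } else {
    cat(sprintf("  usable q range: [%g, %g] (R^2 >= %g on h and D fits)\n",
                x$usable_q[1L], x$usable_q[2L], x$r2_min))
  }
  i <- which.min(abs(x$spectra$q - 2))
  cat(sprintf("  tau(2) = %.3f, h(q=2) = %.3f, D(q=2) = %.3f\n",
              x$spectra$tau[i], x$spectra$h[i], x$spectra$D[i]))
  invisible(x)
}

#' Hurst estimate from the tau(q) spectrum
#'
#' For a monofractal surface `tau(q) = qH - 2`; the least-squares slope
#' of `tau` against `q` over `q_window` estimates `H`, and the
#' intercept estimates the (negative) support codimension, -2.
#'
#' @param spectra an `mf_spectra` object.
#' @param q_window moment window for the linear fit (default `[-2, 2]`).
#' @return named vector with `H` (slope) and `intercept`.
#' @export
tau_slope <- function(spectra, q_window = c(-2, 2)) {
  s <- spectra$spectra
  sel <- s$q >= q_window[1L] & s$q <= q_window[2L]
  fit <- coef(lm(tau ~ q, data = s[sel, ]))
  c(H = unname(fit[2L]), intercept = unname(fit[1L]))
}

#' Legendre-transform consistency check
#'
#' The singularity spectrum can also be obtained as the Legendre
#' transform `D(h) = min_q (q h - tau(q))`.  This routine evaluates that
#' transform on the fitted `tau(q)` at each canonical `h(q')` and
#' returns the worst absolute disagreement with the canonical `D(q')`
#' over the interior moments.  It is a diagnostic cross-check; the
#' canonical route is the primary estimator precisely because the direct
#' transform is numerically fragile.
#'
#' @param spectra an `mf_spectra` object.
#' @return list with `max_dev` and a data frame `detail` (`q`, `h`,
#'   `D_canonical`, `D_legendre`).
#' @export
legendre_check <- function(spectra) {
  s <- spectra$spectra
  d_leg <- vapply(s$h, function(hh) min(s$q * hh - s$tau), numeric(1L))
  interior <- seq_len(nrow(s))[-c(1L, nrow(s))]
  list(max_dev = max(abs(d_leg[interior] - s$D[interior])),
       detail = data.frame(q = s$q, h = s$h, D_canonical = s$D,
                           D_legendre = d_leg))
}
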