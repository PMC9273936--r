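#' Dyadic scale grid
#'
#' Builds the log-equispaced analysis scales `a0 * 2^(j / voices)`,
#' j = 0, 1, ..., capped at `N / 6` so every scale keeps sufficient
#' spatial support inside an `N x N` image.  The default `a0 = 7` px with
#' 8 voices per octave reproduces the conventional "units of 7 * 2^a"
#' scale axis and brackets the printed example scales 20, 56 and 158 px.
#'
#' @param size image edge length N in pixels.
#' @param a0 smallest scale in pixels (>= 1).
#' @param voices voices per octave (integer >= 1).
#' @param fit_range scale window (pixels) used later for spectrum fits;
#'   a warning is recorded if fewer than 4 grid scales fall inside it.
#' @return An object of class `scale_grid`: list with `scales` (pixels,
#'   strictly increasing), `a0`, `voices`, `size`.
#' @examples
#' g <- scale_grid(1024)
#' range(g$scales)
#' @export
scale_grid <- function(size, a0 = 7, voices = 8L, fit_range = c(17, 56)) {
  if (a0 < 1) stop("a0 must be >= 1 pixel, got ", a0)
  if (voices < 1) stop("voices must be a positive integer")
  a_top <- size / 6
  if (a_top < a0) stop("image too small: no scale in [", a0, ", N/6 = ",
                       a_top, "]")
  jmax <- floor(voices * log2(a_top / a0))
  scales <- a0 * 2^((0:jmax) / voices)
  n_fit <- sum(scales >= fit_range[1L] & scales <= fit_range[2L])
  if (n_fit < 4L) {
    warning("only ", n_fit, " scales inside the fit window [",
            fit_range[1L], ", ", fit_range[2L], "] px")
  }
  structure(list(scales = scales, a0 = a0, voices = as.integer(voices),
                 size = as.integer(size)),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat(sprintf("scale_grid: %d scales, %.3g .. %.3g px (a0 = %g, %d voices/octave, N = %d)\n",
              length(x$scales), min(x$scales), max(x$scales),
              x$a0, x$voices, x$size))
  invisible(x)
}

# Radian FFT frequencies for an n-point axis.
fft_freq <- function(n) {
  2 * pi / n * c(0:(n / 2L - 1L), seq.int(-n / 2L, -1L))
}

# Precomputed spectral ingredients shared across scales of one surface.
# Simulated surfaces are periodic by construction; imported images are
# made periodic and continuous by symmetric (mirror) extension to 2N and
# cropped back after the transform.
#
# `noise_floor` models the finite arithmetic precision of a practical
# analysis pipeline: white noise with standard deviation noise_floor *
# sd(heights) is added to the analyzed copy of the surface (the surface
# object itself is untouched).  Everywhere the true response dominates
# this is invisible; inside exactly flat (saturated) regions, where the
# ideal response decays to nothing, it seeds the weak spurious maxima
# that real implementations produce there — the artifact population the
# rescue filters exist to remove.  The *number* of such maxima is set
# by the noise correlation structure, not its amplitude, so any small
# floor gives the same artifact-line counts; the default is the
# single-precision machine epsilon.  The noise is seeded from the
# surface seed (or a content hash), so results are reproducible.
cwt_plan <- function(surface, noise_floor = 2^-23) {
  h <- surface$heights
  n_out <- surface$size
  if (noise_floor > 0) {
    nseed <- if (!is.null(surface$seed)) {
      (surface$seed * 69069 + 1013904223) %% .Machine$integer.max
    } else {
      round(abs(sum(h)) * 1e3) %% .Machine$integer.max
    }
    h <- h + local_seed(nseed, {
      matrix(rnorm(length(h), sd = noise_floor * max(sd(h), 1e-300)),
             nrow(h), ncol(h))
    })
  }
  if (!surface$periodic) {
    idx <- c(seq_len(n_out), rev(seq_len(n_out)))
    h <- h[idx, idx]
  }
  n <- nrow(h)
  k <- fft_freq(n)
  list(fhat = fft(h),
       kx = matrix(k, n, n, byrow = FALSE),   # rows index x
       ky = matrix(k, n, n, byrow = TRUE),
       k2 = outer(k^2, k^2, "+"),
       n = n, n_out = n_out)
}

# Decimation factor for evaluating the scale-a field on a coarser grid:
# the transform is band-limited by exp(-a^2 k^2 / 2), so sampling every
# s <= a/4 pixels loses nothing (the spectrum at the folded frequencies
# is < exp(-70) of peak); powers of two keep the FFT sizes dyadic.
dec_factor <- function(a, n, min_grid = 64L) {
  s <- 2^max(0, floor(log2(a / 4)))
  while (s > 1 && n / s < min_grid) s <- s / 2
  as.integer(s)
}

# Transform pair at one scale, optionally spectrally decimated by s
# (exact sampling of the band-limited field at every s-th pixel) and
# optionally cropped to the original image for mirror-extended plans.
cwt_at_scale <- function(plan, a, s = 1L, crop = TRUE) {
  n <- plan$n
  if (s > 1L) {
    m <- n %/% s
    idx <- c(seq_len(m / 2L), seq.int(n - m / 2L + 1L, n))
    k <- fft_freq(n)[idx]
    kx <- matrix(k, m, m, byrow = FALSE)
    ky <- matrix(k, m, m, byrow = TRUE)
    fhat <- plan$fhat[idx, idx]
    scale_fac <- 1 / (n * n)
  } else {
    m <- n
    kx <- plan$kx; ky <- plan$ky
    fhat <- plan$fhat
    scale_fac <- 1 / (n * n)
  }
  k2 <- if (s > 1L) kx^2 + ky^2 else plan$k2
  damp <- 2 * pi * a * exp(-a^2 * k2 / 2)
  t1 <- Re(fft(fhat * (1i * kx * damp), inverse = TRUE)) * scale_fac
  t2 <- Re(fft(fhat * (1i * ky * damp), inverse = TRUE)) * scale_fac
  out_n <- m
  if (crop && plan$n_out < plan$n) {
    keep <- seq_len(plan$n_out %/% s)
    t1 <- t1[keep, keep]
    t2 <- t2[keep, keep]
    out_n <- length(keep)
  }
  mm <- sqrt(t1^2 + t2^2)
  structure(list(a = a, T1 = t1, T2 = t2, M = mm, A = atan2(t2, t1),
                 size = out_n, decimation = s),
            class = "wavelet_field")
}

#' Continuous 2D wavelet transform at one scale
#'
#' Computes the transform pair `(T1, T2)` of a surface against the
#' first-order analyzing wavelets `dG/dx` and `dG/dy`, where
#' `G(x) = exp(-|x|^2 / 2)` is the isotropic Gaussian, using the
#' L1-type `a^-2` scale normalization.  The convolution is periodic and
#' evaluated in the frequency domain with analytically dilated kernels
#' (`i a k 2pi exp(-a^2 |k|^2 / 2)`), so no spatial sampling bias enters
#' at small scales.  The sign convention makes `(T1, T2)` point along
#' the gradient of the Gaussian-smoothed surface: the argument `A` of a
#' rising ramp is 0, and for a smooth surface the modulus is
#' `~ 2 pi a |grad f|`.
#'
#' @param surface a [rough_surface()].
#' @param a analysis scale in pixels, in `[1, N/6]`.
#' @param noise_floor relative amplitude of the analysis noise floor
#'   (see [wt_skeleton()]); 0 here, i.e. the ideal transform.
#' @return An object of class `wavelet_field`: list with `a`, the fields
#'   `T1`, `T2`, the modulus `M = sqrt(T1^2 + T2^2)`, the argument
#'   `A = atan2(T2, T1)` in (-pi, pi], and `size`.
#' @examples
#' s <- fbm_surface(0.5, 64, seed = 3)
#' w <- cwt(s, 8)
#' max(abs(w$M^2 - (w$T1^2 + w$T2^2)))
#' @export
cwt <- function(surface, a, noise_floor = 0) {
  stopifnot(inherits(surface, "rough_surface"))
  if (a < 1) stop("scale a must be >= 1 pixel, got ", a)
  if (a > surface$size / 6) {
    stop("scale a = ", a, " px exceeds N/6 = ", surface$size / 6,
         " px: insufficient support")
  }
  cwt_at_scale(cwt_plan(surface, noise_floor = noise_floor), a)
}

#' @export
print.wavelet_field <- function(x, ...) {
  cat(sprintf("wavelet_field: scale a = %.4g px, %d x %d, max modulus %.4g\n",
              x$a, x$size, x$size, max(x$M)))
  invisible(x)
}
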