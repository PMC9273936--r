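#' Rough-surface container
#'
#' A `rough_surface` wraps a square matrix of real heights together with
#' its provenance: the Hurst exponent and seed used by the simulator (if
#' any) and the saturation record attached by [apply_saturation()].
#'
#' @param heights square numeric matrix of finite heights.  Rows index
#'   the x direction, columns the y direction (`heights[x + 1, y + 1]`);
#'   positions elsewhere in the package are 0-based `(x, y)` pixel
#'   coordinates.
#' @param hurst optional Hurst exponent in (0, 1) recorded as metadata.
#' @param seed optional integer seed recorded as metadata.
#' @param saturation optional saturation record (see [apply_saturation()]).
#' @param periodic logical; `TRUE` for simulated surfaces (the synthesis
#'   is periodic by construction), `FALSE` for imported images.
#'
#' @return An object of class `rough_surface`: a list with elements
#'   `heights`, `size`, `hurst`, `seed`, `saturation`, `periodic`.
#' @seealso [fbm_surface()], [apply_saturation()]
#' @export
rough_surface <- function(heights, hurst = NULL, seed = NULL,
                          saturation = NULL, periodic = FALSE) {
  heights <- as.matrix(heights)
  if (nrow(heights) != ncol(heights)) {
    stop("heights must be a square matrix, got ", nrow(heights), "x",
         ncol(heights))
  }
  if (!all(is.finite(heights))) {
    stop("heights must be finite everywhere")
  }
  if (!is.null(hurst) && (hurst <= 0 || hurst >= 1)) {
    stop("hurst must lie strictly inside (0, 1), got ", hurst)
  }
  structure(
    list(heights = heights, size = nrow(heights),
         hurst = hurst, seed = if (is.null(seed)) NULL else as.integer(seed),
         saturation = saturation, periodic = isTRUE(periodic)),
    class = "rough_surface")
}

#' @export
print.rough_surface <- function(x, ...) {
  cat(sprintf("rough_surface: %d x %d pixels, heights in [%.4g, %.4g]\n",
              x$size, x$size, min(x$heights), max(x$heights)))
  if (!is.null(x$hurst)) cat(sprintf("  fBm: H = %.3g, seed = %s\n", x$hurst,
                                     if (is.null(x$seed)) "none" else x$seed))
  if (!is.null(x$saturation)) {
    cat(sprintf("  saturated: level = %.3g, critical value = %.4g, achieved = %.4g\n",
                x$saturation$level, x$saturation$critical_value,
                x$saturation$achieved_fraction))
  }
  invisible(x)
}

#' Synthesize a fractional Brownian motion surface
#'
#' Generates an isotropic fBm surface by Fourier filtering: complex
#' Gaussian white noise is shaped in the frequency domain by the
#' amplitude `|k|^-(H+1)` (so the power spectrum falls off as
#' `|k|^-2(H+1)`), the DC component is zeroed, and the real part of the
#' inverse transform is taken.  The result is periodic by construction
#' and is linearly rescaled to the 8-bit-like range [0, 255], the
#' convention the default modulus-filter thresholds refer to.
#'
#' @param hurst Hurst roughness exponent, strictly inside (0, 1).
#' @param size edge length in pixels; a power of two, at least 64.
#' @param seed optional integer seed; the same seed reproduces the
#'   surface bit for bit and the caller's RNG state is left untouched.
#' @param normalize logical; rescale heights linearly to [0, 255]
#'   (default).  With `FALSE` the raw zero-mean field is returned.
#'
#' @return A [rough_surface()] with `hurst`, `seed` and `periodic = TRUE`.
#' @examples
#' s <- fbm_surface(0.7, 128, seed = 1)
#' range(s$heights)
#' @export
fbm_surface <- function(hurst, size, seed = NULL, normalize = TRUE) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1) {
    stop("hurst must be a single value strictly inside (0, 1), got ",
         format(hurst))
  }
  if (!is.numeric(size) || length(size) != 1L || size < 64 ||
      bitwAnd(as.integer(size), as.integer(size) - 1L) != 0L) {
    stop("size must be a power of two >= 64, got ", format(size))
  }
  n <- as.integer(size)
  kk <- c(0:(n / 2L - 1L), seq.int(-n / 2L, -1L))     # integer frequencies
  k2 <- outer(kk^2, kk^2, "+")
  amp <- k2^(-(hurst + 1) / 2)
  amp[1L, 1L] <- 0                                     # zero mean
  noise <- local_seed(seed, {
    matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  })
  field <- Re(fft(noise * amp, inverse = TRUE)) / (n * n)
  if (normalize) {
    rng <- range(field)
    field <- (field - rng[1L]) / (rng[2L] - rng[1L]) * 255
  } else {
    field <- field - mean(field)
  }
  rough_surface(field, hurst = hurst, seed = seed, periodic = TRUE)
}

#' Inject saturation into a surface
#'
#' Emulates sensor saturation: the critical height is the empirical
#' `(1 - level)`-quantile of the pixel values (inverse-CDF quantile), and
#' every pixel above it is clipped to that value, creating flat plateaus.
#' Pixels already exactly at the critical value are counted as saturated,
#' so the achieved fraction can exceed the requested level in the
#' presence of ties.
#'
#' @param surface a [rough_surface()].
#' @param level requested fraction of saturated pixels, strictly inside
#'   (0, 1).
#' @return A new `rough_surface` (the input is untouched) whose
#'   `saturation` element records `level`, `critical_value` and
#'   `achieved_fraction` (the fraction of pixels equal to the critical
#'   value after clipping; always `>= level`).
#' @examples
#' s <- fbm_surface(0.7, 128, seed = 1)
#' sat <- apply_saturation(s, 0.2)
#' sat$saturation$achieved_fraction
#' @export
apply_saturation <- function(surface, level) {
  stopifnot(inherits(surface, "rough_surface"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("saturation level must lie strictly inside (0, 1), got ",
         format(level))
  }
  h <- surface$heights
  if (max(h) == min(h)) {
    stop("surface is constant; saturation is undefined")
  }
  critical <- unname(quantile(h, probs = 1 - level, type = 1L))
  h[h > critical] <- critical
  spec <- list(level = level, critical_value = critical,
               achieved_fraction = mean(h == critical))
  rough_surface(h, hurst = surface$hurst, seed = surface$seed,
                saturation = spec, periodic = surface$periodic)
}

#' Isotropic second-order structure function
#'
#' Estimates `S2(delta) = mean[(f(x + delta) - f(x))^2]` over random
#' axis-aligned pixel pairs, the direct (wavelet-free) check that a
#' simulated surface carries the requested roughness: for fBm,
#' `log S2` vs `log delta` has slope `2H`.
#'
#' @param surface a [rough_surface()].
#' @param lags integer pixel offsets to probe.
#' @param n_pairs number of random pixel pairs per lag.
#' @param seed optional seed for the pair sampling.
#' @return data frame with columns `lag` and `s2`.
#' @export
structure_function <- function(surface, lags = 2^(1:6), n_pairs = 1e5,
                               seed = NULL) {
  stopifnot(inherits(surface, "rough_surface"))
  n <- surface$size
  h <- surface$heights
  local_seed(seed, {
    s2 <- vapply(lags, function(d) {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      horiz <- runif(n_pairs) < 0.5
      i2 <- ifelse(horiz, i, (i + d - 1L) %% n + 1L)
      j2 <- ifelse(horiz, (j + d - 1L) %% n + 1L, j)
      mean((h[cbind(i2, j2)] - h[cbind(i, j)])^2)
    }, numeric(1L))
    data.frame(lag = lags, s2 = s2)
  })
}

#' Radially averaged power spectrum
#'
#' Bins the 2D periodogram by integer radial frequency.  For fBm the
#' log-log slope of power against `k` is `-2(H + 1)`.
#'
#' @param surface a [rough_surface()].
#' @return data frame with columns `k` (radial integer frequency) and
#'   `power` (mean periodogram value in the bin), excluding DC.
#' @export
radial_spectrum <- function(surface) {
  stopifnot(inherits(surface, "rough_surface"))
  n <- surface$size
  p <- Mod(fft(surface$heights))^2 / (n * n)
  kk <- c(0:(n / 2L - 1L), seq.int(-n / 2L, -1L))
  kr <- round(sqrt(outer(kk^2, kk^2, "+")))
  keep <- kr > 0 & kr <= n / 2L
  pow <- tapply(p[keep], kr[keep], mean)
  data.frame(k = as.integer(names(pow)), power = as.numeric(pow))
}
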