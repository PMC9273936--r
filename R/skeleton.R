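#' Link WTMMM across scales into maxima lines
#'
#' Maxima lines are seeded at the smallest scale only (a line must point
#' to a singularity as the scale shrinks), then propagated upward: at
#' each scale transition the surviving lines are matched one-to-one to
#' the WTMMM of the next scale by greedy ascending-distance assignment,
#' with a search radius equal to the target scale (in pixels) and ties
#' broken by line id.  A line with no admissible unclaimed partner
#' terminates at its current scale; WTMMM left unclaimed at an upper
#' scale never seed new lines.
#'
#' @param wtmmm_list list, one element per grid scale, of WTMMM data
#'   frames (columns `x`, `y`, `modulus`) as produced by
#'   [detect_wtmm()] + [wtmmm_points()].
#' @param grid a [scale_grid()].
#' @param size image edge length in pixels.
#' @param periodic use toroidal distances when matching.
#' @param meta optional named list stored with the skeleton (surface
#'   provenance).
#' @return An object of class `wt_skeleton`: list with `scales`, the
#'   per-line record matrices `x`, `y`, `m` (lines by scales, `NA`
#'   beyond each line's termination), `jmax` (1-based index of the last
#'   scale of each line), `n_wtmmm` (WTMMM count per scale), `size`,
#'   `periodic`, `meta`.
#' @export
link_scales <- function(wtmmm_list, grid, size, periodic = TRUE,
                        meta = NULL) {
  stopifnot(inherits(grid, "scale_grid"))
  S <- length(grid$scales)
  stopifnot(length(wtmmm_list) == S)
  n0 <- nrow(wtmmm_list[[1L]])
  X <- Y <- M <- matrix(NA_real_, n0, S)
  jmax <- rep(1L, n0)
  if (n0 > 0L) {
    X[, 1L] <- wtmmm_list[[1L]]$x
    Y[, 1L] <- wtmmm_list[[1L]]$y
    M[, 1L] <- wtmmm_list[[1L]]$modulus
  }
  alive <- seq_len(n0)
  for (j in seq_len(S - 1L)) {
    if (!length(alive)) break
    cand <- wtmmm_list[[j + 1L]]
    nc <- nrow(cand)
    if (nc == 0L) break
    r2 <- grid$scales[j + 1L]^2
    dx <- abs(outer(X[alive, j], cand$x, "-"))
    dy <- abs(outer(Y[alive, j], cand$y, "-"))
    if (periodic) {
      dx <- pmin(dx, size - dx)
      dy <- pmin(dy, size - dy)
    }
    d2 <- dx * dx + dy * dy
    hit <- which(d2 <= r2)
    if (!length(hit)) break
    li <- (hit - 1L) %% length(alive) + 1L
    ci <- (hit - 1L) %/% length(alive) + 1L
    ord <- order(d2[hit], alive[li], ci)
    line_taken <- logical(length(alive))
    cand_taken <- logical(nc)
    for (t in ord) {
      i <- li[t]; k <- ci[t]
      if (!line_taken[i] && !cand_taken[k]) {
        line_taken[i] <- TRUE
        cand_taken[k] <- TRUE
        ln <- alive[i]
        X[ln, j + 1L] <- cand$x[k]
        Y[ln, j + 1L] <- cand$y[k]
        M[ln, j + 1L] <- cand$modulus[k]
        jmax[ln] <- j + 1L
      }
    }
    alive <- alive[line_taken]
  }
  structure(
    list(scales = grid$scales, x = X, y = Y, m = M, jmax = jmax,
         n_wtmmm = vapply(wtmmm_list, nrow, integer(1L)),
         size = as.integer(size), periodic = isTRUE(periodic),
         meta = meta),
    class = "wt_skeleton")
}

#' Build the space-scale skeleton of a surface
#'
#' Runs the full maxima pipeline: continuous wavelet transform at every
#' grid scale, WTMM detection, modulus maxima along the chains (WTMMM),
#' and cross-scale linking into maxima lines ([link_scales()]).
#'
#' @param surface a [rough_surface()].
#' @param grid a [scale_grid()]; built from `a0` and `voices` when `NULL`.
#' @param a0,voices scale-grid parameters used when `grid` is `NULL`.
#' @param floor_frac modulus noise floor passed to [detect_wtmm()].
#' @param frac WTMMM suppression radius as a fraction of the scale, see
#'   [wtmmm_points()].
#' @param decimate evaluate large scales on a spectrally decimated grid
#'   (exact for the band-limited transform; sampling step capped at
#'   `a / 8` pixels).  Positions are then quantized to the sampling
#'   step, well below the linking radius.
#' @param noise_floor relative amplitude of the analysis noise floor,
#'   emulating the finite arithmetic precision of practical pipelines
#'   (default: single-precision epsilon, `2^-23`).  Irrelevant wherever
#'   the surface is rough, but inside exactly flat saturated plateaus it
#'   seeds the weak spurious maxima lines that saturation is known to
#'   inject into the skeleton; with an ideal infinite-precision
#'   transform (0) flat regions yield no response at all and the
#'   saturation artifact cannot be studied.
#' @return A `wt_skeleton`; see [link_scales()].
#' @examples
#' \donttest{
#' s <- fbm_surface(0.7, 256, seed = 2)
#' sk <- wt_skeleton(s)
#' n_lines(sk)
#' }
#' @export
wt_skeleton <- function(surface, grid = NULL, a0 = 7, voices = 8L,
                        floor_frac = 1e-12, frac = 0.5, decimate = TRUE,
                        noise_floor = 2^-23,
                        probe = c("bilinear", "rounded")) {
  stopifnot(inherits(surface, "rough_surface"))
  probe <- match.arg(probe)
  if (is.null(grid)) grid <- scale_grid(surface$size, a0, voices)
  plan <- cwt_plan(surface, noise_floor = noise_floor)
  wtmmm <- lapply(grid$scales, function(a) {
    s <- if (decimate) dec_factor(a, plan$n) else 1L
    fld <- cwt_at_scale(plan, a, s = s, crop = FALSE)
    mm <- wtmmm_points(detect_wtmm(fld, floor_frac, probe), size = fld$size,
                       a = a / s, frac = frac)
    if (s > 1L) {
      mm$x <- mm$x * s
      mm$y <- mm$y * s
    }
    if (!surface$periodic) {
      mm <- mm[mm$x < surface$size & mm$y < surface$size, , drop = FALSE]
    }
    attr(mm, "scale") <- a
    attr(mm, "size") <- surface$size
    mm
  })
  meta <- list(hurst = surface$hurst, seed = surface$seed,
               saturation = surface$saturation)
  link_scales(wtmmm, grid, size = surface$size,
              periodic = surface$periodic, meta = meta)
}

#' @export
print.wt_skeleton <- function(x, ...) {
  cat(sprintf("wt_skeleton: %d maxima lines over %d scales (%.3g .. %.3g px), %d x %d image\n",
              n_lines(x), length(x$scales), min(x$scales), max(x$scales),
              x$size, x$size))
  invisible(x)
}

#' Number of maxima lines in a skeleton
#' @param skel a `wt_skeleton`.
#' @return integer line count.
#' @export
n_lines <- function(skel) nrow(skel$m)

#' Maxima-line count per scale
#' @param skel a `wt_skeleton`.
#' @return integer vector `|L(a)|`, the number of lines still present at
#'   each grid scale.
#' @export
lines_per_scale <- function(skel) {
  vapply(seq_along(skel$scales),
         function(j) sum(skel$jmax >= j), integer(1L))
}

# Keep only the given line rows.
subset_skeleton <- function(skel, idx) {
  out <- skel
  out$x <- skel$x[idx, , drop = FALSE]
  out$y <- skel$y[idx, , drop = FALSE]
  out$m <- skel$m[idx, , drop = FALSE]
  out$jmax <- skel$jmax[idx]
  out
}

#' Sheaf of a skeleton
#'
#' Strips the positional information from the skeleton and keeps, for
#' every maxima line, its curve of `(log2 a, log2 M)` pairs.  The slopes
#' of these curves estimate the Holder exponents of the singularities
#' the lines point to.
#'
#' @param skel a `wt_skeleton`.
#' @return data frame (class `wt_sheaf`) with columns `line`, `scale`
#'   (pixels), `log2_a`, `log2_m`.
#' @export
compute_sheaf <- function(skel) {
  stopifnot(inherits(skel, "wt_skeleton"))
  S <- length(skel$scales)
  nl <- n_lines(skel)
  line <- rep(seq_len(nl), times = S)
  scale <- rep(skel$scales, each = nl)
  m <- as.vector(skel$m)
  ok <- !is.na(m)
  out <- data.frame(line = line[ok], scale = scale[ok],
                    log2_a = log2(scale[ok]), log2_m = log2(m[ok]))
  out <- out[order(out$line, out$scale), ]
  rownames(out) <- NULL
  class(out) <- c("wt_sheaf", "data.frame")
  out
}

#' @export
as.data.frame.wt_skeleton <- function(x, ...) {
  S <- length(x$scales)
  nl <- n_lines(x)
  d <- data.frame(line = rep(seq_len(nl), times = S),
                  scale_index = rep(seq_len(S), each = nl),
                  scale = rep(x$scales, each = nl),
                  x = as.vector(x$x), y = as.vector(x$y),
                  modulus = as.vector(x$m))
  d <- d[!is.na(d$modulus), ]
  d <- d[order(d$line, d$scale_index), ]
  rownames(d) <- NULL
  d
}

#' Persist / load a skeleton
#'
#' The on-disk layout (format version 1) is a long-format CSV with
#' columns `line`, `scale_index`, `scale`, `x`, `y`, `modulus` plus a
#' JSON sidecar `<path>.json` holding the scale grid, image size,
#' periodicity flag, provenance metadata and format version.
#'
#' @param skel a `wt_skeleton`.
#' @param path output CSV path.
#' @return `path` invisibly (`write_skeleton`); a `wt_skeleton`
#'   (`read_skeleton`).
#' @export
write_skeleton <- function(skel, path) {
  stopifnot(inherits(skel, "wt_skeleton"))
  write.csv(as.data.frame(skel), path, row.names = FALSE)
  meta <- list(format = "wtmm2d-skeleton", version = 1L,
               scales = skel$scales, size = skel$size,
               periodic = skel$periodic, n_wtmmm = skel$n_wtmmm,
               meta = skel$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "wtmm2d-skeleton")) {
    stop("not a skeleton container: ", path)
  }
  d <- read.csv(path)
  S <- length(meta$scales)
  nl <- if (nrow(d)) max(d$line) else 0L
  X <- Y <- M <- matrix(NA_real_, nl, S)
  ij <- cbind(d$line, d$scale_index)
  X[ij] <- d$x; Y[ij] <- d$y; M[ij] <- d$modulus
  jmax <- if (nl) vapply(seq_len(nl), function(l) {
    max(d$scale_index[d$line == l])
  }, integer(1L)) else integer(0)
  structure(
    list(scales = meta$scales, x = X, y = Y, m = M, jmax = jmax,
         n_wtmmm = meta$n_wtmmm, size = meta$size,
         periodic = isTRUE(meta$periodic),
         meta = if (length(meta$meta)) meta$meta else NULL),
    class = "wt_skeleton")
}
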