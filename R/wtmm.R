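# Bilinear interpolation of a periodic field at fractional 0-based
# (px, py) positions; rows of M index x, columns y.  Linear-index
# arithmetic keeps this fast on whole-grid inputs.
interp_periodic <- function(M, px, py) {
  n <- nrow(M)
  x0 <- floor(px); y0 <- floor(py)
  fx <- px - x0; fy <- py - y0
  wrap <- function(i) {
    i[i < 0] <- i[i < 0] + n
    i[i >= n] <- i[i >= n] - n
    i
  }
  ix0 <- wrap(x0); ix1 <- wrap(x0 + 1)
  iy0 <- n * wrap(y0); iy1 <- n * wrap(y0 + 1)
  (1 - fx) * ((1 - fy) * M[ix0 + iy0 + 1] + fy * M[ix0 + iy1 + 1]) +
    fx * ((1 - fy) * M[ix1 + iy0 + 1] + fy * M[ix1 + iy1 + 1])
}

#' Detect wavelet transform modulus maxima (WTMM)
#'
#' A grid point is a WTMM when its modulus is at least as large as the
#' bilinearly interpolated modulus one pixel away on either side along
#' the argument direction `(cos A, sin A)`, with strict inequality on at
#' least one side.  Points with modulus below `floor_frac` times the
#' field maximum are discarded as numerical noise (this removes the
#' machine-epsilon ripple inside exactly flat regions).
#'
#' @param field a `wavelet_field` from [cwt()].
#' @param floor_frac relative modulus floor (default `1e-12`).
#' @param probe how the two comparison points along the argument
#'   direction are evaluated: `"bilinear"` interpolates the modulus at
#'   the exact off-grid positions `b +- (cos A, sin A)`; `"rounded"`
#'   compares against the 8-neighbour pair nearest to the argument
#'   direction, the discrete non-maximum suppression used by the
#'   classic C implementations of this method.
#' @return data frame of WTMM points with columns `x`, `y` (0-based
#'   pixels), `modulus`, `argument`; attributes `scale` and `size`.
#'   May have zero rows (e.g. for a constant image).
#' @export
detect_wtmm <- function(field, floor_frac = 1e-12,
                        probe = c("bilinear", "rounded")) {
  stopifnot(inherits(field, "wavelet_field"))
  probe <- match.arg(probe)
  M <- field$M
  n <- field$size
  keep <- which(M > floor_frac * max(M))
  out <- if (length(keep)) {
    x <- (keep - 1L) %% n
    y <- (keep - 1L) %/% n
    ang <- field$A[keep]
    m0 <- M[keep]
    if (probe == "bilinear") {
      ux <- cos(ang); uy <- sin(ang)
      mp <- interp_periodic(M, x + ux, y + uy)
      mm <- interp_periodic(M, x - ux, y - uy)
    } else {
      sect <- (round(ang / (pi / 4)) %% 8) + 1
      dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)[sect]
      dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)[sect]
      at <- function(xx, yy) M[((xx %% n) + n * (yy %% n)) + 1L]
      mp <- at(x + dx, y + dy)
      mm <- at(x - dx, y - dy)
    }
    ok <- m0 >= mp & m0 >= mm & (m0 > mp | m0 > mm)
    data.frame(x = x[ok], y = y[ok], modulus = m0[ok], argument = ang[ok])
  } else {
    data.frame(x = integer(), y = integer(), modulus = numeric(),
               argument = numeric())
  }
  attr(out, "scale") <- field$a
  attr(out, "size") <- n
  out
}

# 8-neighbourhood offsets (half set; both directions are implied).
.half_offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))

# Neighbour row lookup among a point set for one (dx, dy) offset.
neighbor_match <- function(points, size, dx, dy, periodic = TRUE) {
  nx <- points$x + dx
  ny <- points$y + dy
  if (periodic) {
    nx <- nx %% size
    ny <- ny %% size
  }
  key <- points$y * size + points$x
  match(ny * size + nx, key)
}

#' Group WTMM points into maxima chains
#'
#' The WTMM of a scale lie on connected edge curves.  Chains are the
#' 8-connected components of the point set; each chain is returned in
#' traversal order (depth-first from an endpoint, or from an arbitrary
#' point for a closed loop).  Singleton components are kept as
#' degenerate one-point chains.
#'
#' @param points WTMM data frame from [detect_wtmm()].
#' @param size image edge length in pixels (defaults to the `size`
#'   attribute of `points`).
#' @param periodic treat the grid as a torus when testing adjacency.
#' @return list of data frames (columns as in `points`), each with
#'   attributes `closed` (`TRUE` for a simple cycle) and `scale`.
#' @export
chain_wtmm <- function(points, size = attr(points, "size"), periodic = TRUE) {
  np <- nrow(points)
  if (np == 0L) return(list())
  edges <- integer(0)
  for (off in .half_offsets) {
    j <- neighbor_match(points, size, off[1L], off[2L], periodic)
    i <- which(!is.na(j))
    if (length(i)) edges <- c(edges, rbind(i, j[i]))
  }
  g <- igraph::make_graph(edges, n = np, directed = FALSE)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  lapply(seq_len(comp$no), function(ci) {
    vs <- which(comp$membership == ci)
    ord <- if (length(vs) > 1L) {
      ends <- vs[deg[vs] <= 1L]
      root <- if (length(ends)) min(ends) else min(vs)
      o <- igraph::dfs(g, root = root, unreachable = FALSE)$order
      o <- as.integer(o)
      o[!is.na(o)]
    } else {
      vs
    }
    ch <- points[ord, , drop = FALSE]
    rownames(ch) <- NULL
    attr(ch, "closed") <- length(vs) > 2L && min(deg[vs]) >= 2L
    attr(ch, "scale") <- attr(points, "scale")
    attr(ch, "size") <- size
    ch
  })
}

#' Modulus maxima along a maxima chain (WTMMM)
#'
#' Retains the chain points whose modulus is at least that of both
#' chain neighbours (the single neighbour at the open ends; wrapping for
#' closed chains).  A plateau run of equal retained moduli contributes
#' only its first point in traversal order, so a closed constant chain
#' yields exactly one representative.  A singleton chain yields its
#' point.
#'
#' @param chain one chain from [chain_wtmm()] (or any data frame with a
#'   `modulus` column in traversal order, optionally with a `closed`
#'   attribute).
#' @return the retained rows of `chain`.
#' @export
detect_wtmmm <- function(chain) {
  m <- chain$modulus
  L <- length(m)
  if (L == 0L) return(chain)
  if (L == 1L) return(chain)
  closed <- isTRUE(attr(chain, "closed"))
  left <- if (closed) c(m[L], m[-L]) else c(-Inf, m[-L])
  right <- if (closed) c(m[-1L], m[1L]) else c(m[-1L], -Inf)
  keep <- m >= left & m >= right
  idx <- which(keep)
  if (!length(idx)) return(chain[integer(0), , drop = FALSE])
  # first representative of each plateau run of adjacent equal moduli
  new_run <- c(TRUE, !(idx[-1L] == idx[-length(idx)] + 1L &
                         m[idx[-1L]] == m[idx[-length(idx)]]))
  reps <- idx[new_run]
  # on a closed chain a run ending at L and a run starting at 1 with the
  # same modulus are one wrapped plateau: keep only the run-1 representative
  if (closed && length(reps) > 1L &&
      idx[1L] == 1L && idx[length(idx)] == L && m[1L] == m[L]) {
    reps <- reps[-length(reps)]
  }
  out <- chain[reps, , drop = FALSE]
  rownames(out) <- NULL
  for (at in c("closed", "scale", "size")) {
    attr(out, at) <- attr(chain, at)
  }
  out
}

# Circular shift along rows: row i of the result is row i - d of M.
shift_rows <- function(M, d) {
  n <- nrow(M)
  M[((seq_len(n) - 1L - d) %% n) + 1L, , drop = FALSE]
}

# Periodic sliding maximum over the (2r+1)^2 Chebyshev window, built by
# max-doubling along each axis (O(log r) full-matrix passes).
max_filter <- function(M, r) {
  w <- 2L * r + 1L
  slide <- function(G) {
    covered <- 1L
    while (covered < w) {
      s <- min(covered, w - covered)
      G <- pmax(G, shift_rows(G, -s))
      covered <- covered + s
    }
    shift_rows(G, r)
  }
  t(slide(t(slide(M))))
}

#' Modulus maxima of one scale (WTMMM), resolution-matched
#'
#' Reduces the WTMM of a scale to the modulus maxima that seed and
#' propagate maxima lines: a point is retained when its modulus is the
#' largest among all WTMM points within a Chebyshev radius of
#' `max(1, round(frac * a))` pixels.  At `frac * a <= 1` this is the
#' 8-neighbourhood local-maximum rule; at larger scales the suppression
#' radius grows with the analyzing wavelet, which matches the modulus
#' correlation length along the chains and keeps one representative per
#' resolvable structure (pixel-resolution comparison alone lets chain
#' fragmentation and discretization ripple inflate the maxima
#' population at large scales, breaking the `a^-2` line-density
#' scaling).
#'
#' @param points WTMM data frame from [detect_wtmm()].
#' @param size image edge length in pixels.
#' @param a scale in pixels (defaults to the `scale` attribute of
#'   `points`).
#' @param frac suppression radius as a fraction of the scale
#'   (default 0.5, i.e. a window of one wavelet width).
#' @return the retained rows of `points`, same attributes.
#' @export
wtmmm_points <- function(points, size = attr(points, "size"),
                         a = attr(points, "scale"), frac = 0.5) {
  np <- nrow(points)
  if (np <= 1L) return(points)
  r <- max(1L, as.integer(round(a * frac)))
  Mm <- matrix(-Inf, size, size)
  Mm[cbind(points$x + 1L, points$y + 1L)] <- points$modulus
  mf <- max_filter(Mm, r)
  keep <- points$modulus >= mf[cbind(points$x + 1L, points$y + 1L)]
  out <- points[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale") <- a
  attr(out, "size") <- size
  out
}
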