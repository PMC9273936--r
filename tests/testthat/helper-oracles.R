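# Independent brute-force oracles used across the suite.  These are
# deliberately slow and simple; they share no code with the package
# implementations they check.

# Direct spatial quadrature of the gradient-pointing transform at one
# position b = (bx, by) (0-based), truncating the kernel at |u| <= 8a.
oracle_cwt_point <- function(heights, bx, by, a) {
  n <- nrow(heights)
  r <- ceiling(8 * a)
  off <- -r:r
  xs <- (bx + off) %% n
  ys <- (by + off) %% n
  ux <- matrix(-off / a, length(off), length(off))   # (b - x)/a
  uy <- t(ux)
  g <- exp(-(ux^2 + uy^2) / 2)
  f <- heights[xs + 1L, ys + 1L]
  # psi1 = dG/dx evaluated at (b - x)/a
  t1 <- sum(-ux * g * f) / a^2
  t2 <- sum(-uy * g * f) / a^2
  c(T1 = t1, T2 = t2, M = sqrt(t1^2 + t2^2), A = atan2(t2, t1))
}

# Exhaustive directional-maximum test (loop + scalar bilinear interp).
oracle_wtmm <- function(field, floor_frac = 1e-12) {
  M <- field$M; A <- field$A; n <- field$size
  bil <- function(px, py) {
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    ix <- c(x0, x0 + 1) %% n + 1
    iy <- c(y0, y0 + 1) %% n + 1
    (1 - fx) * (1 - fy) * M[ix[1], iy[1]] + fx * (1 - fy) * M[ix[2], iy[1]] +
      (1 - fx) * fy * M[ix[1], iy[2]] + fx * fy * M[ix[2], iy[2]]
  }
  flo <- floor_frac * max(M)
  out <- NULL
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    m0 <- M[x + 1, y + 1]
    if (m0 <= flo) next
    aa <- A[x + 1, y + 1]
    m1 <- bil(x + cos(aa), y + sin(aa))
    m2 <- bil(x - cos(aa), y - sin(aa))
    if (m0 >= m1 && m0 >= m2 && (m0 > m1 || m0 > m2)) {
      out <- rbind(out, c(x, y, m0))
    }
  }
  out
}

# Connected components of a 0-based point set under 8-adjacency
# (periodic), by iterative label propagation.
oracle_components <- function(x, y, size, periodic = TRUE) {
  np <- length(x)
  lab <- seq_len(np)
  repeat {
    changed <- FALSE
    for (i in seq_len(np)) for (j in seq_len(np)) {
      dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
      if (periodic) {
        dx <- min(dx, size - dx); dy <- min(dy, size - dy)
      }
      if (dx <= 1 && dy <= 1 && lab[j] < lab[i]) {
        lab[i] <- lab[j]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, sort(unique(lab)))
}

# Brute-force local maxima (>= both neighbours, plateau-first) of a
# modulus sequence along an open or closed chain.
oracle_chain_maxima <- function(m, closed = FALSE) {
  L <- length(m)
  if (L == 1L) return(1L)
  nb <- function(i) {
    out <- c(i - 1L, i + 1L)
    if (closed) ((out - 1L) %% L) + 1L else out[out >= 1L & out <= L]
  }
  keep <- vapply(seq_len(L), function(i) all(m[i] >= m[nb(i)]), logical(1L))
  reps <- integer(0)
  i <- 1L
  while (i <= L) {
    if (!keep[i]) { i <- i + 1L; next }
    j <- i
    while (j < L && keep[j + 1L] && m[j + 1L] == m[i]) j <- j + 1L
    reps <- c(reps, i)
    i <- j + 1L
  }
  # closed chain: a plateau wrapping the origin is a single run
  if (closed && length(reps) > 1L && keep[1L] && keep[L] && m[1L] == m[L]) {
    reps <- reps[-length(reps)]
  }
  reps
}

# A synthetic skeleton with iid random moduli and random termination
# scales (no power-law structure) for oracle checks.
random_skeleton <- function(n_lines, scales, seed) {
  S <- length(scales)
  withr::with_seed(seed, {
    jmax <- sample(seq_len(S), n_lines, replace = TRUE, prob = (S:1)^1.5)
    m <- matrix(NA_real_, n_lines, S)
    for (l in seq_len(n_lines)) {
      m[l, seq_len(jmax[l])] <- exp(rnorm(jmax[l], mean = 3, sd = 1))
    }
    zeros <- matrix(0, n_lines, S)
    zeros[is.na(m)] <- NA_real_
    structure(list(scales = scales, x = zeros, y = zeros, m = m,
                   jmax = jmax, n_wtmmm = colSums(!is.na(m)),
                   size = NA_integer_, periodic = TRUE, meta = NULL),
              class = "wt_skeleton")
  })
}

# Cusp surface |x - x0|^h with a mild angular modulation (heights in
# [0, 255]).  The modulation breaks the rotational degeneracy of the
# modulus-maximum ring around the tip — a perfectly isotropic cusp has
# no preferred maximum, so its representative flips sides between
# scales — without changing the Holder exponent at the tip.
cusp_field <- function(h, n, cx, cy, eps = 0.3, dir = "x") {
  xy <- 0:(n - 1)
  dx <- outer(xy - cx, rep(1, n))
  dy <- outer(rep(1, n), xy - cy)
  r <- sqrt(dx^2 + dy^2)
  u <- if (dir == "x") dx else dy
  ct <- ifelse(r > 0, u / r, 0)
  r^h * (1 + eps * ct)
}

cusp_surface <- function(h, n = 512) {
  f <- cusp_field(h, n, n / 2, n / 2)
  rough_surface(255 * (1 - f / max(f)), periodic = TRUE)
}

# The maxima line tracking a cusp at (cx, cy): the line nearest the tip
# at the smallest scale among those that span the whole fit window.
cusp_line <- function(sk, cx, cy, jtop, d_max = 30) {
  d0 <- sqrt((sk$x[, 1L] - cx)^2 + (sk$y[, 1L] - cy)^2)
  cand <- which(d0 < d_max & sk$jmax >= jtop)
  if (!length(cand)) return(integer(0))
  cand[order(d0[cand])]
}

angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
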