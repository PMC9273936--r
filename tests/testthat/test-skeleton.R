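test_that("an isolated cusp is tracked by a single window-spanning line", {
  g <- scale_grid(512)
  jtop <- max(which(g$scales <= 56))
  s <- cusp_surface(0.5)
  sk <- wt_skeleton(s, g, noise_floor = 0)
  cand <- cusp_line(sk, 256, 256, jtop)
  expect_length(cand, 1L)
  # the line stays near the tip (the modulus-maximum ring radius grows
  # with the scale, so the allowance is proportional to a)
  line <- cand[1L]
  dx <- sqrt((sk$x[line, ] - 256)^2 + (sk$y[line, ] - 256)^2)
  ok <- !is.na(dx)
  expect_true(all(dx[ok] <= 1.5 * sk$scales[ok] + 3))
})

test_that("two distant cusps give two disjoint window-spanning lines", {
  n <- 512
  # anisotropy perpendicular to the separation axis keeps the mutual
  # background ramps from biasing either cusp's dominant direction
  f <- cusp_field(0.5, n, 128, 256, dir = "y") +
    cusp_field(0.5, n, 384, 256, dir = "y")
  s <- rough_surface(255 * (1 - f / max(f)), periodic = TRUE)
  g <- scale_grid(n)
  jtop <- max(which(g$scales <= 56))
  sk <- wt_skeleton(s, g, noise_floor = 0)
  l1 <- cusp_line(sk, 128, 256, jtop)
  l2 <- cusp_line(sk, 384, 256, jtop)
  expect_gte(length(l1), 1L)
  expect_gte(length(l2), 1L)
  expect_length(intersect(l1, l2), 0L)
})

test_that("linking respects the search radius and never births mid-scale", {
  g <- structure(list(scales = c(4, 8, 16), a0 = 4, voices = 1L,
                      size = 128L), class = "scale_grid")
  mk <- function(x = numeric(0), y = numeric(0), m = numeric(0)) {
    data.frame(x = x, y = y, modulus = m)
  }
  # second-scale candidates beyond radius 8 from the seed: line ends
  wl <- list(mk(10, 10, 5), mk(30, 10, 5), mk(31, 10, 5))
  sk <- link_scales(wl, g, size = 128)
  expect_equal(n_lines(sk), 1L)
  expect_equal(sk$jmax, 1L)
  # within radius: the line follows the nearest candidate; the far
  # unclaimed candidate does not seed a new line
  wl2 <- list(mk(10, 10, 5), mk(c(16, 50), c(10, 50), c(4, 9)),
              mk(20, 12, 6))
  sk2 <- link_scales(wl2, g, size = 128)
  expect_equal(n_lines(sk2), 1L)
  expect_equal(sk2$jmax, 3L)
  expect_equal(sk2$x[1L, ], c(10, 16, 20))
  # greedy one-to-one: two lines compete for one candidate
  wl3 <- list(mk(c(10, 14), c(10, 10), c(5, 5)), mk(12, 10, 7), mk())
  sk3 <- link_scales(wl3, g, size = 128)
  expect_equal(n_lines(sk3), 2L)
  expect_equal(sort(sk3$jmax), c(1L, 2L))
})

test_that("line counts never increase with scale and records are WTMMM", {
  s <- fbm_surface(0.5, 256, seed = 13)
  g <- scale_grid(256)
  plan <- wtmm2d:::cwt_plan(s)
  sk <- wt_skeleton(s, g)
  expect_true(all(diff(lines_per_scale(sk)) <= 0))
  expect_true(all(sk$jmax >= 1L))
  expect_true(all(!is.na(sk$m[, 1L])))   # every line starts at scale 1
  # every record at the smallest scale is a detected WTMMM of that field
  fld <- wtmm2d:::cwt_at_scale(plan, g$scales[1L])
  mm <- wtmmm_points(detect_wtmm(fld), size = 256, a = g$scales[1L])
  expect_true(all(paste(sk$x[, 1L], sk$y[, 1L]) %in% paste(mm$x, mm$y)))
})

test_that("sheaf curves carry the Holder exponent of cusp singularities", {
  g <- scale_grid(512)
  sel <- g$scales >= 17 & g$scales <= 56
  jtop <- max(which(g$scales <= 56))
  for (h in c(0.3, 0.7)) {
    sk <- wt_skeleton(cusp_surface(h), g, noise_floor = 0)
    line <- cusp_line(sk, 256, 256, jtop)[1L]
    expect_false(is.na(line))
    slope <- unname(coef(lm(log2(sk$m[line, sel]) ~
                              log2(g$scales[sel])))[2L])
    expect_lt(abs(slope - h), 0.05)
  }
})

test_that("sheaf extraction strips positions and keeps exact curves", {
  scales <- 7 * 2^((0:8) / 8)
  sk <- make_fixture_skeleton(list(list(n = 1, h = 0.7, c = 2)), scales)
  sh <- compute_sheaf(sk)
  fit <- lm(log2_m ~ log2_a, sh)
  expect_equal(unname(coef(fit)[2L]), 0.7, tolerance = 1e-10)
  expect_equal(nrow(sh), length(scales))

  empty <- make_fixture_skeleton(list(list(n = 1, h = 0.5, c = 1)), scales)
  empty$m <- empty$m[0, , drop = FALSE]
  empty$x <- empty$x[0, , drop = FALSE]
  empty$y <- empty$y[0, , drop = FALSE]
  empty$jmax <- integer(0)
  expect_equal(nrow(compute_sheaf(empty)), 0L)
})
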