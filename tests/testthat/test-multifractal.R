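scales9 <- 7 * 2^((0:8) / 8)

test_that("running supremum equals the brute-force prefix maximum", {
  sk <- random_skeleton(100, scales9, seed = 21)
  for (l in c(1, 7, 42, 100)) {
    for (j in seq_len(sk$jmax[l])) {
      expect_equal(sup_modulus(sk, l, scales9[j]),
                   max(sk$m[l, 1:j]))
    }
  }
  expect_error(sup_modulus(sk, which.min(sk$jmax), max(scales9) * 2),
               "grid scale|terminates")
  # hand cases
  skh <- make_fixture_skeleton(list(list(n = 1, h = 0, c = 1)), c(1, 2, 4))
  skh$m[1, ] <- c(4, 2, 8)
  expect_equal(sup_modulus(skh, 1, 2), 4)
  expect_equal(sup_modulus(skh, 1, 4), 8)
})

test_that("partition function matches direct summation", {
  sk <- random_skeleton(5, scales9, seed = 3)
  sup <- t(apply(sk$m, 1L, cummax))
  for (q in c(-2, -1, 1, 2)) for (j in c(1, 3, 5)) {
    alive <- sk$jmax >= j
    if (!any(alive)) next
    expect_equal(partition_function(sk, q, scales9[j]),
                 sum(sup[alive, j]^q), tolerance = 1e-12)
  }
  # q = 0 counts lines; a single line with sup 2 at q = 3 gives 8
  expect_equal(partition_function(sk, 0, scales9[1L]), 5)
  one <- make_fixture_skeleton(list(list(n = 1, h = 0, c = 2)), scales9)
  expect_equal(partition_function(one, 3, scales9[4L]), 8)
})

test_that("Boltzmann weights normalize and match direct powers", {
  sk <- random_skeleton(50, scales9, seed = 5)
  for (q in c(-3, -0.5, 0, 1, 4)) for (j in c(1, 4, 8)) {
    w <- boltzmann_weights(sk, q, scales9[j])
    expect_equal(sum(w$weight), 1, tolerance = 1e-10)
    expect_true(all(w$weight > 0))
    sup <- vapply(w$line, function(l) max(sk$m[l, 1:j]), numeric(1L))
    expect_equal(w$weight, sup^q / sum(sup^q), tolerance = 1e-10)
  }
  # q = 0: uniform; two lines with sup 2 and 4 at q = 1: weights 1/3, 2/3
  w0 <- boltzmann_weights(sk, 0, scales9[1L])
  expect_equal(w0$weight, rep(1 / 50, 50))
  two <- make_fixture_skeleton(list(list(n = 2, h = 0, c = c(2, 4))),
                               scales9)
  expect_equal(boltzmann_weights(two, 1, scales9[3L])$weight, c(1, 2) / 3)
})

test_that("partition-function arrays satisfy the structural invariants", {
  sk <- random_skeleton(80, scales9, seed = 9)
  pf <- partition_functions(sk)
  # Z(0, a) equals the number of surviving lines (where any survive)
  pop <- pf$n_lines > 0
  expect_equal(2^pf$log2_z[pf$q == 0, pop], as.numeric(pf$n_lines[pop]),
               tolerance = 1e-9)
  expect_true(all(pf$D_num[!is.na(pf$D_num)] <= 1e-12))
  expect_equal(pf$n_lines, lines_per_scale(sk))
})

test_that("ensemble averaging reduces to the stated elementary cases", {
  sk <- make_fixture_skeleton(list(list(n = 10, h = 0.5,
                                        c = function(n) exp(rnorm(n)))),
                              scales9)
  pf <- partition_functions(sk)
  for (pooled in c(FALSE, TRUE)) {
    avg <- ensemble_average(list(pf, pf, pf), pooled = pooled)
    expect_equal(avg$log2_z, pf$log2_z, tolerance = 1e-10)
    expect_equal(avg$h_num, pf$h_num, tolerance = 1e-10)
    expect_equal(avg$D_num, pf$D_num, tolerance = 1e-10)
  }
  # mean of Z: two surfaces with Z = 2 and 4 average to 3
  pf2 <- pf; pf2$log2_z[] <- 1; pf2b <- pf; pf2b$log2_z[] <- 2
  expect_equal(2^ensemble_average(list(pf2, pf2b))$log2_z[1L, 1L], 3)
  # streaming-mean oracle over replicates
  pfs <- lapply(1:8, function(r) {
    partition_functions(random_skeleton(40, scales9, seed = 100 + r))
  })
  avg <- ensemble_average(pfs, pooled = FALSE)
  hm <- Reduce(`+`, lapply(pfs, `[[`, "h_num")) / 8
  expect_equal(avg$h_num, hm, tolerance = 1e-12)
  expect_error(ensemble_average(list(pf, partition_functions(sk, q = 0:3))),
               "identical")
})

test_that("exact power-law skeletons yield exact spectra", {
  scales_fit <- 7 * 2^((0:24) / 8)
  sk <- make_fixture_skeleton(
    list(list(n = 100, h = 0.7, c = function(n) exp(rnorm(n, 0, 0.5)))),
    scales_fit)
  sp <- fit_spectra(partition_functions(sk), fit_range = c(17, 56))
  expect_lt(max(abs(sp$spectra$h - 0.7)), 1e-6)
  expect_lt(max(abs(sp$spectra$tau - 0.7 * sp$spectra$q -
                      (sp$spectra$tau[sp$spectra$q == 0]))), 1e-6)
  expect_true(all(sp$spectra$r2_h >= 0.999))
  expect_equal(sp$usable_q, c(-3, 5))
  # D(q) follows the line-count decay: families terminating dyadically
  fams <- lapply(1:5, function(k) {
    list(n = 2^(6 - k), h = 0.5, c = 1, jmax = 5 * k)
  })
  skd <- make_fixture_skeleton(fams, scales_fit)
  pfd <- partition_functions(skd, q = 0)
  sel <- scales_fit >= 17 & scales_fit <= 56
  slope_n <- coef(lm(log(pfd$n_lines[sel]) ~ log(scales_fit[sel])))[2L]
  spd <- fit_spectra(pfd, fit_range = c(17, 56))
  expect_equal(spd$spectra$D[1L], -unname(slope_n), tolerance = 0.15)
})

test_that("two-family skeleton interpolates h(q) between exponents", {
  scales_fit <- 7 * 2^((0:24) / 8)
  a_top <- max(scales_fit)
  # amplitudes anchored at the top scale: strong singularities (small h)
  # dominate the small-scale moduli
  sk <- make_fixture_skeleton(
    list(list(n = 60, h = 0.3, c = 100 * a_top^-0.3),
         list(n = 60, h = 0.7, c = 100 * a_top^-0.7)),
    scales_fit)
  pf <- partition_functions(sk)
  sp <- fit_spectra(pf, fit_range = c(17, 56))
  h <- sp$spectra$h
  expect_true(all(diff(h) <= 1e-9))          # non-increasing in q
  expect_lt(h[length(h)] - 0.3, 0.1)         # q >> 0 -> rough family
  expect_gt(h[1L], 0.6)                      # q << 0 -> smooth family
  # closed-form two-term oracle at a probe (q, a)
  qq <- 2; j <- 15
  m1 <- 100 * a_top^-0.3 * scales_fit[j]^0.3
  m2 <- 100 * a_top^-0.7 * scales_fit[j]^0.7
  z <- 60 * m1^qq + 60 * m2^qq
  expect_equal(2^pf$log2_z[pf$q == qq, j], z, tolerance = 1e-9)
  h_ora <- (60 * m1^qq * log(m1) + 60 * m2^qq * log(m2)) / z
  expect_equal(pf$h_num[pf$q == qq, j], h_ora, tolerance = 1e-9)
})

test_that("Legendre transform agrees with the canonical spectra", {
  # exactly linear tau with constant h: plug-in gives D = 2 everywhere
  q <- seq(-3, 5, 0.5)
  sp <- structure(list(spectra = data.frame(
    q = q, tau = 0.5 * q - 2, h = 0.5, D = 2,
    r2_tau = 1, r2_h = 1, r2_D = 1)), class = "mf_spectra")
  lc <- legendre_check(sp)
  expect_equal(max(abs(lc$detail$D_legendre - 2)), 0, tolerance = 1e-12)
  expect_equal(lc$max_dev, 0, tolerance = 1e-12)
  # concave tau keeps the transform well-defined on the grid
  sp$spectra$tau <- 0.5 * q - 2 - 0.02 * q^2
  expect_true(all(diff(diff(sp$spectra$tau)) <= 1e-12))
  expect_true(is.finite(legendre_check(sp)$max_dev))
})

test_that("spectrum fitting rejects under-determined windows", {
  sk <- make_fixture_skeleton(list(list(n = 5, h = 0.5, c = 1)),
                              c(18, 24, 32))
  expect_error(fit_spectra(partition_functions(sk), fit_range = c(17, 56)),
               "at least 4 scales")
})
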