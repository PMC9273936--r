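scalesA <- 7 * 2^((0:16) / 8)

# skeleton with hand-set modulus trajectories
manual_skeleton <- function(m_list, scales = scalesA) {
  S <- length(scales)
  m <- do.call(rbind, lapply(m_list, function(v) c(v, rep(NA, S - length(v)))))
  zeros <- matrix(0, nrow(m), S)
  zeros[is.na(m)] <- NA
  structure(list(scales = scales, x = zeros, y = zeros, m = m,
                 jmax = vapply(m_list, length, integer(1L)),
                 n_wtmmm = colSums(!is.na(m)), size = NA_integer_,
                 periodic = TRUE, meta = NULL),
            class = "wt_skeleton")
}

test_that("adjusted slope follows the log2 start/end formula", {
  sk <- manual_skeleton(list(
    c(2^6, 2^5, 2^4),        # (6 - 4)/4 = 0.5
    c(2^8, 2^8, 2^8),        # 0
    c(2^5, 2^4),             # (5 - 4)/4 = 0.25
    c(2^6),                  # single record: undefined
    c(2^3, 0.5)))            # degenerate denominator: undefined
  ma <- adjusted_slope(sk)
  expect_equal(ma[1:3], c(0.5, 0, 0.25))
  expect_true(all(is.na(ma[4:5])))
})

test_that("pruning applies inclusive MF then SF, labels partition lines", {
  sk <- manual_skeleton(list(
    c(16, 20, 30),            # M_first == MF: removed by MF (inclusive)
    c(16, 2, 1),              # would satisfy both: counted under MF only
    c(17, 2^4, 2^4),          # m_adj = (log2 17 - 4)/4 < 0.5: kept
    c(2^6, 2^5, 2^4),         # m_adj = 0.5 == SF: removed by SF (inclusive)
    c(2^8, 2^9, 2^10),        # healthy: kept
    c(64, 32),                # single... two records, rising denominator fine
    c(24, 0.5),               # denominator degenerate, declining: SF
    c(0.9, 1.5),              # degenerate, rising: kept (M_first <= 16 tho)
    c(18)))                   # single record above MF: kept
  pr <- prune_skeleton(sk, mf = 16, sf = 0.5)
  lab <- as.character(pr$labels)
  expect_equal(lab[1:2], c("removed_MF", "removed_MF"))
  expect_equal(lab[3], "kept")
  expect_equal(lab[4], "removed_SF")
  expect_equal(lab[5], "kept")
  expect_equal(lab[7], "removed_SF")
  expect_equal(lab[8], "removed_MF")   # 0.9 <= 16
  expect_equal(lab[9], "kept")
  expect_equal(sum(pr$counts), n_lines(sk))
  expect_equal(sum(pr$pct), 100, tolerance = 1e-9)
  expect_equal(n_lines(pr$skeleton), sum(lab == "kept"))
  # original untouched
  expect_equal(n_lines(sk), 9L)
})

test_that("a no-op filter keeps everything and preserves spectra", {
  sk <- make_fixture_skeleton(
    list(list(n = 50, h = 0.6, c = function(n) 30 * exp(rnorm(n, 0, 0.3)))),
    7 * 2^((0:24) / 8))
  pr <- prune_skeleton(sk, mf = 1e-12, sf = Inf)
  expect_equal(as.integer(pr$counts), c(50L, 0L, 0L))
  sp0 <- fit_spectra(partition_functions(sk))
  sp1 <- fit_spectra(partition_functions(pr$skeleton))
  expect_equal(sp1$spectra, sp0$spectra, tolerance = 1e-12)
})

test_that("removal report percentages are exact and ensemble-averaged", {
  m_list <- c(
    replicate(10, c(1, 1, 1), simplify = FALSE),       # MF fodder
    replicate(20, c(2^9, 2^5, 2^4), simplify = FALSE), # m_adj = 1.25: SF
    replicate(170, c(2^7, 2^8, 2^9), simplify = FALSE))
  sk <- manual_skeleton(m_list)
  pr <- prune_skeleton(sk, mf = 16, sf = 0.5)
  rep1 <- removal_report(pr)
  expect_equal(rep1$pct_MF, 5)
  expect_equal(rep1$pct_SF, 10)
  expect_equal(rep1$pct_MF + rep1$pct_SF + rep1$pct_kept, 100)
  reps <- removal_report(list(pr, pr))
  expect_equal(nrow(reps), 3L)
  expect_equal(reps$pct_MF[3L], 5)
  expect_error(removal_report(list()), "length")
})

test_that("a whole fixture family below MF is removed exactly", {
  sk <- make_fixture_skeleton(
    list(list(n = 30, h = 0.5, c = 0.01),
         list(n = 70, h = 0.5, c = 50)),
    scalesA)
  pr <- prune_skeleton(sk, mf = 16, sf = 0.5)
  expect_equal(as.character(pr$labels[1:30]), rep("removed_MF", 30))
  expect_equal(pr$pct[2L], 30)
})

test_that("modulus-filter registry matches the calibrated table", {
  expect_equal(mf_for_hurst(0.7), 16)
  expect_equal(mf_for_hurst(0.5), 48)
  expect_equal(mf_for_hurst(0.3), 96)
  expect_equal(mf_for_hurst(0.1), 192)
  expect_warning(mid <- mf_for_hurst(0.6), "interpolating")
  expect_true(mid > 16 && mid < 48)
  expect_warning(out <- mf_for_hurst(0.9), "outside")
  expect_equal(out, 16)
})

test_that("modulus recalibration quantile-matches the clean tail", {
  sk <- manual_skeleton(replicate(200, c(2^7, 2^8), simplify = FALSE))
  sk$m[1:2, 1L] <- c(1, 2)    # exactly 1% of lines below
  thr <- recalibrate_mf(sk, keep_frac = 0.99)
  expect_lte(mean(sk$m[, 1L] <= thr), 0.01)
  expect_equal(thr, 2)        # the 1% empirical quantile
  # rescaling moduli rescales the threshold linearly
  expect_equal(recalibrate_mf(rescale_skeleton(sk, 4)), 4 * thr)
})
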