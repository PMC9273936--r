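#' Construct a synthetic skeleton with exact power-law lines
#'
#' Builds a `wt_skeleton` directly from line-family descriptions,
#' bypassing any wavelet transform: family `f` contributes `n` lines
#' whose modulus records are exactly `M(a) = c * a^h` up to the family's
#' termination scale.  Used to exercise the partition-function,
#' spectrum-fit and pruning machinery against closed-form expectations.
#'
#' @param families list of family descriptions; each a list with
#'   elements `n` (line count), `h` (power-law exponent), `c` (amplitude
#'   prefactor: a scalar, a vector of length `n`, or a function of `n`
#'   returning one draw per line) and optionally `jmax` (1-based
#'   termination scale index; defaults to the top scale).
#' @param scales analysis scales in pixels (strictly increasing).
#' @return a `wt_skeleton` whose positions are all zero.
#' @examples
#' sk <- make_fixture_skeleton(
#'   list(list(n = 50, h = 0.7, c = 2)),
#'   scales = 7 * 2^((0:16) / 8))
#' @export
make_fixture_skeleton <- function(families, scales) {
  if (!length(families)) stop("at least one line family is required")
  if (is.unsorted(scales, strictly = TRUE)) {
    stop("scales must be strictly increasing")
  }
  S <- length(scales)
  rows <- lapply(families, function(f) {
    stopifnot(is.numeric(f$n), f$n >= 1)
    jm <- if (is.null(f$jmax)) S else as.integer(f$jmax)
    stopifnot(jm >= 1L, jm <= S)
    cc <- if (is.function(f$c)) f$c(f$n) else rep_len(f$c, f$n)
    m <- matrix(NA_real_, f$n, S)
    m[, seq_len(jm)] <- outer(cc, scales[seq_len(jm)]^f$h)
    list(m = m, jmax = rep(jm, f$n))
  })
  m <- do.call(rbind, lapply(rows, `[[`, "m"))
  jmax <- unlist(lapply(rows, `[[`, "jmax"))
  zeros <- matrix(0, nrow(m), S)
  zeros[is.na(m)] <- NA_real_
  structure(list(scales = scales, x = zeros, y = zeros, m = m,
                 jmax = jmax, n_wtmmm = colSums(!is.na(m)),
                 size = NA_integer_, periodic = TRUE,
                 meta = list(fixture = TRUE)),
            class = "wt_skeleton")
}
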