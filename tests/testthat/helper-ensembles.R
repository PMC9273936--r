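# Shared fBm calibration ensembles for the acceptance checks.  Built
# lazily and cached for the session, so several test blocks can reuse
# the same ensembles.  Sizes follow the calibration design (1024 px,
# a0 = 7, 8 voices/octave, fit window 17-56 px) with 4 replicates per
# condition to keep the suite within a desk-scale runtime.

.ens_cache <- new.env(parent = emptyenv())

ens_seed_base <- 1L
ens_n <- 4L
ens_size <- 1024L

ens_grid <- function() {
  key <- "grid"
  if (is.null(.ens_cache[[key]])) {
    .ens_cache[[key]] <- scale_grid(ens_size)
  }
  .ens_cache[[key]]
}

# Clean ensemble for one Hurst value: per-surface partition functions
# on unit-aligned skeletons, plus the alignment factor kappa and the
# clean pruning percentages.
ens_clean <- function(hurst) {
  key <- sprintf("clean_H%g", hurst)
  if (is.null(.ens_cache[[key]])) {
    g <- ens_grid()
    mf_h <- suppressWarnings(mf_for_hurst(hurst))
    skels <- lapply(seq_len(ens_n), function(r) {
      wt_skeleton(fbm_surface(hurst, ens_size,
                              seed = ens_seed_base + r - 1L), g)
    })
    kappa <- mf_h / recalibrate_mf(skels)
    skels <- lapply(skels, rescale_skeleton, kappa = kappa)
    prs <- lapply(skels, prune_skeleton, mf = mf_h, sf = 0.5)
    .ens_cache[[key]] <- list(
      kappa = kappa, mf = mf_h,
      pf = lapply(skels, partition_functions),
      pf_pruned = lapply(prs, function(p) partition_functions(p$skeleton)),
      pct = rowMeans(vapply(prs, `[[`, numeric(3L), "pct")))
  }
  .ens_cache[[key]]
}

# Saturated ensemble (H = 0.7) at one level: raw and rescued partition
# functions plus ensemble-mean removal percentages, in the clean
# ensemble's modulus units.
ens_saturated <- function(level) {
  key <- sprintf("sat_%g", level)
  if (is.null(.ens_cache[[key]])) {
    g <- ens_grid()
    cl <- ens_clean(0.7)
    skels <- lapply(seq_len(ens_n), function(r) {
      s <- fbm_surface(0.7, ens_size, seed = ens_seed_base + r - 1L)
      rescale_skeleton(wt_skeleton(apply_saturation(s, level), g),
                       cl$kappa)
    })
    prs <- lapply(skels, prune_skeleton, mf = cl$mf, sf = 0.5)
    .ens_cache[[key]] <- list(
      pf_raw = lapply(skels, partition_functions),
      pf_rescued = lapply(prs, function(p) partition_functions(p$skeleton)),
      pct = rowMeans(vapply(prs, `[[`, numeric(3L), "pct")))
  }
  .ens_cache[[key]]
}
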