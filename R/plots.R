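#' Plot a sheaf, optionally annotated with pruning labels
#'
#' Draws the `log2 M` vs `log2 a` curve of every maxima line.  When a
#' [prune_skeleton()] result is supplied, curves removed by the modulus
#' filter are red, those removed by the slope filter green, and the
#' kept lines black.
#'
#' @param x a `wt_skeleton`; for the three-colour annotated version use
#'   [plot_pruned_sheaf()] with the parent skeleton and its pruning.
#' @param alpha line transparency.
#' @param max_lines cap on the number of lines drawn (sampled without
#'   replacement when exceeded) to keep plots light.
#' @return a ggplot object.
#' @export
plot_sheaf <- function(x, alpha = 0.2, max_lines = 2000L) {
  stopifnot(inherits(x, "wt_skeleton"))
  sheaf <- compute_sheaf(x)
  keep <- sample_lines(sheaf$line, max_lines)
  sheaf <- sheaf[sheaf$line %in% keep, ]
  ggplot2::ggplot(sheaf,
                  ggplot2::aes(x = .data$log2_a, y = .data$log2_m,
                               group = .data$line)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.2) +
    ggplot2::labs(x = expression(log[2] ~ a ~ "(pixels)"),
                  y = expression(log[2] ~ M)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_sheaf
#' @param skel the original (unpruned) `wt_skeleton`.
#' @param pruned the [prune_skeleton()] result obtained from `skel`.
#' @export
plot_pruned_sheaf <- function(skel, pruned, alpha = 0.2,
                              max_lines = 2000L) {
  stopifnot(inherits(skel, "wt_skeleton"),
            inherits(pruned, "pruned_skeleton"),
            length(pruned$labels) == n_lines(skel))
  sheaf <- compute_sheaf(skel)
  sheaf$label <- pruned$labels[sheaf$line]
  keep <- sample_lines(sheaf$line, max_lines)
  sheaf <- sheaf[sheaf$line %in% keep, ]
  ggplot2::ggplot(sheaf,
                  ggplot2::aes(x = .data$log2_a, y = .data$log2_m,
                               group = .data$line,
                               colour = .data$label)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.2) +
    ggplot2::scale_colour_manual(
      values = c(kept = "black", removed_MF = "red",
                 removed_SF = "green3"),
      name = NULL) +
    ggplot2::labs(x = expression(log[2] ~ a ~ "(pixels)"),
                  y = expression(log[2] ~ M)) +
    ggplot2::theme_minimal()
}

sample_lines <- function(line_ids, max_lines) {
  ids <- unique(line_ids)
  if (length(ids) <= max_lines) return(ids)
  sample(ids, max_lines)
}

#' Plot fitted multifractal spectra
#'
#' @param spectra an `mf_spectra` object (or a named list of them, drawn
#'   together for comparison).
#' @param which one of `"tau"`, `"h"`, `"D"`, `"Dh"`.
#' @return a ggplot object.
#' @export
plot_spectra <- function(spectra, which = c("h", "tau", "D", "Dh")) {
  which <- match.arg(which)
  if (inherits(spectra, "mf_spectra")) spectra <- list(spectra = spectra)
  d <- do.call(rbind, lapply(names(spectra), function(nm) {
    s <- spectra[[nm]]$spectra
    s$set <- nm
    s
  }))
  if (which == "Dh") {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$h, y = .data$D,
                                         colour = .data$set)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::labs(x = "h", y = "D(h)")
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data[[which]],
                                         colour = .data$set)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::labs(x = "q", y = switch(which, tau = "tau(q)",
                                        h = "h(q)", D = "D(q)"))
  }
  p + ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = if (length(spectra) > 1L)
      "bottom" else "none")
}

#' @importFrom rlang .data
NULL
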