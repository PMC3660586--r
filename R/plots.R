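# ggplot2 displays for fitted mixtures and scan profiles.

#' Plot six-generation phenotype distributions
#'
#' Histograms of plant-level values, one facet per generation.
#'
#' @param data Phenotype tibble (`generation`, `value`).
#' @param binwidth Histogram bin width (default 10, the RGB class width).
#' @return A ggplot object.
#' @export
plot_generations <- function(data, binwidth = 10) {
  data <- validate_phenotypes(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white") +
    ggplot2::facet_wrap(~generation, scales = "free_y") +
    ggplot2::labs(x = "phenotype value", y = "plants") +
    ggplot2::theme_minimal()
}

#' Autoplot a segregation fit
#'
#' Overlays the fitted mixture density on the per-generation histograms.
#'
#' @param object A `seg_fit`.
#' @param binwidth Histogram bin width.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot seg_fit
#' @export
autoplot.seg_fit <- function(object, binwidth = 10, ...) {
  data <- object$data
  comps <- object$components
  grid <- dplyr::bind_rows(lapply(unique(comps$generation), function(g) {
    cg <- comps[comps$generation == g, ]
    xg <- data$value[data$generation == g]
    xs <- seq(min(xg) - 10, max(xg) + 10, length.out = 200)
    dens <- rowSums(vapply(seq_len(nrow(cg)), function(j) {
      cg$frequency[j] * stats::dnorm(xs, cg$mean[j], sqrt(cg$variance[j]))
    }, numeric(length(xs))))
    tibble::tibble(generation = g, value = xs, density = dens)
  }))
  grid$generation <- factor(grid$generation, levels = seg_generations())
  ggplot2::ggplot(data, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth, fill = "grey80",
                            colour = "white") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$density), colour = "#2c7fb8") +
    ggplot2::facet_wrap(~generation, scales = "free") +
    ggplot2::labs(x = "phenotype value", y = "density",
                  title = paste("Fitted mixture, model", object$model)) +
    ggplot2::theme_minimal()
}

#' Autoplot a QTL scan profile
#'
#' LOD along each linkage group, optionally with the genome-wide threshold.
#'
#' @param object A `qtl_scan`.
#' @param threshold Optional LOD threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$position, y = .data$lod)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}
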