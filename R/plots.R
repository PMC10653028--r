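# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_line
#'   labs theme_minimal scale_color_manual
NULL

#' @rdname pca_qc
#' @param object A `merip_pca` object.
#' @export
autoplot.merip_pca <- function(object, ...) {
  v <- object$variance$var_fraction
  ggplot(object$scores, aes(.data$PC1, .data$PC2,
                            color = .data$condition)) +
    geom_point(size = 3) +
    labs(x = sprintf("PC1 (%.0f%%)", 100 * v[1]),
         y = sprintf("PC2 (%.0f%%)",
                     100 * ifelse(length(v) > 1, v[2], 0)),
         title = "Sample PCA on log2 normalized peak IP counts") +
    theme_minimal()
}

#' Volcano plot of the consensus differential-methylation result
#'
#' Corrected methylation LFC against the Wald-test evidence, colored by
#' the direction call of the filtering cascade.
#'
#' @param dm A [consensus_and_filter()] result.
#' @return A ggplot object.
#' @export
plot_volcano <- function(dm) {
  d <- dm[!is.na(dm$p_wald), ]
  d$neglog10p <- -log10(pmax(d$p_wald, 1e-300))
  ggplot(d, aes(.data$lfc_meth_corrected, .data$neglog10p,
                color = .data$direction)) +
    geom_point(alpha = 0.6, size = 1) +
    scale_color_manual(values = c(hyper_condA = "#4575b4",
                                  hyper_condB = "#d73027",
                                  none = "grey70")) +
    labs(x = "corrected methylation log2FC",
         y = "-log10 p (Wald interaction)",
         title = "Differential m6A peaks") +
    theme_minimal()
}

#' Bar chart of the filtering cascade
#'
#' @param dm A [consensus_and_filter()] result.
#' @return A ggplot object.
#' @export
plot_cascade <- function(dm) {
  cascade <- cascade_summary(dm)
  cascade$stage <- factor(cascade$stage, levels = cascade$stage)
  ggplot(cascade, aes(.data$stage, .data$n_peaks)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "peaks", title = "Filtering cascade") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Peak location-category distribution plot
#'
#' @param locdist A [location_distribution()] result.
#' @return A ggplot object.
#' @export
plot_location_distribution <- function(locdist) {
  ggplot(locdist, aes(.data$group, .data$proportion,
                      fill = .data$category)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "proportion of peaks",
         title = "Peak location categories") +
    theme_minimal()
}

#' @rdname fit_half_life
#' @param object A `decay_fit` object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  ggplot(object$data, aes(.data$time_h, .data$fraction)) +
    geom_point(size = 2) +
    geom_line(aes(y = .data$fitted), color = "firebrick") +
    labs(x = "time after actinomycin D (h)", y = "fraction remaining",
         title = if (object$stable) "stable transcript" else
           sprintf("t1/2 = %.2f h", object$t_half)) +
    theme_minimal()
}
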