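#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a codebook as a bit heatmap
#'
#' @param object A `codebook`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.codebook <- function(object, ...) {
  m <- codeword_matrix(object)
  df <- tidyr::expand_grid(codeword = seq_len(nrow(m)),
                           bit = seq_len(ncol(m)))
  df$on <- as.vector(t(m)) == 1
  df$kind <- ifelse(object$is_blank[df$codeword], "blank",
                    ifelse(is.na(object$name[df$codeword]), "unused",
                           "target"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bit, y = .data$codeword,
                                   fill = .data$on)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey95")) +
    ggplot2::labs(x = "bit", y = "codeword",
                  title = sprintf("%d-bit weight-%d codebook (%d codewords)",
                                  attr(object, "n_bits"),
                                  attr(object, "weight"), nrow(m))) +
    ggplot2::theme_minimal()
}

#' Plot a zone map
#'
#' @param object A `zone_map`.
#' @param ... Unused.
#' @return A ggplot of the per-bin zone labels.
#' @export
autoplot.zone_map <- function(object, ...) {
  df <- tidyr::expand_grid(bx = seq_len(object$n_bins),
                           by = seq_len(object$n_bins))
  df$zone <- object$zone[cbind(df$bx, df$by)]
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bx - 0.5) * object$bin_um,
    y = (.data$by - 0.5) * object$bin_um, fill = .data$zone
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(pericentral = "#7b3294",
                                          periportal = "#008837")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "zone") +
    ggplot2::theme_minimal()
}

#' Plot ranked energy distances
#'
#' @param object An `edist_result`.
#' @param ... Unused.
#' @return A ggplot ranking groups by energy distance, significant
#'   groups highlighted.
#' @export
autoplot.edist_result <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object),
                       dplyr::desc(.data$statistic))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$statistic,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "perturbation rank", y = "energy distance vs control",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot the misidentification-score distributions
#'
#' @param molecules Decoded molecules with a `score` column (from
#'   [apply_adaptive_threshold()]).
#' @return A ggplot of score densities for blank- and coding-assigned
#'   molecules.
#' @export
plot_misid_scores <- function(molecules) {
  df <- dplyr::filter(molecules, .data$outcome %in% c("target", "blank"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   fill = .data$outcome)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::labs(x = "classifier score (P coding)", y = "molecules",
                  fill = "assignment") +
    ggplot2::theme_minimal()
}

#' Plot simulated tissue colored by zonal coordinate
#'
#' @param screen A `sim_screen`.
#' @return A ggplot of cell positions colored by z.
#' @export
plot_tissue <- function(screen) {
  ggplot2::ggplot(screen$cells, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$z)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  colour = "zonal z\n(0 = pericentral)") +
    ggplot2::theme_minimal()
}
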