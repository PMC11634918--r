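#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a motor-distance matrix
#'
#' @param object A `motor_dist` object.
#' @param ... Unused.
#' @return A ggplot heatmap with subjects ordered as in the matrix.
#' @method autoplot motor_dist
#' @export
autoplot.motor_dist <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    subject1 = factor(rep(rownames(v), times = ncol(v)), levels = rownames(v)),
    subject2 = factor(rep(colnames(v), each = nrow(v)),
                      levels = rev(colnames(v))),
    distance = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$subject1, .data$subject2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "motor\ndistance",
                  title = paste0(toupper(object$method), " distances, ",
                                 object$condition)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatterplot of an MDS embedding
#'
#' @param object A `motor_mds` object.
#' @param ... Unused.
#' @return A ggplot of the first two embedding dimensions coloured by
#'   group.
#' @method autoplot motor_mds
#' @export
autoplot.motor_mds <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("MDS embedding (stress = ",
                                 signif(object$stress, 3), ")")) +
    ggplot2::theme_minimal()
}

#' Robustness curve plot
#'
#' @param object A `robustness_curve` object.
#' @param ... Unused.
#' @return A ggplot of ICC(A,1) against the fraction of removed trials.
#' @method autoplot robustness_curve
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fraction, .data$icc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "trials removed", y = "ICC (absolute agreement)") +
    ggplot2::theme_minimal()
}

#' Kinematic profiles of ranked neighbours
#'
#' Plots the FPT wv/wa/wj profiles of a reference subject together with its
#' flagged neighbours (nearest, 33rd percentile, 66th percentile,
#' farthest), the standard way to see what the motor distance responds to.
#'
#' @param fpt FPT tibble from [fpt_trials()].
#' @param D The matching `motor_dist` object.
#' @param reference Reference subject label.
#' @return A ggplot faceted by kinematic variable.
#' @export
plot_neighbour_profiles <- function(fpt, D, reference) {
  rk <- rank_neighbours(D, reference)
  flagged <- rk[!is.na(rk$flag), c("subject", "flag")]
  sel <- dplyr::bind_rows(
    tibble::tibble(subject = reference, flag = "reference"), flagged)
  df <- dplyr::inner_join(fpt, sel, by = "subject")
  df$flag <- factor(df$flag,
                    levels = c("reference", "nearest", "p33", "p66",
                               "farthest"))
  df$variable <- factor(df$variable, levels = c("wv", "wa", "wj"),
                        labels = c("WV (mm/s)", "WA (mm/s²)",
                                   "WJ (mm/s³)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$timepoint, .data$mean,
                                   colour = .data$flag)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = seq(2, 10, 2)) +
    ggplot2::labs(x = "normalized time point", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
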