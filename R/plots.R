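#' Plot a pipeline report
#'
#' Raw versus adjusted chromosome Z-scores with the call threshold.
#'
#' @param object A `nipt_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nipt_report <- function(object, ...) {
  df <- object$chromosomes |>
    tidyr::pivot_longer(c("raw_z", "adjusted_z"), names_to = "stage",
                        values_to = "z") |>
    dplyr::mutate(stage = factor(.data$stage, c("raw_z", "adjusted_z"),
                                 c("raw", "adjusted")))
  thr <- object$chromosomes$threshold[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$z,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "chromosome Z-score", fill = NULL,
                  title = sprintf("sample %s", object$sample_id)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient-versus-effect agreement plot
#'
#' Scatter of the analytic coverage coefficient against the empirical
#' coverage ratio from paired simulations, with the identity line the two
#' should fall on.
#'
#' @param cells Output of [summarize_alpha_effect()].
#' @return A ggplot object.
#' @export
plot_alpha_agreement <- function(cells) {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$alpha, y = .data$mean_ratio,
                                      colour = factor(.data$f))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "coefficient α (truth parameters)",
                  y = "empirical coverage ratio", colour = "fetal fraction") +
    ggplot2::theme_minimal()
}

#' Z-score curves across maternal CNV sizes
#'
#' The signature pattern of the maternal-CNV adjustment: raw Z-scores of a
#' euploid fetus grow with CNV size (solid), adjusted Z-scores stay flat
#' near 0 (dashed).
#'
#' @param grid_z Output of [grid_zscores()] in `"full"` mode.
#' @return A ggplot object.
#' @export
plot_z_curves <- function(grid_z) {
  df <- grid_z |>
    dplyr::group_by(.data$chrom, .data$direction, .data$f, .data$size_mb) |>
    dplyr::summarise(raw = mean(.data$raw_z), adjusted = mean(.data$adjusted_z),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("raw", "adjusted"), names_to = "stage",
                        values_to = "z")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_mb, y = .data$z,
                                   colour = factor(.data$f),
                                   linetype = .data$stage)) +
    ggplot2::geom_hline(yintercept = c(-3, 3), colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(.data$direction ~ .data$chrom) +
    ggplot2::scale_linetype_manual(values = c(raw = "solid",
                                              adjusted = "dashed")) +
    ggplot2::labs(x = "maternal CNV size (Mb)", y = "chromosome Z-score",
                  colour = "fetal fraction", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Fetal-fraction concordance plot
#'
#' Scatter of the chromosome X fetal fraction against the
#' aneuploid-chromosome fetal fraction; concordant true positives fall on
#' the identity line.
#'
#' @param pairs Tibble with columns `f_x`, `f_aneu` and optionally
#'   `flagged`.
#' @return A ggplot object.
#' @export
plot_fcd_scatter <- function(pairs) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$f_x, y = .data$f_aneu))
  if ("flagged" %in% names(pairs)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$flagged))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "fetal fraction from chrX",
                  y = "fetal fraction from aneuploid chromosome") +
    ggplot2::theme_minimal()
}
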