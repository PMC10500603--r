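# ggplot2 autoplot methods for pglr result types.

#' Plot an ROI result set
#'
#' Dot plot of regions ordered by rank: mean -log10 adjusted p on the x
#' axis, point size by donor frequency.
#'
#' @param object A `pgl_rois` from [get_rois()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgl_rois <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$region, -.data$rank),
    size = .data$frequency)) +
    ggplot2::geom_point(colour = "#2c6e91") +
    ggplot2::labs(x = expression(mean ~ -log[10] ~ "adjusted p"),
                  y = NULL, size = "donor\nfrequency",
                  title = "Regions of interest") +
    ggplot2::theme_minimal()
}

#' Plot a false-positive calibration report
#'
#' @param object A `pgl_fp` from [false_positive_simulation()].
#' @param ... Unused.
#' @return A ggplot of the fraction of random lists yielding any ROI, by
#'   list size.
#' @export
autoplot.pgl_fp <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      fraction = .data$n_lists_with_roi /
                        pmax(.data$n_lists, 1))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$list_size),
                                   y = .data$fraction)) +
    ggplot2::geom_col(fill = "#b04a5a") +
    ggplot2::labs(x = "random list size", y = "fraction of lists with an ROI",
                  title = "Random-gene-list false-positive calibration") +
    ggplot2::theme_minimal()
}

#' Plot matching balance diagnostics
#'
#' Pre- vs post-match p-values per matching variable, with the 0.05
#' flagging threshold.
#'
#' @param object A `pgl_match` from [euclidean_match()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgl_match <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$balance_pre, stage = "pre-match"),
    dplyr::mutate(object$balance_post, stage = "post-match")
  )
  df$stage <- factor(df$stage, levels = c("pre-match", "post-match"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$p,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::labs(x = NULL, y = "balance-test p", fill = NULL,
                  title = "Covariate balance before and after matching") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a correlation matrix
#'
#' @param object A `pgl_corr` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot heat map of pairwise Pearson r.
#' @export
autoplot.pgl_corr <- function(object, ...) {
  vars <- colnames(object$r)
  df <- tidyr::expand_grid(var1 = vars, var2 = vars) |>
    dplyr::mutate(r = as.vector(t(object$r)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
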