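# ggplot2 displays for the pipeline's result types.

#' @importFrom rlang .data
NULL

#' Plot a line profile
#'
#' @param object A [line_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot: HU against position along the line (micrometres).
#' @export
autoplot.line_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position_um, .data$hu)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (µm)", y = "HU",
                  title = "HU line profile") +
    ggplot2::theme_minimal()
}

#' Plot a windowed CT slice
#'
#' Applies the display [window_level()] transform to one slice and renders
#' it as a grayscale raster.
#'
#' @param hu An [hu_volume()].
#' @param slice 1-based slice index.
#' @param level,width Window centre and width, HU.
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(hu, slice, level = 5211, width = 7884) {
  stopifnot(inherits(hu, "hu_volume"))
  disp <- window_level(hu$hu[slice, , , drop = FALSE], level, width)
  d <- dim(hu$hu)[2:3]
  dim(disp) <- d
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$value <- as.vector(disp)  # expand_grid varies `col` fastest = row-major
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "display",
                  title = sprintf("slice %d (level %g, width %g)",
                                  slice, level, width)) +
    ggplot2::theme_minimal()
}

#' Plot a cohort analysis
#'
#' Scatter of collagen content against raw and volume-normalized mean HU,
#' one panel per variant.
#'
#' @param object A `cohort_analysis` from [run_cohort_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_analysis <- function(object, ...) {
  rec <- object$records
  long <- dplyr::bind_rows(
    tibble(collagen_content = rec$collagen_content, hu = rec$mean_hu,
           variant = "raw HU"),
    tibble(collagen_content = rec$collagen_content, hu = rec$normalized_hu,
           variant = "volume-normalized HU")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$collagen_content, .data$hu)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~variant, scales = "free_y") +
    ggplot2::labs(x = "histological collagen content", y = "mean HU",
                  title = "HU vs collagen content") +
    ggplot2::theme_minimal()
}
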