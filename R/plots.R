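#' Bland-Altman plot
#'
#' Difference against mean for paired interstudy measurements, with the
#' bias (solid) and 95% limits of agreement (dashed) drawn as horizontal
#' lines.
#'
#' @param object a `ba_points` object from [bland_altman_points()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ba_points <- function(object, ...) {
  df <- tidy.ba_points(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "bias")) +
    ggplot2::geom_hline(yintercept = attr(object, "loa_low"), linetype = 2) +
    ggplot2::geom_hline(yintercept = attr(object, "loa_high"), linetype = 2) +
    ggplot2::labs(x = "Mean of initial and repeat study",
                  y = "Difference (initial - repeat)") +
    ggplot2::theme_minimal()
}

#' Plot a scalar map slice
#'
#' Raster view of one short-axis slice of an FA, MD or HA map; masked-out
#' voxels are blank. HA maps use a diverging scale centred on the
#' circumferential direction (0 degrees).
#'
#' @param object a `scalar_map`.
#' @param slice slice index (default 1).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scalar_map <- function(object, slice = 1, ...) {
  v <- object$values[, , slice]
  v[!object$mask[, , slice]] <- NA
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$value <- v[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = paste0(object$kind, " [", object$units, "]")) +
    ggplot2::theme_void()
  if (identical(object$kind, "HA"))
    p <- p + ggplot2::scale_fill_gradient2(limits = c(-90, 90),
                                           low = "blue", mid = "grey90",
                                           high = "red", na.value = "white")
  else
    p <- p + ggplot2::scale_fill_viridis_c(na.value = "white")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
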