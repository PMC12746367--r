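#' Plot an acquisition schedule
#'
#' Per-image saturation power (and offset, when varied) as lollipop panels.
#'
#' @param object An `st_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_schedule <- function(object, ...) {
  df <- tibble(index = seq_len(nrow(object)),
               b1_uT = object$b1_uT, offset_ppm = object$offset_ppm)
  long <- tidyr::pivot_longer(df, -"index",
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "image index", y = NULL,
                  title = "Acquisition schedule") +
    ggplot2::theme_minimal()
}

#' Plot an MRF signal trajectory
#' @param object An `st_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "image index", y = "signal (fraction of M0)",
                  title = "MRF signal trajectory") +
    ggplot2::theme_minimal()
}

#' Plot the basin-hopping loss trace
#' @param object An `st_optim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_optim <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$accepted)) +
    ggplot2::geom_hline(yintercept = object$best_loss, linetype = 2) +
    ggplot2::labs(x = "basin hop", y = "CRB loss",
                  title = "Schedule optimization trace") +
    ggplot2::theme_minimal()
}

#' Plot reconstructed parameter maps
#' @param object A `param_maps`.
#' @param parameter `"fs"`, `"ksw"` or `"score"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.param_maps <- function(object, parameter = c("fs", "ksw", "score"),
                                ...) {
  parameter <- match.arg(parameter)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[parameter]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = paste("Reconstructed", parameter, "map"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
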