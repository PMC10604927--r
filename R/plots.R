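# ggplot2 displays for the main result types

#' @export
autoplot.kidseg_result <- function(object, image = NULL, truth_contour = NULL,
                                   ...) {
  df <- NULL
  if (!is.null(image)) {
    df <- tibble(x = rep(0:(ncol(image) - 1), each = nrow(image)),
                 y = rep(0:(nrow(image) - 1), times = ncol(image)),
                 intensity = as.numeric(image))
  }
  p <- ggplot2::ggplot()
  if (!is.null(df)) {
    p <- p + ggplot2::geom_raster(
      data = df, ggplot2::aes(x = .data$x, y = .data$y,
                              fill = .data$intensity)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  if (!is.null(truth_contour)) {
    p <- p + ggplot2::geom_path(
      data = rbind(truth_contour, truth_contour[1, ]),
      ggplot2::aes(x = .data$x, y = .data$y, colour = "truth"))
  }
  if (!object$no_object) {
    rc <- object$refined_contour
    p <- p + ggplot2::geom_path(
      data = rbind(rc[, c("x", "y")], rc[1, c("x", "y")]),
      ggplot2::aes(x = .data$x, y = .data$y, colour = "refined"))
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::scale_colour_manual(
      NULL, values = c(truth = "red", refined = "deepskyblue")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dfln_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "Dice loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.abnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kidseg_report <- function(object, ...) {
  s <- object$summary
  xvar <- setdiff(names(s), c("n", "dsc_mean", "dsc_sd", "jaccard_mean",
                              "jaccard_sd", "model_id"))[1]
  s[[xvar]] <- factor(s[[xvar]], levels = unique(s[[xvar]]))
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[xvar]], y = .data$dsc_mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dsc_mean - .data$dsc_sd,
                   ymax = pmin(1, .data$dsc_mean + .data$dsc_sd)),
      width = 0.25) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "DSC (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Overlay a phantom, its ground truth and a refined contour
#'
#' @param phantom a [generate_phantom()] result.
#' @param result optional `kidseg_result` for the same image.
#' @return A ggplot object.
#' @export
plot_phantom <- function(phantom, result = NULL) {
  if (is.null(result)) {
    result <- structure(list(no_object = TRUE), class = "kidseg_result")
  }
  autoplot(result, image = phantom$image, truth_contour = phantom$contour)
}
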