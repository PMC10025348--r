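#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Grouped bar chart of a contingency table
#'
#' Mirrors the standard presentation of the influence cross-tabulations:
#' one group of bars per conditioning level, one bar per response level.
#'
#' @param object A [contingency_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.contingency_table <- function(object, ...) {
  d <- tidy(object)
  names(d) <- c("conditioning", "response", "n")
  d$conditioning <- factor(d$conditioning, levels = rownames(object$counts))
  d$response <- factor(d$response, levels = colnames(object$counts))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conditioning, y = .data$n,
                                  fill = .data$response)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = object$conditioning, y = "records",
                  fill = object$response) +
    ggplot2::theme_minimal()
}

#' Training loss curve of a fitted classifier
#'
#' @param object A fitted `rescnn` model.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rescnn <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}

#' Spectrogram-style image of a log-Mel feature channel
#'
#' @param F A t x k x 3 tensor from [stack_log_mels()].
#' @param channel Which channel to draw: `"static"`, `"delta"` or
#'   `"delta_delta"`.
#' @return A ggplot object.
#' @export
plot_log_mels <- function(F, channel = c("static", "delta", "delta_delta")) {
  channel <- match.arg(channel)
  m <- F[, , channel]
  d <- tidyr::expand_grid(frame = seq_len(nrow(m)), band = seq_len(ncol(m)))
  d$value <- as.vector(m)[(d$band - 1) * nrow(m) + d$frame]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$band,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = channel) +
    ggplot2::labs(x = "frame", y = "mel band") +
    ggplot2::theme_minimal()
}
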