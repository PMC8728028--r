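#' Plot a fitted GC trend over the data
#'
#' @param object A `gc_fit`.
#' @param data Optional data frame with the original `gc`/outcome columns to
#'   draw as points (the fit stores only the model).
#' @param ... Unused.
#' @return A ggplot object: fitted polynomial curve across the observed GC
#'   range (with the training scatter when `data` is given).
#' @export
autoplot.gc_fit <- function(object, data = NULL, ...) {
  grid <- tibble::tibble(
    gc = seq(object$gc_range[1], object$gc_range[2], length.out = 200)
  )
  grid$fit <- predict(object, grid$gc)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$gc, y = .data$fit))
  if (!is.null(data)) {
    pts <- tibble::tibble(
      gc = data$gc_fraction,
      y = data[[object$outcome]]
    )
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$gc, y = .data$y),
      alpha = 0.3, size = 0.6
    )
  }
  p +
    ggplot2::geom_line(colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "GC fraction",
      y = object$outcome,
      title = sprintf("GC trend (order %d polynomial)", object$order)
    )
}

#' Boxplots of segment activity by ARE cluster
#'
#' Mirrors the established-cluster view of reporter activity: one boxplot
#' per cluster label, ordered none < AUUUA_only < C1 < ... < C5.
#'
#' @param data Segment table with a `cluster` column (see
#'   [segment_features()]) and the outcome column.
#' @param outcome Outcome column (tidy-eval), e.g. `stability`.
#' @return A ggplot object.
#' @export
plot_cluster_activity <- function(data, outcome) {
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$cluster, y = {{ outcome }})
  ) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.size = 0.5,
                          fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "ARE cluster",
                  y = rlang::as_label(rlang::enquo(outcome)))
}

#' Mean activity by ARE effective length
#'
#' @param data Segment table with `are_effective_length` and the outcome.
#' @param outcome Outcome column (tidy-eval).
#' @return A ggplot object: per-effective-length means with standard error
#'   bars.
#' @export
plot_effective_length <- function(data, outcome) {
  d <- data |>
    dplyr::filter(!is.na(.data$are_effective_length)) |>
    dplyr::group_by(.data$are_effective_length) |>
    dplyr::summarise(
      mean = mean({{ outcome }}, na.rm = TRUE),
      se = stats::sd({{ outcome }}, na.rm = TRUE) /
        sqrt(sum(!is.na({{ outcome }}))),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$are_effective_length,
                                  y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "ARE effective length (nt)",
                  y = rlang::as_label(rlang::enquo(outcome)))
}

#' Plot out-of-chromosome predictions against measurements
#'
#' @param object A `loco_report`.
#' @param ... Unused.
#' @return A ggplot object with the pooled correlation in the title.
#' @export
autoplot.loco_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::labs(
      title = sprintf("%s on %s: pooled r = %.3f",
                      object$method, object$outcome, object$r),
      x = "out-of-chromosome prediction", y = "measured"
    )
}
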