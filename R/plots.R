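## Plotting helpers for motivational trajectories and event logs.

#' Plot stomach / hunger / caching-motivation trajectories
#'
#' @param trajectory tibble from [motivation_trajectory()].
#' @param foods optional subset of food types to display.
#' @return A ggplot object.
#' @export
plot_motivation <- function(trajectory, foods = NULL) {
  df <- trajectory
  if (!is.null(foods)) df <- df[df$food_type %in% foods, , drop = FALSE]
  long <- dplyr::bind_rows(
    dplyr::transmute(df, time = .data$time, food_type = .data$food_type,
                     variable = "stomach", value = .data$s),
    dplyr::transmute(df, time = .data$time, food_type = .data$food_type,
                     variable = "hunger", value = .data$h))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$food_type)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time [min]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an event log
#'
#' @param events tibble from [bird_events()].
#' @return A ggplot raster of actions over time per bird.
#' @export
plot_events <- function(events) {
  ggplot2::ggplot(events, ggplot2::aes(x = .data$time, y = .data$bird,
                                       color = .data$action)) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "time [min]", y = NULL) +
    ggplot2::theme_minimal()
}
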