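#' Plot a presentation log
#'
#' Presented image over session time (points, one per 5-s tick) with the
#' noise scale `s` in force drawn underneath. Looping shows up as long
#' horizontal runs on a single image; high `s` as frequent vertical jumps.
#'
#' @param object a `presentation_log`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot presentation_log
#' @export
autoplot.presentation_log <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session_time)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$s_in_force * 1), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = as.integer(factor(.data$image_id)),
                                     colour = .data$image_id),
                        show.legend = FALSE, size = 0.8) +
    ggplot2::labs(x = "session time [s]",
                  y = "presented image (index) / noise scale s",
                  title = "Presentation log") +
    ggplot2::theme_minimal()
}

#' Plot a processed HRV / noise-parameter stream
#'
#' Windowed HRV and the resulting noise scale `s` over time, one point per
#' 3-beat packet.
#'
#' @param samples output of [process_stream()].
#' @return A ggplot object.
#' @export
plot_hrv_samples <- function(samples) {
  long <- tidyr::pivot_longer(as_tibble(samples), c("hrv", "s"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = "Windowed HRV and noise scale") +
    ggplot2::theme_minimal()
}

#' Plot a cohort comparison
#'
#' Boxplots of the behavioral indices by interaction mode, built from the
#' per-session summaries.
#'
#' @param summaries combined per-session summaries with a `mode` column
#'   (rows from [summarize_session()]).
#' @return A ggplot object.
#' @export
plot_cohort <- function(summaries) {
  long <- tidyr::pivot_longer(as_tibble(summaries),
                              c("total_switches", "unique_images"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$mode, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Behavioral indices by mode") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cohort
#' @param object a `cohort_report`.
#' @param ... unused.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("sync_median", "counterbalance_median"),
                              names_to = "arm", values_to = "median")
  ggplot2::ggplot(long, ggplot2::aes(.data$arm, .data$median)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "median", title = "Cohort medians") +
    ggplot2::theme_minimal()
}
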