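#' Plot the splicing-event landscape
#'
#' Scatter of signed event size against location percentage along the
#' standard transcript, colored by event type: insertions plot with
#' positive sizes, deletions with negative sizes, so the two clouds
#' separate around zero and region structure along the transcript is
#' visible on the x axis.
#'
#' @param object A `splice_event_set` from [call_splice_events()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_event_set <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$location_pct,
                                   y = .data$signed_size,
                                   color = .data$type)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(insertion = "#1b7837",
                                           deletion = "#762a83")) +
    ggplot2::labs(
      x = sprintf("location along transcript (%%, origin: %s)",
                  object$params$origin),
      y = "event size (bp; insertions > 0, deletions < 0)",
      color = NULL,
      title = sprintf("%d splicing events in %d isoforms",
                      object$summary$n_events, object$summary$n_isoforms)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.splice_event_set
#' @export
autoplot.target_regulation <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = factor(.data$direction,
                                          c("up", "down", "unchanged")),
                               y = .data$n, fill = .data$direction)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(up = "#2166ac", down = "#b2182b",
                                          unchanged = "grey70")) +
    ggplot2::labs(x = NULL, y = "RIP-target transcripts",
                  title = "Regulation of bound targets") +
    ggplot2::theme_minimal()
}

#' Expression scatter of two conditions
#'
#' Mean FPKM (log10, with pseudocount) in one condition against the
#' other, colored by DE direction.
#'
#' @param de_calls Output of [call_de()].
#' @param pseudocount Added before the log for display.
#' @return A ggplot object.
#' @export
plot_expression_scatter <- function(de_calls, pseudocount = 0.1) {
  check_columns(de_calls, c("mean_a", "mean_b", "direction"), "de_calls")
  ggplot2::ggplot(de_calls,
                  ggplot2::aes(x = log10(.data$mean_b + pseudocount),
                               y = log10(.data$mean_a + pseudocount),
                               color = .data$direction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 0.3,
                         color = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_color_manual(values = c(up = "#2166ac", down = "#b2182b",
                                           unchanged = "#e8c95d")) +
    ggplot2::labs(x = "log10 mean FPKM (reference)",
                  y = "log10 mean FPKM (contrast)", color = NULL) +
    ggplot2::theme_minimal()
}
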