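#' Plot per-trigger fire counts
#'
#' @param object A [flag_cohort()] result.
#' @param ... Unused.
#' @return A ggplot: triggers ordered by fire count.
#' @method autoplot flag_summary
#' @export
autoplot.flag_summary <- function(object, ...) {
  counts <- dplyr::filter(object$per_trigger_counts, .data$n_fired > 0)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$trigger_id,
                                                  .data$n_fired),
                               y = .data$n_fired)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "flagged visits",
      title = paste0("Trigger fires: ", object$n_flagged, "/",
                     object$n_total, " visits flagged (",
                     as_pct(object$n_flagged / object$n_total), "%)")
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-trigger positive predictive values
#'
#' @param object A [evaluate_cohort()] result.
#' @param ... Unused.
#' @return A ggplot: per-trigger PPV with confidence intervals, the
#'   overall PPV as a dashed reference line.
#' @method autoplot dredtt_metrics
#' @export
autoplot.dredtt_metrics <- function(object, ...) {
  per <- object$ppv_per_trigger
  ggplot2::ggplot(per,
                  ggplot2::aes(x = .data$estimate,
                               y = stats::reorder(.data$trigger_id,
                                                  .data$estimate))) +
    ggplot2::geom_vline(xintercept = object$ppv_overall$estimate,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.25, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$denominator),
                        colour = "grey20") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = "positive predictive value", y = NULL,
      title = paste0("Per-trigger PPV (overall ",
                     as_pct(object$ppv_overall$estimate), "%)"),
      caption = paste0(toupper(object$method), " ",
                       100 * object$level, "% CI; point size ~ sampled fires")
    ) +
    ggplot2::theme_minimal()
}
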