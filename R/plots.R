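# Displays of sweep results: per algorithm, F1 (non-deferred), overall
# F1 and defer rate against the control parameter, with the no-defer
# diagnostic F1 as a dashed reference.

#' Plot a deferral sweep
#'
#' Seed-averaged F1, overall F1 and defer rate against the control
#' parameter (`alpha` or entropy threshold), faceted by algorithm when
#' several are bound together.  The dashed horizontal line is the
#' no-defer diagnostic network's F1.
#'
#' @param object A `defer_sweep` tibble from [sweep_defer()] (or several
#'   row-bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.defer_sweep <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object),
                    .data$algorithm, .data$param_name, .data$param_value),
    dplyr::across(c("f1", "f1_overall", "defer_rate", "diagnostic_f1"),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  long <- tidyr::pivot_longer(df, c("f1", "f1_overall", "defer_rate"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$param_value, .data$value,
                                     colour = .data$metric,
                                     linetype = .data$metric)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$diagnostic_f1),
                        data = df, linetype = "dotted", colour = "grey30") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(
      values = c(f1 = "#c0392b", f1_overall = "#c0392b", defer_rate = "#2980b9")) +
    ggplot2::scale_linetype_manual(
      values = c(f1 = "solid", f1_overall = "dashed", defer_rate = "solid")) +
    ggplot2::facet_wrap(~algorithm, scales = "free_x") +
    ggplot2::labs(x = "control parameter (alpha / entropy threshold)",
                  y = "value",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.defer_sweep
#' @param records A `defer_sweep` tibble.
#' @export
plot_sweep <- function(records, ...) autoplot.defer_sweep(records, ...)
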