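# ggplot2 graphics ------------------------------------------------------

#' Plot single-cell reporter or activity traces
#'
#' @param traces Trace tibble.
#' @param value Column to plot (default "intensity").
#' @param alpha Line transparency for single cells.
#' @return A ggplot object: one line per cell over time.
#' @export
plot_traces <- function(traces, value = "intensity", alpha = 0.4) {
  ggplot(traces, aes(x = .data$time_h, y = .data[[value]],
                     group = .data$cell_id)) +
    geom_line(alpha = alpha, colour = "grey30") +
    labs(x = "time (h)", y = value) +
    theme_minimal()
}

#' @describeIn align_to_mitosis Single-cell lines plus the cohort median
#'   against time relative to mitosis.
#' @param object An `aligned_traces` object.
#' @param ... Unused.
#' @export
autoplot.aligned_traces <- function(object, ...) {
  ggplot(object$data,
         aes(x = .data$rel_time_h, y = .data$value,
             group = .data$cell_id)) +
    geom_line(alpha = 0.25, colour = "grey60") +
    geom_line(data = object$summary,
              aes(y = .data$median, group = NULL),
              colour = "firebrick", linewidth = 1, na.rm = TRUE) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "time relative to mitosis (h)", y = "value") +
    theme_minimal()
}

#' @describeIn fit_dose_response Responses and the fitted logistic curve
#'   on a log dose axis.
#' @param object A `dose_response_fit` object.
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$dose, y = .data$response)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "dose (uM)", y = "response") +
    theme_minimal()
  if (object$converged) {
    grid <- tibble(dose = exp(seq(log(min(object$data$dose)),
                                  log(max(object$data$dose)),
                                  length.out = 100)))
    grid$response <- fourpl(grid$dose, object$bottom, object$top,
                            object$ic50, object$hill)
    p <- p + geom_line(data = grid, colour = "steelblue") +
      geom_vline(xintercept = object$ic50, linetype = 2)
  }
  p
}

#' @describeIn correlate_activity_protein Scatter plot of the paired
#'   single-cell data annotated with rho.
#' @param object A `correlation_result` object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$protein_level, y = .data$activity)) +
    geom_point(alpha = 0.4) +
    labs(x = "protein level (a.u.)", y = "activity (a.u./h)",
         subtitle = sprintf("%s rho = %.3f (n = %d)", object$method,
                            object$rho, object$n)) +
    theme_minimal()
}

#' Percent-activity heatmap of a screening plate
#'
#' @param pa_table Output of [normalize_plate()].
#' @param limit Symmetric colour-scale limit in percent.
#' @return A ggplot tile plot in plate coordinates.
#' @export
plot_plate <- function(pa_table, limit = 100) {
  ggplot(pa_table, aes(x = .data$col, y = .data$row, fill = .data$pa)) +
    geom_tile() +
    scale_fill_gradient2(low = "darkorange", mid = "white",
                         high = "steelblue",
                         limits = c(-limit, limit), oob = scales::squish,
                         name = "PA (%)") +
    scale_y_reverse() +
    coord_equal() +
    labs(x = "column", y = "row") +
    theme_minimal()
}
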