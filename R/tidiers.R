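# broom-style tidiers for fitted objects --------------------------------

#' @rdname fit_dose_response
#' @param x A `dose_response_fit` object.
#' @param ... Unused.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("bottom", "top", "ic50", "hill"),
         estimate = c(x$bottom, x$top, x$ic50, x$hill))
}

#' @rdname fit_dose_response
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(converged = x$converged, fit_class = x$fit_class,
         rss = x$rss, n = nrow(x$data))
}

#' @rdname correlate_activity_protein
#' @param x A `correlation_result` object.
#' @param ... Unused.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble(estimate = x$rho, conf.low = x$ci[1], conf.high = x$ci[2],
         method = x$method, n = x$n)
}

#' @rdname correlate_activity_protein
#' @export
glance.correlation_result <- function(x, ...) tidy(x)

#' @rdname compare_activity_populations
#' @param x A `fold_result` object.
#' @param ... Unused.
#' @export
tidy.fold_result <- function(x, ...) {
  tibble(estimate = x$fold, conf.low = x$ci[1], conf.high = x$ci[2],
         median_a = x$median_a, median_b = x$median_b)
}

#' @rdname estimate_synthesis_rate
#' @param x A `synthesis_fit` object.
#' @param ... Unused.
#' @export
tidy.synthesis_fit <- function(x, ...) x$slopes

#' @rdname estimate_synthesis_rate
#' @export
glance.synthesis_fit <- function(x, ...) {
  tibble(s = x$s, n_cells = nrow(x$slopes),
         residual_k_flag = x$residual_k_flag)
}
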