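# broom-style tidiers for the package's fitted objects

#' Tidy a circular-shift bootstrap result
#'
#' @param x A `strical_bootstrap`.
#' @param ... Unused.
#' @return A one-row tibble with `observed`, `p_value`, `significant`,
#'   `threshold`, `n_events`, `n_null`.
#' @export
tidy.strical_bootstrap <- function(x, ...) {
  tibble(observed = x$observed, p_value = x$p_value,
         significant = x$significant, threshold = x$threshold,
         n_events = x$n_events, n_null = length(x$null_areas))
}

#' @rdname tidy.strical_bootstrap
#' @export
glance.strical_bootstrap <- function(x, ...) tidy.strical_bootstrap(x, ...)

#' Tidy an exponential decay fit
#'
#' @param x A `strical_decay_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `tau_s`, `a`, `b`, `residual`.
#' @export
tidy.strical_decay_fit <- function(x, ...) {
  tibble(tau_s = x$tau_s, a = x$a, b = x$b, residual = x$residual)
}

#' Tidy a correlation-distance regression
#'
#' @param x A `strical_distance_fit`.
#' @param ... Unused.
#' @return `tidy()` returns the binned curve; `glance()` the regression
#'   statistics (slope, R-squared, p, bin count).
#' @export
tidy.strical_distance_fit <- function(x, ...) x$curve

#' @rdname tidy.strical_distance_fit
#' @export
glance.strical_distance_fit <- function(x, ...) x$stats

#' Tidy a population JPSTH
#'
#' @param x A `strical_pop_jpsth`.
#' @param ... Unused.
#' @return A long tibble with `lag1_s`, `lag2_s`, `value`.
#' @export
tidy.strical_pop_jpsth <- function(x, ...) {
  g <- expand.grid(lag1_s = x$lag_s, lag2_s = x$lag_s)
  tibble(lag1_s = g$lag1_s, lag2_s = g$lag2_s, value = as.vector(x$matrix))
}
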