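# broom-style tidiers for the package's result objects.

#' Tidy an encoding-model fit
#'
#' @param x An `encoding_fit`.
#' @param ... Unused.
#' @return One row per predictor: median/mean delta R-squared and the
#'   relative contribution in percent, ranked.
#' @export
tidy.encoding_fit <- function(x, ...) rank_contributions(x)

#' @rdname tidy.encoding_fit
#' @return For `glance()`: a one-row tibble with the median and mean
#'   full-model validation R-squared, iteration count, mode, and the
#'   all-zero flag.
#' @export
glance.encoding_fit <- function(x, ...) {
  tibble(
    r2_full_median = median(x$r2_full),
    r2_full_mean = mean(x$r2_full),
    iterations = x$spec$iterations,
    mode = x$spec$mode,
    n = x$spec$n,
    all_zero = x$all_zero
  )
}

#' Tidy a simple linear fit
#'
#' @param x A `linfit_result`.
#' @param ... Unused.
#' @return Two rows (intercept, slope) with estimates and the slope's
#'   two-sided p-value.
#' @export
tidy.linfit_result <- function(x, ...) {
  tibble(term = c("(Intercept)", "slope"),
         estimate = c(x$intercept, x$slope),
         p.value = c(NA_real_, x$p_slope))
}

#' @rdname tidy.linfit_result
#' @export
glance.linfit_result <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_slope, nobs = x$n)
}

#' Tidy a lagged cross-correlation
#'
#' @param x A `lag_correlation`.
#' @param ... Unused.
#' @return The per-lag tibble (`lag_s`, `r`).
#' @export
tidy.lag_correlation <- function(x, ...) x$lags

#' @rdname tidy.lag_correlation
#' @export
glance.lag_correlation <- function(x, ...) {
  tibble(peak_lag_s = x$peak_lag, peak_r = x$peak_r, max_lag_s = x$max_lag)
}

#' Tidy a hysteresis loop
#'
#' @param x A `hysteresis_loop`.
#' @param ... Unused.
#' @return The ordered 50-point tibble (`time_s`, `x`, `activity`).
#' @export
tidy.hysteresis_loop <- function(x, ...) x$points

#' @rdname tidy.hysteresis_loop
#' @export
glance.hysteresis_loop <- function(x, ...) {
  tibble(signed_area = x$signed_area, n_points = nrow(x$points),
         t_start = x$bounds[1], t_end = x$bounds[2])
}

#' Tidy a bout set
#'
#' @param x A `bout_set`.
#' @param ... Unused.
#' @return The per-bout tibble.
#' @export
tidy.bout_set <- function(x, ...) x$bouts

#' @rdname tidy.bout_set
#' @export
glance.bout_set <- function(x, ...) {
  tibble(count = x$count, mean_duration_s = x$mean_duration,
         mean_speed = x$mean_speed, threshold = x$threshold)
}

#' Tidy a cell-classification result
#'
#' @param x A `cell_classification`.
#' @param ... Unused.
#' @return The per-cell tibble (class, correlations, p-values).
#' @export
tidy.cell_classification <- function(x, ...) x$cells

#' @rdname tidy.cell_classification
#' @export
glance.cell_classification <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$prevalence[, c("class", "fraction")],
                             names_from = "class", values_from = "fraction")
  dplyr::bind_cols(tibble(n_cells = nrow(x$cells)), wide)
}

#' Tidy a multiplexing cross-tab
#'
#' @param x A `multiplex_table`.
#' @param ... Unused.
#' @return The long count/fraction tibble.
#' @export
tidy.multiplex_table <- function(x, ...) x$table

#' @rdname tidy.multiplex_table
#' @export
glance.multiplex_table <- function(x, ...) {
  tibble(n_cells = x$n_cells, multiplexed_fraction = x$multiplexed_fraction)
}
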