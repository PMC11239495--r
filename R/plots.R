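# ggplot2 autoplot methods for the package's result objects.

#' Plot a lagged cross-correlation
#'
#' @param object A `lag_correlation`.
#' @param ... Unused.
#' @return A ggplot: r against lag, peak marked.
#' @export
autoplot.lag_correlation <- function(object, ...) {
  ggplot(object$lags, aes(x = .data$lag_s, y = .data$r)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line() +
    geom_point(data = tibble(lag_s = object$peak_lag, r = object$peak_r),
               colour = "red", size = 2) +
    labs(x = "lag (s; positive = activity delayed)",
         y = "Pearson r", title = "Lagged cross-correlation") +
    theme_minimal()
}

#' Plot a hysteresis loop
#'
#' @param object A `hysteresis_loop`.
#' @param ... Unused.
#' @return A ggplot: activity against glucose (or its derivative), points
#'   connected in time order and coloured by time.
#' @export
autoplot.hysteresis_loop <- function(object, ...) {
  ggplot(object$points,
         aes(x = .data$x, y = .data$activity, colour = .data$time_s)) +
    geom_path() +
    geom_point(size = 1.5) +
    scale_colour_viridis_c(name = "time (s)") +
    labs(x = "glucose axis", y = "activity (z)",
         title = sprintf("Hysteresis loop (signed area %.3g)",
                         object$signed_area)) +
    theme_minimal()
}

#' Plot encoding-model contributions
#'
#' @param object An `encoding_fit`.
#' @param ... Unused.
#' @return A ggplot: ranked per-predictor relative contributions.
#' @export
autoplot.encoding_fit <- function(object, ...) {
  d <- rank_contributions(object)
  d$predictor <- factor(d$predictor, levels = rev(d$predictor))
  ggplot(d, aes(x = .data$contribution_pct, y = .data$predictor)) +
    geom_col(fill = "steelblue") +
    labs(x = "relative contribution (% of explained variance)", y = NULL,
         title = "Encoding-model predictor ranking") +
    theme_minimal()
}

#' Plot classification prevalences
#'
#' @param object A `cell_classification`.
#' @param ... Unused.
#' @return A ggplot: class fractions.
#' @export
autoplot.cell_classification <- function(object, ...) {
  d <- object$prevalence
  d$class <- factor(d$class, levels = d$class)
  ggplot(d, aes(x = .data$class, y = .data$fraction)) +
    geom_col(fill = "darkorange") +
    labs(x = "glucose-response class", y = "fraction of cells",
         title = "Single-cell class prevalences") +
    theme_minimal()
}

#' Plot a template set
#'
#' @param object A `template_set`.
#' @param ... Unused.
#' @return A ggplot of the four glucose-derived waveforms.
#' @export
autoplot.template_set <- function(object, ...) {
  d <- purrr::map_dfr(names(object$waveforms), function(nm) {
    tibble(time_min = object$time_min, value = object$waveforms[[nm]],
           template = nm)
  })
  d$template <- factor(d$template, levels = c("G", "dG", "iG", "idG"))
  ggplot(d, aes(x = .data$time_min, y = .data$value)) +
    geom_line() +
    facet_wrap(~template) +
    labs(x = "time post-infusion (min)", y = "template (z)",
         title = "Glucose-derived classification templates") +
    theme_minimal()
}

#' Plot all channels of a session record
#'
#' @param object A `session_record`.
#' @param ... Unused.
#' @return A ggplot: channels in facets against time, infusion marked.
#' @export
autoplot.session_record <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                           names_to = "channel", values_to = "value")
  d$channel <- factor(d$channel, levels = setdiff(session_channels, "time_s"))
  p <- ggplot(d, aes(x = .data$time_s / 60, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(x = "time (min)", y = NULL, title = "Session channels") +
    theme_minimal()
  ev <- session_events(object)
  if (nrow(ev) > 0L) {
    p <- p + geom_vline(xintercept = ev$time_s / 60,
                        linetype = "dashed", colour = "red")
  }
  p
}
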