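#' Support samples for baseline fitting: the lower convex hull of a trace
#'
#' Finds the samples that lie on the lower convex hull of the point set
#' `(time, values)` using the monotone-chain construction. These are the
#' local minima that trace out the slow baseline (photobleaching) envelope
#' of a fluorescence recording; an exponential baseline is later fit
#' through them. Collinear hull points are retained, and the first and
#' last samples are always part of the support.
#'
#' @param values Numeric trace.
#' @param time Sample times in seconds. Defaults to `0:(n-1)`.
#' @return Integer vector of support indices, in time order.
#' @seealso [fit_triple_exponential()], [detrend()]
#' @export
lower_hull_support <- function(values, time = seq_along(values) - 1) {
  assert_same_length(values, time)
  if (length(values) < 3L) abort("lower_hull_support() needs at least 3 samples")
  if (!all(is.finite(values)) || !all(is.finite(time))) {
    abort("lower_hull_support() requires finite values")
  }
  if (any(diff(time) <= 0)) abort("time must be strictly increasing")

  cross <- function(o, a, b) {
    (time[a] - time[o]) * (values[b] - values[o]) -
      (values[a] - values[o]) * (time[b] - time[o])
  }
  # collinearity tolerance scaled to the data so exactly-linear segments
  # survive floating-point rounding
  eps <- 1e-12 * max(diff(range(time)) * diff(range(values)), 1e-300)
  hull <- integer(0)
  for (i in seq_along(values)) {
    # pop while the last three points make a clockwise (concave-from-below)
    # turn; collinear points (within eps) are kept
    while (length(hull) >= 2L &&
           cross(hull[length(hull) - 1L], hull[length(hull)], i) < -eps) {
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, i)
  }
  hull
}

# Triple-exponential-plus-offset model curve.
texp_curve <- function(t, a, tau, c0) {
  drop(exp(-outer(t, 1 / tau)) %*% a) + c0
}

#' Fit a non-negative triple exponential through baseline support points
#'
#' Least-squares fit of `f(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) +
#' a3 exp(-t/tau3) + c` with `a_i >= 0`, `tau_i > 0`, `c >= 0`, the
#' standard photobleaching model for fluorescence baselines. The fit uses
#' variable projection: for each candidate set of time constants the
#' amplitudes are solved by non-negative least squares
#' ([pracma::lsqnonneg()]); the time constants are multi-started on a
#' fixed log-spaced grid (27 combinations over 0.01, 0.1 and 1 times the
#' trace duration) and the best starts are polished by Nelder-Mead on
#' log time constants. Fully deterministic.
#'
#' With fewer than 8 support points the model falls back to a double
#' (>= 6 points) or single (>= 4 points) exponential; the number of
#' components used is recorded in the returned model.
#'
#' @param time Times (seconds) of the support samples.
#' @param values Trace values at the support samples.
#' @param n_components Maximum number of exponential components (default 3).
#' @return A `detrend_model` object: list with `amplitudes`,
#'   `time_constants`, `offset`, `residual_norm`, `support_time`,
#'   `n_components`, and `fitted(model, t)` support via [predict()].
#' @export
fit_triple_exponential <- function(time, values, n_components = 3L) {
  assert_same_length(time, values)
  n <- length(time)
  if (n < 4L) abort("fit_triple_exponential() needs at least 4 support points")
  n_components <- as.integer(n_components)
  # fallback ladder: 3 exps need >= 8 points, 2 need >= 6
  if (n < 8L && n_components > 2L) n_components <- 2L
  if (n < 6L && n_components > 1L) n_components <- 1L

  t0 <- time - time[1L]
  span <- max(t0)
  if (span <= 0) abort("support points must span a positive time range")

  rss_for_tau <- function(tau) {
    basis <- cbind(exp(-outer(t0, 1 / tau)), 1)
    fit <- pracma::lsqnonneg(basis, values)
    list(rss = sum((basis %*% fit$x - values)^2), coefs = fit$x)
  }

  tau_grid <- span * c(0.01, 0.1, 1)
  starts <- as.matrix(expand.grid(rep(list(tau_grid), n_components)))
  scored <- apply(starts, 1L, function(tau) rss_for_tau(tau)$rss)
  keep <- order(scored)[seq_len(min(4L, nrow(starts)))]

  best <- NULL
  for (k in keep) {
    obj <- function(log_tau) rss_for_tau(exp(log_tau))$rss
    opt <- optim(log(starts[k, ]), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 4000L))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || !is.finite(best$value)) {
    abort("triple-exponential fit failed to converge from any start")
  }

  tau <- exp(best$par)
  sol <- rss_for_tau(tau)
  a <- sol$coefs[seq_len(n_components)]
  c0 <- sol$coefs[n_components + 1L]
  ord <- order(tau)

  structure(
    list(
      amplitudes = unname(a[ord]),
      time_constants = unname(tau[ord]),
      offset = unname(c0),
      t_ref = time[1L],
      residual_norm = sqrt(sol$rss),
      support_time = time,
      n_components = n_components
    ),
    class = "detrend_model"
  )
}

#' @export
predict.detrend_model <- function(object, newdata, ...) {
  t <- if (is.data.frame(newdata)) newdata$time_s else newdata
  texp_curve(t - object$t_ref, object$amplitudes, object$time_constants,
             object$offset)
}

#' @export
print.detrend_model <- function(x, ...) {
  cat("<detrend_model> ", x$n_components, "-exponential + offset\n", sep = "")
  cat("  tau (s): ", paste(signif(x$time_constants, 4), collapse = ", "), "\n")
  cat("  amplitudes: ", paste(signif(x$amplitudes, 4), collapse = ", "),
      "; offset: ", signif(x$offset, 4), "\n", sep = "")
  cat("  residual norm: ", signif(x$residual_norm, 4), " over ",
      length(x$support_time), " support points\n", sep = "")
  invisible(x)
}

#' Remove a fitted slow baseline from a trace
#'
#' Computes `(y - f) / f` where `f` is the fitted baseline evaluated on
#' the trace's grid: the fractional fluorescence change relative to the
#' bleaching envelope (a dF/F-style quantity).
#'
#' @param values Raw trace.
#' @param time Sample times (seconds).
#' @param model A `detrend_model` from [fit_triple_exponential()].
#' @return Dimensionless detrended trace.
#' @export
detrend <- function(values, time, model) {
  assert_same_length(values, time)
  f <- predict(model, time)
  if (any(f <= 0)) abort("fitted baseline is not strictly positive; cannot divide")
  (values - f) / f
}

#' Normalize a trace to its pre-event baseline window
#'
#' z-scores a trace using the mean and standard deviation computed over a
#' stated baseline window (conventionally the 20 minutes before the
#' infusion), so values are in baseline standard-deviation units.
#'
#' @param values Trace values.
#' @param time Sample times (seconds).
#' @param window Length-2 numeric `(start, end)` in seconds, inclusive.
#' @return A tibble with columns `time_s`, `value_z`, plus attributes
#'   `baseline_window`, `baseline_mean`, `baseline_sd`.
#' @export
zscore_baseline <- function(values, time, window) {
  assert_same_length(values, time)
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("window must be (start, end) with start < end")
  }
  in_win <- time >= window[1] & time <= window[2]
  if (!any(in_win)) abort("baseline window contains no samples")
  m <- mean(values[in_win])
  s <- sd(values[in_win])
  if (!is.finite(s) || s == 0) abort("baseline window is constant; sd is zero")
  out <- tibble(time_s = time, value_z = (values - m) / s)
  attr(out, "baseline_window") <- window
  attr(out, "baseline_mean") <- m
  attr(out, "baseline_sd") <- s
  out
}

#' Centered moving mean with truncated edges
#'
#' The window shrinks at the edges of the trace rather than padding, so no
#' data are fabricated at session boundaries.
#'
#' @param values Trace values on a uniform grid.
#' @param window Window length in seconds.
#' @param dt Sampling interval in seconds.
#' @return Smoothed trace, same length.
#' @export
moving_mean <- function(values, window, dt = 1) {
  if (window < dt) abort("window must cover at least one sample")
  n <- length(values)
  k <- floor(window / (2 * dt))
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Downsample by taking every step-th sample
#'
#' @param values Trace values on a uniform grid.
#' @param step Step in seconds between retained samples.
#' @param dt Sampling interval in seconds.
#' @return Every `step/dt`-th sample starting from the first.
#' @export
downsample_every <- function(values, step, dt = 1) {
  if (step < dt) abort("step must be at least one sampling interval")
  stride <- max(1L, round(step / dt))
  values[seq(1L, length(values), by = stride)]
}

#' Savitzky-Golay filter
#'
#' Thin wrapper over [signal::sgolayfilt()] at the conventions used
#' throughout the pipeline: first-order polynomial, five-sample window by
#' default.
#'
#' @param values Trace values on a uniform grid.
#' @param order Polynomial order (default 1).
#' @param window Filter window length in samples (odd, default 5).
#' @return Filtered trace, same length.
#' @export
savgol <- function(values, order = 1L, window = 5L) {
  if (window %% 2L != 1L) abort("savgol window must be odd")
  if (length(values) < window) abort("trace shorter than the filter window")
  signal::sgolayfilt(values, p = order, n = window)
}

#' Resample a trace onto a uniform grid at a target rate
#'
#' Linear interpolation onto `seq(min(time), max(time), by = 1/rate)`;
#' used to bring all simultaneously recorded channels to a common
#' acquisition rate (conventionally 1 Hz).
#'
#' @param values Trace values.
#' @param time Sample times in seconds (strictly increasing).
#' @param rate Target rate in Hz.
#' @return Tibble with columns `time_s`, `value`.
#' @export
resample_to <- function(values, time, rate) {
  assert_same_length(values, time)
  if (rate <= 0) abort("rate must be positive")
  if (any(diff(time) <= 0)) abort("time must be strictly increasing")
  grid <- seq(time[1L], time[length(time)], by = 1 / rate)
  tibble(time_s = grid, value = approx(time, values, xout = grid)$y)
}

#' Detrend and normalize a raw fluorescence trace
#'
#' The full conditioning pipeline for a bleached fluorescence recording:
#' (1) find the lower convex hull of the trace (its local-minima
#' envelope); (2) fit a non-negative triple exponential through the hull;
#' (3) subtract and divide by the fit; (4) z-score against the baseline
#' window.
#'
#' @param values Raw fluorescence.
#' @param time Sample times (seconds).
#' @param baseline_window Length-2 `(start, end)` seconds for the
#'   normalisation window (conventionally the 20 min before infusion).
#' @return Tibble `time_s`, `value_z` (as [zscore_baseline()]), with the
#'   fitted `detrend_model` attached as attribute `"model"`.
#' @export
preprocess_photometry <- function(values, time, baseline_window) {
  support <- lower_hull_support(values, time)
  model <- fit_triple_exponential(time[support], values[support])
  flat <- detrend(values, time, model)
  out <- zscore_baseline(flat, time, baseline_window)
  attr(out, "model") <- model
  out
}
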