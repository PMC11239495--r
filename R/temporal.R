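#' Finite-difference temporal derivative in per-minute units
#'
#' Central differences in the interior, one-sided differences at the
#' edges, scaled to units per minute (the convention for blood-glucose
#' rates of change, mM/min).
#'
#' @param values Trace on a uniform grid.
#' @param dt Sampling interval in seconds.
#' @return Derivative trace, same length, in `units(values)` per minute.
#' @export
finite_derivative <- function(values, dt = 1) {
  n <- length(values)
  if (n < 2L) abort("finite_derivative() needs at least 2 samples")
  d <- numeric(n)
  d[1L] <- (values[2L] - values[1L]) / dt
  d[n] <- (values[n] - values[n - 1L]) / dt
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (values[i + 1L] - values[i - 1L]) / (2 * dt)
  }
  d * 60
}

#' Lagged cross-correlation between two simultaneously recorded signals
#'
#' Pearson correlation of the overlapping segments of `x` and `y` at each
#' integer-sample lag in `[-max_lag, +max_lag]`. Sign convention:
#' a positive lag means `y` is delayed relative to `x`, so if
#' `y(t) = x(t - L)` the peak falls at `+L`. The peak is the extremum of
#' `|r|` over the grid.
#'
#' @param x,y Equal-length series on a common uniform grid.
#' @param max_lag Maximum lag in seconds.
#' @param dt Sampling interval in seconds.
#' @return A `lag_correlation` object; its `lags` tibble has columns
#'   `lag_s`, `r` (NA where the overlap is degenerate), and fields
#'   `peak_lag`, `peak_r`.
#' @export
lag_crosscorr <- function(x, y, max_lag, dt = 1) {
  n <- assert_same_length(x, y)
  kmax <- floor(max_lag / dt)
  if (n - kmax < 10L) abort("overlap at max lag must be at least 10 samples")
  ks <- seq(-kmax, kmax)
  r <- vapply(ks, function(k) {
    if (k >= 0) {
      xs <- x[seq_len(n - k)]
      ys <- y[seq_len(n - k) + k]
    } else {
      xs <- x[seq_len(n + k) - k]
      ys <- y[seq_len(n + k)]
    }
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))
  if (all(is.na(r))) abort("all lags degenerate: constant overlap everywhere")
  ipk <- which.max(abs(r))
  structure(
    list(
      lags = tibble(lag_s = ks * dt, r = r),
      peak_lag = ks[ipk] * dt,
      peak_r = r[ipk],
      max_lag = max_lag,
      dt = dt
    ),
    class = "lag_correlation"
  )
}

#' @export
print.lag_correlation <- function(x, ...) {
  cat("<lag_correlation> peak r =", signif(x$peak_r, 3),
      "at lag", x$peak_lag, "s (positive lag: second signal delayed)\n")
  invisible(x)
}

#' Ordinary least-squares fit of one response on one predictor
#'
#' The simple linear regression used to relate neural activity to glucose
#' or to its derivative: slope, intercept, R-squared, and the two-sided
#' p-value for a nonzero slope.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @return A `linfit_result`: list with `slope`, `intercept`, `r_squared`,
#'   `p_slope`, `n`.
#' @export
linfit <- function(x, y) {
  n <- assert_same_length(x, y)
  if (n < 3L) abort("linfit() needs at least 3 points")
  if (sd(x) == 0) abort("predictor is constant; slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = sm$r.squared,
      p_slope = unname(sm$coefficients[2L, 4L]),
      n = n
    ),
    class = "linfit_result"
  )
}

#' @export
print.linfit_result <- function(x, ...) {
  cat(sprintf("<linfit> slope %.4g, intercept %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$p_slope, x$n))
  invisible(x)
}

#' Detect the temporal boundaries of a glucose transient
#'
#' Threshold crossing relative to baseline statistics: the transient
#' starts at the first time glucose exceeds `baseline mean + k * baseline
#' sd` sustained for at least `sustain` seconds, and ends at the first
#' later time it falls back below that level for at least `sustain`
#' seconds (or at the last sample if it never returns).
#'
#' @param values Glucose trace (mM) on a uniform grid.
#' @param time Sample times (seconds).
#' @param baseline_window `(start, end)` seconds of the pre-transient
#'   baseline.
#' @param k Threshold in baseline standard deviations (default 3).
#' @param sustain Persistence requirement in seconds (default 60).
#' @return List with `t_start`, `t_end`, `threshold` (mM).
#' @export
detect_transient <- function(values, time, baseline_window, k = 3, sustain = 60) {
  assert_same_length(values, time)
  dt <- grid_dt(time)
  in_base <- time >= baseline_window[1] & time <= baseline_window[2]
  if (!any(in_base)) abort("baseline window contains no samples")
  thr <- mean(values[in_base]) + k * sd(values[in_base])
  need <- max(1L, ceiling(sustain / dt))

  above <- values > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= need &
                  time[starts] > baseline_window[2])
  if (length(cand) == 0L) abort("no sustained transient above threshold")
  i_start <- starts[cand[1L]]

  after <- which(!above & seq_along(above) > ends[cand[1L]])
  t_end <- time[length(time)]
  if (length(after) > 0L) {
    runs2 <- rle(above[(ends[cand[1L]] + 1L):length(above)])
    e2 <- cumsum(runs2$lengths)
    s2 <- e2 - runs2$lengths + 1L
    below <- which(!runs2$values & runs2$lengths >= need)
    if (length(below) > 0L) {
      t_end <- time[ends[cand[1L]] + s2[below[1L]]]
    }
  }
  list(t_start = time[i_start], t_end = t_end, threshold = thr)
}

#' Hysteresis loop of activity against glucose over a transient
#'
#' Interpolates both signals at exactly `n` equally spaced times across
#' the transient and returns the ordered loop together with its signed
#' area (shoelace formula over the closed `(x, activity)` polygon,
#' positive for counterclockwise traversal). A purely proportional
#' relationship collapses the loop onto a line (area 0); derivative
#' coupling opens it.
#'
#' @param activity Activity trace (z-units).
#' @param x Glucose (mM) or glucose-derivative (mM/min) trace.
#' @param time Common sample times (seconds).
#' @param bounds `(t_start, t_end)` of the transient, e.g. from
#'   [detect_transient()].
#' @param n Number of loop points (default 50).
#' @return A `hysteresis_loop`: `points` tibble (`time_s`, `x`,
#'   `activity`), `bounds`, `signed_area`.
#' @export
hysteresis_loop <- function(activity, x, time, bounds, n = 50L) {
  assert_same_length(activity, x, time)
  if (bounds[1] < time[1L] || bounds[2] > time[length(time)] ||
      bounds[1] >= bounds[2]) {
    abort("bounds must lie within the recording and be increasing")
  }
  ts <- seq(bounds[1], bounds[2], length.out = n)
  xi <- approx(time, x, xout = ts)$y
  ai <- approx(time, activity, xout = ts)$y
  j <- c(seq_len(n)[-1L], 1L)
  area <- 0.5 * sum(xi * ai[j] - xi[j] * ai)
  structure(
    list(
      points = tibble(time_s = ts, x = xi, activity = ai),
      bounds = bounds,
      signed_area = area
    ),
    class = "hysteresis_loop"
  )
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf("<hysteresis_loop> %d points over [%.0f, %.0f] s, signed area %.4g\n",
              nrow(x$points), x$bounds[1], x$bounds[2], x$signed_area))
  invisible(x)
}

#' Mean activity in canonical epochs around an infusion
#'
#' Averages activity in named windows expressed in minutes relative to the
#' infusion. The defaults are the canonical baseline (-11 to -2 min),
#' high-glucose-derivative (2 to 11 min) and high-absolute-glucose (11 to
#' 20 min) periods.
#'
#' @param activity Activity trace.
#' @param time Sample times (seconds).
#' @param infusion_time Infusion onset (seconds).
#' @param windows Named list of `(start, end)` windows in minutes relative
#'   to the infusion.
#' @return Tibble `epoch`, `start_min`, `end_min`, `mean`, `diff_vs_baseline`
#'   (NA for the baseline row when a window named `"baseline"` exists).
#' @export
epoch_means <- function(activity, time, infusion_time,
                        windows = list(baseline = c(-11, -2),
                                       deriv = c(2, 11),
                                       abs = c(11, 20))) {
  assert_same_length(activity, time)
  rel_min <- (time - infusion_time) / 60
  res <- purrr::map_dfr(names(windows), function(nm) {
    w <- windows[[nm]]
    sel <- rel_min >= w[1] & rel_min <= w[2]
    if (!any(sel)) abort(sprintf("epoch '%s' contains no samples", nm))
    tibble(epoch = nm, start_min = w[1], end_min = w[2],
           mean = mean(activity[sel]))
  })
  if ("baseline" %in% res$epoch) {
    base <- res$mean[res$epoch == "baseline"]
    res$diff_vs_baseline <- ifelse(res$epoch == "baseline", NA_real_,
                                   res$mean - base)
  } else {
    res$diff_vs_baseline <- NA_real_
  }
  res
}

#' Respiratory energy expenditure by Weir's formula
#'
#' `EE (kcal/min) = 3.94 * VO2 (l/min) + 1.1 * VCO2 (l/min)`, elementwise.
#'
#' @param vo2,vco2 Oxygen consumption and carbon-dioxide production in
#'   l/min (non-negative).
#' @return Energy expenditure in kcal/min.
#' @export
weir_ee <- function(vo2, vco2) {
  assert_same_length(vo2, vco2)
  if (any(vo2 < 0) || any(vco2 < 0)) abort("gas volumes must be non-negative")
  3.94 * vo2 + 1.1 * vco2
}

#' Respiratory exchange ratio
#'
#' `RER = VCO2 / VO2`, elementwise. Values drift toward 1 when
#' carbohydrate oxidation dominates (e.g. after a glucose load).
#'
#' @param vo2,vco2 Gas-exchange series in l/min; `vo2` must be strictly
#'   positive.
#' @return RER series.
#' @export
rer <- function(vo2, vco2) {
  assert_same_length(vo2, vco2)
  if (any(vo2 <= 0)) abort("vo2 must be strictly positive")
  vco2 / vo2
}

#' Detect locomotion bouts from a running-speed trace
#'
#' A bout is a run of samples above `threshold`; runs separated by gaps of
#' at most `max_gap` seconds are merged, and merged bouts shorter than
#' `min_duration` seconds are discarded (gap merging first, then the
#' duration rule). Default thresholds in the field are 18 cm/s for
#' untethered and 10 cm/s for tethered animals.
#'
#' @param speed Speed trace (cm/s) on a uniform grid.
#' @param threshold Speed threshold in cm/s (positive).
#' @param min_duration Minimum bout duration in seconds (default 1).
#' @param max_gap Maximum within-bout gap in seconds (default 2; bouts
#'   must be separated by more than this to count as separate).
#' @param dt Sampling interval in seconds.
#' @return A `bout_set`: tibble `bouts` (`start_s`, `end_s`,
#'   `duration_s`, `mean_speed`), with `count`, `mean_duration`,
#'   `mean_speed` fields.
#' @export
detect_bouts <- function(speed, threshold, min_duration = 1, max_gap = 2,
                         dt = 1) {
  if (threshold <= 0) abort("threshold must be positive")
  time <- (seq_along(speed) - 1L) * dt
  above <- speed > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hot <- which(runs$values)
  bouts <- tibble(start_s = numeric(0), end_s = numeric(0),
                  duration_s = numeric(0), mean_speed = numeric(0))
  if (length(hot) > 0L) {
    s <- starts[hot]
    e <- ends[hot]
    # merge runs whose separating gap is <= max_gap seconds
    ms <- s[1L]; me <- e[1L]
    merged <- list()
    if (length(hot) > 1L) {
      for (i in 2:length(hot)) {
        gap_s <- (s[i] - me - 1L) * dt
        if (gap_s <= max_gap) {
          me <- e[i]
        } else {
          merged[[length(merged) + 1L]] <- c(ms, me)
          ms <- s[i]; me <- e[i]
        }
      }
    }
    merged[[length(merged) + 1L]] <- c(ms, me)
    rows <- purrr::map_dfr(merged, function(b) {
      dur <- (b[2] - b[1] + 1L) * dt
      sel <- b[1]:b[2]
      tibble(start_s = time[b[1]], end_s = time[b[2]] + dt,
             duration_s = dur,
             mean_speed = mean(speed[sel][speed[sel] > threshold]))
    })
    bouts <- rows[rows$duration_s >= min_duration, ]
  }
  structure(
    list(
      bouts = bouts,
      count = nrow(bouts),
      mean_duration = if (nrow(bouts)) mean(bouts$duration_s) else NA_real_,
      mean_speed = if (nrow(bouts)) mean(bouts$mean_speed) else NA_real_,
      threshold = threshold
    ),
    class = "bout_set"
  )
}

#' @export
print.bout_set <- function(x, ...) {
  cat(sprintf("<bout_set> %d bouts above %.1f cm/s; mean duration %.2f s\n",
              x$count, x$threshold, x$mean_duration))
  invisible(x)
}
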