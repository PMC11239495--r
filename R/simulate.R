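#' Parameters of a simulated blood-glucose transient
#'
#' Bi-exponential absorption/clearance kinetics: after the infusion the
#' noiseless curve is
#' `baseline + amplitude * k * (exp(-(t-onset)/tau_clear) - exp(-(t-onset)/tau_abs))`
#' with `k` chosen so the noiseless peak equals `amplitude` above
#' baseline. This is the simplest shape with separate rising and falling
#' phases, which the downstream analyses need to distinguish proportional
#' from derivative coupling. Defaults are set so realized baselines,
#' peaks and maximal rates of change fall inside the physiological ranges
#' reported for infused mice (baseline 3.5-11.1 mM, peak 11.1-34.9 mM,
#' max rate 0.12-1.45 mM/min); intragastric ("IG") delivery uses slower
#' absorption than intraperitoneal ("IP").
#'
#' @param baseline Baseline glucose in mM.
#' @param amplitude Peak height above baseline in mM (non-negative).
#' @param tau_abs Absorption time constant in minutes.
#' @param tau_clear Clearance time constant in minutes.
#' @param noise_sd Measurement-noise sd in mM. The noise is temporally
#'   correlated (white noise low-pass filtered with `noise_tau`), as an
#'   electrochemical telemetry sensor reports slowly varying readings
#'   rather than sample-to-sample white noise.
#' @param noise_tau Noise correlation time constant in seconds
#'   (default 30; 0 gives white noise).
#' @param route `"IP"` or `"IG"`; sets the default `tau_abs` (6 vs 9 min).
#' @return A `glucose_params` list.
#' @export
glucose_params <- function(baseline = 7.3, amplitude = 5.5,
                           tau_abs = if (route == "IG") 9 else 6,
                           tau_clear = 30, noise_sd = 0.1, noise_tau = 30,
                           route = c("IP", "IG")) {
  route <- match.arg(route)
  if (amplitude < 0) abort("amplitude must be non-negative")
  if (tau_abs <= 0 || tau_clear <= 0) abort("time constants must be positive")
  structure(list(baseline = baseline, amplitude = amplitude,
                 tau_abs = tau_abs, tau_clear = tau_clear,
                 noise_sd = noise_sd, noise_tau = noise_tau, route = route),
            class = "glucose_params")
}

#' Configuration for a synthetic recording session
#'
#' Collects every tunable of the generator: grid rates, infusion timing
#' and kinetics, cell-population composition, coupling gains, noise, the
#' photobleaching model, and the calcium-indicator kernel. Defaults
#' emulate the study conditions the analyses assume: 1-Hz master rate,
#' 5-Hz cell traces, a session long enough for a 20-min pre-infusion
#' baseline and 20+ min of post-infusion coverage, and class prevalences
#' at the reported single-cell proportions (25% G, 11% dG, 33% iG, 31%
#' idG, 2% no-response, scaled to sum to one).
#'
#' @param duration Session length in seconds.
#' @param master_rate Master (session-channel) rate in Hz.
#' @param cell_rate Single-cell trace rate in Hz.
#' @param infusion_time Infusion onset in seconds from session start.
#' @param infusion_route `"IP"` or `"IG"`.
#' @param seed Integer RNG seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @param n_cells Number of simulated cells.
#' @param prevalences Named fractions over classes
#'   `G, dG, iG, idG, N/A`; must sum to 1.
#' @param coupling_gains List: `slow_gain_mean`, `slow_gain_sd` (glucose
#'   coupling, z-units per unit template), `running_gain` (magnitude of
#'   locomotor coupling), `running_mix` (fractions of positively,
#'   negatively and non-running-coupled cells).
#' @param noise_sd Per-cell white-noise sd in z-units.
#' @param bleach_params Triple-exponential photobleaching model:
#'   `amplitudes`, `taus` (seconds), `offset`; multiplied into the raw
#'   photometry trace and (scaled per cell) added as a slow trend to cell
#'   traces.
#' @param cell_bleach_sd sd of per-cell additive bleach-trend amplitude
#'   (z-units); 0 disables cell bleaching.
#' @param indicator_tau Calcium-indicator decay constant in seconds used
#'   to filter the locomotor input (default 1.5 s, a slow indicator).
#' @param glucose A [glucose_params()] object; default derived from
#'   `infusion_route`.
#' @param locomotion List of bout-process parameters: `bout_rate`
#'   (bouts/s), `min_duration` + exponential `mean_extra_duration` (s),
#'   lognormal super-threshold speed (`speed_meanlog`, `speed_sdlog`),
#'   detection `threshold` (cm/s).
#' @param metabolic List of gas-exchange/temperature couplings (baselines,
#'   gains, time constants, noise); placeholders tuned for the sign and
#'   direction of post-glucose effects (RER and temperature rise).
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration = 3600, master_rate = 1, cell_rate = 5,
                       infusion_time = 1500,
                       infusion_route = c("IP", "IG"),
                       seed = 1L, n_cells = 100L,
                       prevalences = c(G = 0.245, dG = 0.108, iG = 0.323,
                                       idG = 0.304, `N/A` = 0.020),
                       coupling_gains = list(slow_gain_mean = 3,
                                             slow_gain_sd = 0.5,
                                             running_gain = 0.5,
                                             running_mix = c(positive = 0.28,
                                                             negative = 0.14,
                                                             none = 0.58)),
                       noise_sd = 1,
                       bleach_params = list(amplitudes = c(0.3, 0.2, 0.1),
                                            taus = c(300, 1500, 6000),
                                            offset = 1),
                       cell_bleach_sd = 0.2,
                       indicator_tau = 1.5,
                       glucose = NULL,
                       locomotion = list(bout_rate = 1 / 60,
                                         min_duration = 1,
                                         mean_extra_duration = 2,
                                         speed_meanlog = log(7),
                                         speed_sdlog = 0.4,
                                         threshold = 18),
                       metabolic = list(vo2_base = 0.0025,
                                        run_gain = 0.15,
                                        run_tau = 60,
                                        rer_base = 0.85,
                                        rer_gain = 0.10,
                                        rer_tau = 300,
                                        temp_base = 36.5,
                                        temp_gain = 0.4,
                                        temp_tau = 600,
                                        noise_frac = 0.02)) {
  infusion_route <- match.arg(infusion_route)
  if (master_rate <= 0 || cell_rate <= 0) abort("rates must be positive")
  if (abs(sum(prevalences) - 1) > 1e-9) abort("prevalences must sum to 1")
  if (any(prevalences < 0)) abort("prevalences must be non-negative")
  if (infusion_time < 20 * 60) {
    abort("session must cover at least 20 min before the infusion")
  }
  if (duration - infusion_time < 25 * 60) {
    abort("session must cover at least 25 min after the infusion")
  }
  if (is.null(glucose)) glucose <- glucose_params(route = infusion_route)
  structure(list(duration = duration, master_rate = master_rate,
                 cell_rate = cell_rate, infusion_time = infusion_time,
                 infusion_route = infusion_route, seed = as.integer(seed),
                 n_cells = as.integer(n_cells), prevalences = prevalences,
                 coupling_gains = coupling_gains, noise_sd = noise_sd,
                 bleach_params = bleach_params,
                 cell_bleach_sd = cell_bleach_sd,
                 indicator_tau = indicator_tau, glucose = glucose,
                 locomotion = locomotion, metabolic = metabolic),
            class = "sim_config")
}

# Causal single-exponential smoothing (recursive EMA), used both as the
# indicator kernel and for slow metabolic couplings.
ema <- function(x, tau, dt) {
  if (tau <= 0) return(x)
  a <- exp(-dt / tau)
  as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
}

# Normalized triple-exponential bleach curve, value 1 at t = 0.
bleach_curve <- function(t, params) {
  raw <- texp_curve(t, params$amplitudes, params$taus, params$offset)
  raw / raw[1L]
}

#' Simulate a blood-glucose transient
#'
#' Evaluates the bi-exponential transient of [glucose_params()] on a time
#' grid, adds white measurement noise, and post-hoc checks the noiseless
#' curve against the physiological ranges (peak within 11.1-34.9 mM,
#' maximal rate of change within 0.12-1.45 mM/min, baseline within
#' 3.5-11.1 mM), warning when a range is violated.
#'
#' @param params A [glucose_params()] object.
#' @param time Time grid in seconds (uniform).
#' @param onset Infusion onset in seconds; must lie within the grid.
#' @return Glucose series in mM on `time`.
#' @export
simulate_glucose <- function(params, time, onset) {
  if (abs(params$tau_abs - params$tau_clear) < 1e-12) {
    abort("degenerate kinetics: tau_abs must differ from tau_clear")
  }
  if (params$amplitude < 0) abort("amplitude must be non-negative")
  if (onset < time[1L] || onset > time[length(time)]) {
    abort("onset must lie within the time grid")
  }
  ta <- params$tau_abs
  tc <- params$tau_clear
  tp <- ta * tc / (tc - ta) * log(tc / ta)
  k <- 1 / (exp(-tp / tc) - exp(-tp / ta))
  dmin <- pmax((time - onset) / 60, 0)
  clean <- params$baseline +
    params$amplitude * k * (exp(-dmin / tc) - exp(-dmin / ta))

  if (params$baseline < 3.5 || params$baseline > 11.1) {
    warn(sprintf("baseline %.2f mM outside the physiological range 3.5-11.1 mM",
                 params$baseline))
  }
  peak <- max(clean)
  if (params$amplitude > 0 && (peak < 11.1 || peak > 34.9)) {
    warn(sprintf("noiseless peak %.2f mM outside the range 11.1-34.9 mM", peak))
  }
  if (params$amplitude > 0) {
    dt <- grid_dt(time)
    max_rate <- max(finite_derivative(clean, dt))
    if (max_rate < 0.12 || max_rate > 1.45) {
      warn(sprintf("noiseless max rate %.2f mM/min outside the range 0.12-1.45 mM/min",
                   max_rate))
    }
  }
  noise <- rnorm(length(time))
  tau <- params$noise_tau %||% 0
  if (tau > 0 && params$noise_sd > 0) {
    dt <- grid_dt(time)
    a <- exp(-dt / tau)
    noise <- ema(noise, tau, dt) / sqrt((1 - a) / (1 + a))
  }
  clean + params$noise_sd * noise
}

#' Simulate a bout-structured running-speed trace
#'
#' Bout start times follow a Poisson point process; each bout lasts
#' `min_duration` plus an exponential excess and runs at a lognormal
#' speed above the detection threshold. Speed is zero between bouts
#' (overlapping bouts take the larger speed).
#'
#' @param config A [sim_config()].
#' @param rate Sampling rate in Hz of the returned trace (default the
#'   configured `cell_rate`).
#' @return Tibble `time_s`, `speed_cms` with the generated ground-truth
#'   bout table attached as attribute `"bouts"`.
#' @export
simulate_locomotion <- function(config, rate = config$cell_rate) {
  loc <- config$locomotion
  if (loc$bout_rate < 0) abort("bout rate must be non-negative")
  if (rate <= 0) abort("sampling rate must be positive")
  dt <- 1 / rate
  time <- seq(0, config$duration - dt, by = dt)
  speed <- numeric(length(time))

  starts <- numeric(0)
  if (loc$bout_rate > 0) {
    t <- rexp(1, loc$bout_rate)
    while (t < config$duration) {
      starts <- c(starts, t)
      t <- t + rexp(1, loc$bout_rate)
    }
  }
  bouts <- tibble(start_s = numeric(0), end_s = numeric(0),
                  speed_cms = numeric(0))
  if (length(starts) > 0L) {
    durs <- loc$min_duration + rexp(length(starts), 1 / loc$mean_extra_duration)
    spds <- loc$threshold + rlnorm(length(starts), loc$speed_meanlog,
                                   loc$speed_sdlog)
    bouts <- tibble(start_s = starts, end_s = pmin(starts + durs,
                                                   config$duration),
                    speed_cms = spds)
    for (i in seq_len(nrow(bouts))) {
      sel <- time >= bouts$start_s[i] & time < bouts$end_s[i]
      speed[sel] <- pmax(speed[sel], bouts$speed_cms[i])
    }
  }
  out <- tibble(time_s = time, speed_cms = speed)
  attr(out, "bouts") <- bouts
  out
}

#' Simulate gas-exchange and body-temperature channels
#'
#' Couplings are placeholders tuned for the direction of the reported
#' post-glucose effects: VO2 rises with (lagged, smoothed) running, the
#' respiratory exchange ratio VCO2/VO2 drifts upward after the glucose
#' transient, and body temperature slowly increases post-infusion. All
#' channels carry small multiplicative-scale additive noise and stay
#' strictly positive.
#'
#' @param glucose Glucose series (mM) on the master grid.
#' @param running Running-speed series (cm/s) on the same grid.
#' @param config A [sim_config()].
#' @return Tibble `vo2_lmin`, `vco2_lmin`, `temp_C` aligned to the input
#'   grid.
#' @export
simulate_metabolics <- function(glucose, running, config) {
  if (length(glucose) != length(running)) {
    abort("glucose and running must be on a common grid")
  }
  met <- config$metabolic
  dt <- 1 / config$master_rate
  exc <- pmax(glucose - config$glucose$baseline, 0) /
    max(config$glucose$amplitude, 1e-9)
  run_sm <- ema(running, met$run_tau, dt) / 20   # ~unit scale at 20 cm/s
  exc_sm <- ema(exc, met$rer_tau, dt)
  exc_slow <- ema(exc, met$temp_tau, dt)

  n <- length(glucose)
  vo2 <- met$vo2_base * (1 + met$run_gain * run_sm) *
    (1 + met$noise_frac * rnorm(n))
  rer_t <- met$rer_base + met$rer_gain * exc_sm
  vco2 <- rer_t * vo2 * (1 + met$noise_frac * rnorm(n))
  temp <- met$temp_base + met$temp_gain * exc_slow +
    0.05 * met$noise_frac * met$temp_base * rnorm(n)
  tibble(vo2_lmin = vo2, vco2_lmin = vco2, temp_C = temp)
}

#' Draw ground-truth class labels for a simulated population
#'
#' Multinomial draw over the configured class prevalences; used by
#' [simulate_cells()] and exported so label-frequency properties can be
#' checked at large `n` without generating traces.
#'
#' @param n Number of cells.
#' @param prevalences Named non-negative fractions summing to 1.
#' @return Character vector of class labels.
#' @export
draw_cell_labels <- function(n, prevalences) {
  if (n <= 0) abort("n must be positive")
  if (abs(sum(prevalences) - 1) > 1e-9) abort("prevalences must sum to 1")
  sample(names(prevalences), n, replace = TRUE, prob = prevalences)
}

# Class response waveforms evaluated on an arbitrary grid: the z-scored
# 1.5-min-smoothed glucose (G), its re-smoothed derivative (dG), and
# their negatives.
class_waveforms <- function(glucose, time, out_time) {
  dt <- grid_dt(time)
  g_sm <- moving_mean(glucose, 90, dt)
  dg <- moving_mean(finite_derivative(g_sm, dt), 90, dt)
  g_w <- zscore_vec(g_sm, centre_only = TRUE)
  dg_w <- zscore_vec(dg, centre_only = TRUE)
  list(
    G = approx(time, g_w, xout = out_time, rule = 2)$y,
    dG = approx(time, dg_w, xout = out_time, rule = 2)$y
  )
}

#' Simulate a matrix of single-cell traces with ground-truth labels
#'
#' Each cell's trace is `slow_gain * (its class waveform evaluated on the
#' session's glucose) + running_gain * (indicator-filtered running speed)
#' + bleach trend + white noise`, at the configured cell rate. Class
#' waveforms are the smoothed glucose (G), its derivative (dG) and their
#' negatives (iG, idG); `N/A` cells have zero glucose coupling. The sign
#' of the running gain sets the cell's ground-truth running class.
#'
#' @param config A [sim_config()].
#' @param glucose Glucose series (mM) on the master grid.
#' @param glucose_time Master-grid times (seconds).
#' @param running Tibble from [simulate_locomotion()] (cell-rate grid), or
#'   a numeric speed vector on that grid.
#' @return List: `traces` (matrix, rows = cell-grid samples, columns =
#'   cells), `time` (cell grid, seconds), `truth` (tibble `cell_id`,
#'   `class`, `running_class`, `slow_gain`, `running_gain`,
#'   `bleach_amp`), `waveforms` (list `G`, `dG` on the cell grid).
#' @export
simulate_cells <- function(config, glucose, glucose_time, running) {
  if (config$n_cells <= 0) abort("n_cells must be positive")
  dt_c <- 1 / config$cell_rate
  time_c <- seq(0, config$duration - dt_c, by = dt_c)
  speed <- if (is.data.frame(running)) running$speed_cms else running
  if (length(speed) != length(time_c)) {
    abort("running must be sampled on the cell-rate grid")
  }
  wf <- class_waveforms(glucose, glucose_time, time_c)
  run_kernel <- ema(speed, config$indicator_tau, dt_c)
  run_z <- zscore_vec(run_kernel, centre_only = TRUE)

  g <- config$coupling_gains
  labels <- draw_cell_labels(config$n_cells, config$prevalences)
  run_class <- sample(names(g$running_mix), config$n_cells, replace = TRUE,
                      prob = g$running_mix)
  slow_gain <- abs(rnorm(config$n_cells, g$slow_gain_mean, g$slow_gain_sd))
  slow_gain[labels == "N/A"] <- 0
  run_gain <- g$running_gain *
    (as.numeric(run_class == "positive") - as.numeric(run_class == "negative"))
  bleach_amp <- if (config$cell_bleach_sd > 0) {
    abs(rnorm(config$n_cells, 0, config$cell_bleach_sd))
  } else {
    numeric(config$n_cells)
  }
  bl <- bleach_curve(time_c, config$bleach_params)

  base_wave <- cbind(G = wf$G, dG = wf$dG, iG = -wf$G, idG = -wf$dG,
                     `N/A` = 0)
  slow_part <- sweep(base_wave[, labels, drop = FALSE], 2L, slow_gain, "*")
  traces <- slow_part +
    outer(run_z, run_gain) +
    outer(bl, bleach_amp) +
    matrix(rnorm(length(time_c) * config$n_cells, sd = config$noise_sd),
           nrow = length(time_c))
  colnames(traces) <- sprintf("cell_%03d", seq_len(config$n_cells))

  list(
    traces = traces,
    time = time_c,
    truth = tibble(cell_id = colnames(traces), class = labels,
                   running_class = run_class, slow_gain = slow_gain,
                   running_gain = run_gain, bleach_amp = bleach_amp),
    waveforms = wf
  )
}

#' Simulate a full multichannel recording session
#'
#' Orchestrates the generator: glucose transient, bout-structured
#' locomotion, gas exchange and temperature, a labelled single-cell
#' population, and a population photometry channel consistent with the
#' cells (the prevalence-weighted cell mean, z-scored to the 20-min
#' pre-infusion baseline). A raw bleached fluorescence trace
#' (`bleach(t) * (1 + scale * population)`) is attached for testing the
#' detrending pipeline. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `session_sim` list: `session` (tibble `time_s`,
#'   `glucose_mM`, `activity_z`, `running_cms`, `vo2_lmin`, `vco2_lmin`,
#'   `temp_C`, with `events` and `meta` attributes), `cells`, `cell_time`,
#'   `truth`, `running_cells` (5-Hz speed), `raw_f` (bleached raw
#'   photometry on the master grid), `waveforms`, `config`.
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    dt_m <- 1 / config$master_rate
    time_m <- seq(0, config$duration - dt_m, by = dt_m)
    glucose <- simulate_glucose(config$glucose, time_m, config$infusion_time)

    loco <- simulate_locomotion(config, rate = config$cell_rate)
    # master-rate running: bin means of the cell-rate trace
    ratio <- round(config$cell_rate / config$master_rate)
    run_m <- colMeans(matrix(loco$speed_cms, nrow = ratio))

    met <- simulate_metabolics(glucose, run_m, config)
    cells <- simulate_cells(config, glucose, time_m, loco)

    pop <- rowMeans(cells$traces)
    pop_m <- colMeans(matrix(pop, nrow = ratio))
    base_win <- c(config$infusion_time - 20 * 60, config$infusion_time)
    act <- zscore_baseline(pop_m, time_m, base_win)

    bl <- bleach_curve(time_m, config$bleach_params)
    raw_f <- bl * (1 + 0.03 * pmax(act$value_z, -20))

    session <- tibble(
      time_s = time_m,
      glucose_mM = glucose,
      activity_z = act$value_z,
      running_cms = run_m,
      vo2_lmin = met$vo2_lmin,
      vco2_lmin = met$vco2_lmin,
      temp_C = met$temp_C
    )
    events <- tibble(label = "infusion", time_s = config$infusion_time,
                     route = config$infusion_route)
    session <- new_session_record(session, events = events,
                                  meta = list(seed = config$seed,
                                              duration = config$duration,
                                              master_rate = config$master_rate))
    structure(
      list(session = session, cells = cells$traces,
           cell_time = cells$time, truth = cells$truth,
           running_cells = loco$speed_cms, raw_f = raw_f,
           waveforms = cells$waveforms, config = config),
      class = "session_sim"
    )
  })
}

#' @export
print.session_sim <- function(x, ...) {
  cat(sprintf("<session_sim> %d s at %g Hz; %d cells at %g Hz; infusion (%s) at %d s; seed %d\n",
              x$config$duration, x$config$master_rate,
              ncol(x$cells), x$config$cell_rate,
              x$config$infusion_route, x$config$infusion_time,
              x$config$seed))
  invisible(x)
}
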