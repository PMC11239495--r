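# Independent brute-force oracles used to validate the implementations.
# These deliberately use different algorithms from the package code.

# O(n^3) lower-hull oracle: a sample is a support point iff it does not
# lie strictly above any segment between an earlier and a later sample.
oracle_lower_hull <- function(time, values, tol = 1e-9) {
  n <- length(values)
  on_hull <- rep(TRUE, n)
  for (i in setdiff(seq_len(n), c(1L, n))) {
    for (j in 1:(i - 1L)) {
      for (k in (i + 1L):n) {
        yline <- values[j] + (values[k] - values[j]) *
          (time[i] - time[j]) / (time[k] - time[j])
        if (values[i] > yline + tol) {
          on_hull[i] <- FALSE
          break
        }
      }
      if (!on_hull[i]) break
    }
  }
  which(on_hull)
}

# Morphological-closing bout oracle: bridge sub-threshold gaps of at most
# max_gap seconds sample-by-sample, then enumerate runs and drop the
# short ones. Structurally different from the run-merge implementation.
oracle_bouts <- function(speed, threshold, min_duration = 1, max_gap = 2,
                         dt = 1) {
  above <- speed > threshold
  n <- length(above)
  bridged <- above
  i <- 1L
  while (i <= n) {
    if (!bridged[i]) {
      j <- i
      while (j <= n && !bridged[j]) j <- j + 1L
      gap_len <- (j - i) * dt
      interior <- i > 1L && j <= n
      if (interior && gap_len <= max_gap) bridged[i:(j - 1L)] <- TRUE
      i <- j
    } else {
      i <- i + 1L
    }
  }
  bouts <- list()
  i <- 1L
  while (i <= n) {
    if (bridged[i]) {
      j <- i
      while (j <= n && bridged[j]) j <- j + 1L
      dur <- (j - i) * dt
      if (dur >= min_duration) {
        bouts[[length(bouts) + 1L]] <- c(start = (i - 1L) * dt,
                                         end = (j - 1L) * dt, dur = dur)
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  bouts
}

# Plain union-find for connected components over joined pairs.
oracle_components <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges$roi_a[e])
      rb <- find(edges$roi_b[e])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  split(ids, roots)
}

# Noiseless bi-exponential transient (closed form, written independently
# of the generator).
oracle_transient <- function(t_min, baseline, amplitude, tau_a, tau_c) {
  tp <- tau_a * tau_c / (tau_c - tau_a) * log(tau_c / tau_a)
  k <- 1 / (exp(-tp / tau_c) - exp(-tp / tau_a))
  shape <- ifelse(t_min < 0, 0, exp(-t_min / tau_c) - exp(-t_min / tau_a))
  baseline + amplitude * k * shape
}

# A short synthetic session config kept small for test runtime.
quick_config <- function(seed = 1L, n_cells = 40L, ...) {
  sim_config(seed = seed, n_cells = n_cells, ...)
}

# Shared fixture: a noiseless reference session and its templates.
make_templates <- function(seed = 101) {
  cfg <- quick_config(seed = seed, n_cells = 4)
  cfg$glucose$noise_sd <- 0
  sim <- simulate_session(cfg)
  list(sim = sim,
       templates = build_templates(sim$session$glucose_mM,
                                   sim$session$time_s,
                                   cfg$infusion_time),
       infusion = cfg$infusion_time)
}
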