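test_that("finite differences recover analytic derivatives in per-minute units", {
  expect_equal(finite_derivative(rep(4, 10)), rep(0, 10))
  # ramp of 0.5 units/min sampled at 1 Hz
  t <- seq(0, 599)
  expect_equal(finite_derivative(7 + 0.5 * t / 60), rep(0.5, 600),
               tolerance = 1e-9)
  # sine -> cosine within O(dt^2)
  dt <- 0.5
  ts <- seq(0, 20, by = dt)
  d <- finite_derivative(sin(ts), dt = dt) / 60
  expect_lt(max(abs(d[2:(length(d) - 1)] - cos(ts)[2:(length(d) - 1)])),
            dt^2)
  expect_error(finite_derivative(1), "2 samples")
})

test_that("derivative then cumulative re-integration recovers the input", {
  dt <- 0.1
  ts <- seq(0, 30, by = dt)
  x <- sin(ts) + 0.3 * ts
  d <- finite_derivative(x, dt = dt) / 60   # back to per-second units
  recon <- x[1] + cumsum(c(0, (d[-length(d)] + d[-1]) / 2)) * dt
  expect_lt(max(abs(recon - x)), 10 * dt^2)
})

test_that("lagged cross-correlation has the documented sign convention", {
  withr::with_seed(2, x <- as.numeric(arima.sim(list(ar = 0.95), 2000)))
  self <- lag_crosscorr(x, x, max_lag = 60)
  expect_equal(self$peak_lag, 0)
  expect_equal(self$peak_r, 1)

  # y delayed by 30 s peaks at +30 exactly
  y <- dplyr::lag(x, 30)
  keep <- !is.na(y)
  xc <- lag_crosscorr(x[keep], y[keep], max_lag = 90)
  expect_equal(xc$peak_lag, 30)
  expect_gt(xc$peak_r, 0.99)

  # activity proportional to the negated derivative anticipates glucose:
  # the most negative correlation sits at a negative lag (activity leads)
  tt <- seq(0, 3599)
  g <- oracle_transient((tt - 900) / 60, 7.3, 10, 6, 30)
  a <- -finite_derivative(g)
  xg <- lag_crosscorr(g, a, max_lag = 600)
  i_neg <- which.min(xg$lags$r)
  expect_lt(xg$lags$r[i_neg], -0.4)
  expect_lt(xg$lags$lag_s[i_neg], 0)
})

test_that("linear fits reproduce hand-computed OLS", {
  f <- suppressWarnings(linfit(c(1, 2, 3), c(1, 3, 5)))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, -1)
  expect_equal(f$r_squared, 1)

  f2 <- suppressWarnings(linfit(1:10, 2 * (1:10)))
  expect_equal(f2$slope, 2)
  expect_equal(f2$r_squared, 1)
  expect_error(linfit(rep(1, 5), 1:5), "constant")

  # independent noise: R^2 stays near zero
  small <- withr::with_seed(10, {
    mean(replicate(40, linfit(rnorm(1000), rnorm(1000))$r_squared < 0.02))
  })
  expect_gte(small, 0.95)
})

test_that("transient detection finds threshold crossings and handles edge cases", {
  t <- seq(0, 5399)
  g <- oracle_transient((t - 1500) / 60, 7.3, 10, 6, 30)
  noisy <- withr::with_seed(3, g + 0.05 * rnorm(length(g)))
  det <- detect_transient(noisy, t, baseline_window = c(0, 1200))
  # noiseless first crossing of the baseline-derived threshold
  thr <- det$threshold
  t_cross <- t[which(g > thr & t > 1200)[1]]
  expect_lt(abs(det$t_start - t_cross), 60)
  expect_gt(det$t_end, det$t_start)

  expect_error(detect_transient(rep(7.3, 1000) +
                                  withr::with_seed(1, rnorm(1000, 0, 0.01)),
                                seq_len(1000) - 1, c(0, 500)),
               "no sustained transient")

  # step with no return ends at the last sample
  step <- c(rep(0, 600), rep(5, 600)) +
    withr::with_seed(2, rnorm(1200, 0, 0.01))
  ds <- detect_transient(step, seq_len(1200) - 1, c(0, 500))
  expect_equal(ds$t_end, 1199)
})

test_that("hysteresis loops have 50 points, shoelace area, and the right invariances", {
  t <- seq(0, 3599)
  g <- oracle_transient((t - 900) / 60, 7.3, 10, 6, 30)

  # proportional coupling collapses the loop
  prop <- hysteresis_loop(-2 * g + 1, g, t, bounds = c(900, 3000))
  expect_equal(nrow(prop$points), 50L)
  expect_lt(abs(prop$signed_area), 1e-9)

  # derivative coupling opens it; traversal of the (g, -dg) curve over a
  # rise-then-fall transient is counterclockwise (positive area)
  a <- -finite_derivative(g)
  loop <- hysteresis_loop(a, g, t, bounds = c(900, 3000))
  expect_equal(nrow(loop$points), 50L)
  expect_gt(abs(loop$signed_area), 0.1)
  expect_gt(loop$signed_area, 0)

  # area invariant to offsets on either axis, flips under time reversal
  sh <- hysteresis_loop(a + 5, g, t, bounds = c(900, 3000))
  expect_equal(sh$signed_area, loop$signed_area, tolerance = 1e-9)
  sh2 <- hysteresis_loop(a, g + 100, t, bounds = c(900, 3000))
  expect_equal(sh2$signed_area, loop$signed_area, tolerance = 1e-6)
  flipped <- hysteresis_loop(rev(a), rev(g), t,
                             bounds = c(t[length(t)] - 3000,
                                        t[length(t)] - 900))
  expect_equal(flipped$signed_area, -loop$signed_area, tolerance = 1e-6)

  expect_error(hysteresis_loop(a, g, t, bounds = c(-10, 100)), "bounds")
})

test_that("epoch means use the canonical windows", {
  t <- seq(0, 3599)
  infusion <- 1500
  act <- (t - infusion) / 60     # activity equal to minutes from infusion
  em <- epoch_means(act, t, infusion)
  expect_equal(em$mean[em$epoch == "baseline"], -6.5, tolerance = 0.01)
  expect_equal(em$mean[em$epoch == "deriv"], 6.5, tolerance = 0.01)
  expect_equal(em$mean[em$epoch == "abs"], 15.5, tolerance = 0.01)

  emc <- epoch_means(rep(2, length(t)), t, infusion)
  expect_equal(emc$diff_vs_baseline[emc$epoch != "baseline"], c(0, 0))
  expect_error(epoch_means(act, t, infusion,
                           windows = list(late = c(100, 200))),
               "no samples")
})

test_that("a derivative-inhibited population dips only in the high-derivative epoch", {
  cfg <- quick_config(seed = 6, n_cells = 60,
                      prevalences = c(G = 0, dG = 0, iG = 0, idG = 1,
                                      `N/A` = 0))
  sim <- simulate_session(cfg)
  em <- epoch_means(sim$session$activity_z, sim$session$time_s,
                    cfg$infusion_time)
  d_deriv <- em$diff_vs_baseline[em$epoch == "deriv"]
  d_abs <- em$diff_vs_baseline[em$epoch == "abs"]
  expect_lt(d_deriv, 0)
  expect_lt(abs(d_abs), abs(d_deriv))
})

test_that("metabolic formulas are exact", {
  expect_equal(weir_ee(1, 0), 3.94)
  expect_equal(weir_ee(0, 1), 1.1)
  expect_equal(weir_ee(0, 0), 0)
  expect_equal(weir_ee(0.5, 0.5), 2.52)
  expect_equal(weir_ee(c(1, 0.5), c(0, 0.5)), c(3.94, 2.52))
  expect_error(weir_ee(-1, 0), "non-negative")

  expect_equal(rer(1, 0.8), 0.8)
  expect_equal(rer(2, 2), 1)
  expect_error(rer(c(1, 0), c(1, 1)), "positive")
})

test_that("bout detection applies merge-then-duration rules and matches the oracle", {
  expect_equal(detect_bouts(c(0, 20, 20, 0, 0, 0, 20, 20, 20, 0), 18)$count,
               2L)
  expect_equal(detect_bouts(c(0, 20, 20, 0, 0, 20, 20, 0), 18)$count, 1L)
  expect_equal(detect_bouts(rep(0, 50), 18)$count, 0L)
  expect_error(detect_bouts(rep(0, 50), -1), "positive")

  withr::with_seed(31, {
    for (rep in 1:200) {
      dt <- sample(c(0.2, 0.5, 1), 1)
      n <- sample(20:120, 1)
      speed <- ifelse(runif(n) < 0.35, runif(n, 19, 40), 0)
      det <- detect_bouts(speed, 18, dt = dt)
      orc <- oracle_bouts(speed, 18, dt = dt)
      expect_equal(det$count, length(orc))
      if (length(orc) > 0) {
        expect_equal(det$bouts$start_s, vapply(orc, `[[`, 0, "start"))
        expect_equal(det$bouts$duration_s, vapply(orc, `[[`, 0, "dur"))
      }
    }
  })
})
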