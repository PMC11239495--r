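test_that("glucose transient has the closed-form shape, peak and timing", {
  time <- seq(0, 5400)
  p0 <- glucose_params(amplitude = 0, noise_sd = 0)
  expect_equal(simulate_glucose(p0, time, 1200), rep(7.3, length(time)))

  # noiseless argmax of the bi-exponential: (ta*tc/(tc-ta)) * log(tc/ta)
  p <- glucose_params(amplitude = 12, tau_abs = 5, tau_clear = 20,
                      noise_sd = 0)
  g <- suppressWarnings(simulate_glucose(p, time, 1200))
  t_peak_min <- (time[which.max(g)] - 1200) / 60
  expect_equal(t_peak_min, (5 * 20 / 15) * log(20 / 5), tolerance = 1e-3)

  # peak equals baseline + amplitude by construction (study's mean peak)
  p24 <- glucose_params(baseline = 7.3, amplitude = 16.7, noise_sd = 0)
  g24 <- suppressWarnings(simulate_glucose(p24, time, 1200))
  expect_equal(max(g24), 24.0, tolerance = 1e-6)  # 1-s grid quantisation
  # matches the independently written closed form everywhere
  expect_equal(g24, oracle_transient((time - 1200) / 60, 7.3, 16.7, 6, 30),
               tolerance = 1e-9)
})

test_that("glucose generator validates kinetics and warns outside ranges", {
  time <- seq(0, 5400)
  expect_error(simulate_glucose(glucose_params(tau_abs = 10, tau_clear = 10),
                                time, 1200), "degenerate")
  expect_error(simulate_glucose(glucose_params(), time, 1e6), "onset")
  # default parameters stay inside all printed physiological ranges
  expect_silent(g <- simulate_glucose(glucose_params(noise_sd = 0),
                                      time, 1200))
  expect_gte(max(g), 11.1)
  expect_lte(max(g), 34.9)
  rate <- max(finite_derivative(g))
  expect_gte(rate, 0.12)
  expect_lte(rate, 1.45)
  # an over-fast transient triggers the max-rate warning
  expect_warning(
    simulate_glucose(glucose_params(amplitude = 16.7, noise_sd = 0),
                     time, 1200),
    "rate")
})

test_that("locomotion is bout-structured, deterministic, and matches its own ground truth", {
  cfg <- quick_config(seed = 5)
  a <- withr::with_seed(11, simulate_locomotion(cfg))
  b <- withr::with_seed(11, simulate_locomotion(cfg))
  expect_identical(a, b)

  cfg0 <- quick_config(seed = 5)
  cfg0$locomotion$bout_rate <- 0
  z <- withr::with_seed(1, simulate_locomotion(cfg0))
  expect_true(all(z$speed_cms == 0))
  cfg0$locomotion$bout_rate <- -1
  expect_error(withr::with_seed(1, simulate_locomotion(cfg0)), "rate")

  # detect_bouts on the generated trace recovers the generated bout count
  # after accounting for the merge rule (gaps must exceed 2 s)
  loco <- withr::with_seed(42, simulate_locomotion(cfg))
  truth <- attr(loco, "bouts")
  det <- detect_bouts(loco$speed_cms, cfg$locomotion$threshold,
                      dt = 1 / cfg$cell_rate)
  merged <- oracle_bouts(loco$speed_cms, cfg$locomotion$threshold,
                         dt = 1 / cfg$cell_rate)
  expect_equal(det$count, length(merged))
  expect_gt(det$count, 0)
})

test_that("metabolic channels have the right directions and stay positive", {
  cfg <- quick_config()
  cfg$metabolic$noise_frac <- 0
  n <- cfg$duration
  flat_g <- rep(cfg$glucose$baseline, n)
  no_run <- numeric(n)
  met0 <- simulate_metabolics(flat_g, no_run, cfg)
  expect_equal(var(met0$vo2_lmin), 0)
  expect_equal(var(rer(met0$vo2_lmin, met0$vco2_lmin)), 0)

  # RER rises after a glucose transient (noiseless)
  time <- seq(0, cfg$duration - 1)
  g <- suppressWarnings(
    simulate_glucose(glucose_params(noise_sd = 0), time, cfg$infusion_time))
  met <- simulate_metabolics(g, no_run, cfg)
  r <- rer(met$vo2_lmin, met$vco2_lmin)
  pre <- time < cfg$infusion_time
  expect_gt(mean(r[!pre]), mean(r[pre]))

  expect_error(simulate_metabolics(g[-1], no_run, cfg), "common grid")

  # positivity sweep over seeded noisy runs (short series for speed)
  cfg$metabolic$noise_frac <- 0.02
  ok <- withr::with_seed(99, {
    all(replicate(1000, {
      m <- simulate_metabolics(g[1:120], no_run[1:120], cfg)
      all(m$vo2_lmin > 0) && all(m$vco2_lmin > 0) && all(m$temp_C > 0)
    }))
  })
  expect_true(ok)
})

test_that("cell traces are built from their class waveforms", {
  cfg <- quick_config(seed = 2, n_cells = 1,
                      prevalences = c(G = 0, dG = 0, iG = 0, idG = 1,
                                      `N/A` = 0),
                      noise_sd = 0, cell_bleach_sd = 0)
  cfg$coupling_gains$running_mix <- c(positive = 0, negative = 0, none = 1)
  cfg$coupling_gains$slow_gain_sd <- 0
  time_m <- seq(0, cfg$duration - 1)
  g <- withr::with_seed(2, simulate_glucose(cfg$glucose, time_m, 1500))
  loco <- withr::with_seed(3, simulate_locomotion(cfg))
  cells <- withr::with_seed(4, simulate_cells(cfg, g, time_m, loco))
  expect_identical(cells$truth$class, "idG")
  # pure idG cell with no running/noise/bleach is proportional to -dG wave
  expect_equal(cor(cells$traces[, 1], -cells$waveforms$dG), 1,
               tolerance = 1e-12)
  expect_error(simulate_cells(quick_config(n_cells = 0), g, time_m, loco),
               "n_cells")
})

test_that("label prevalences are honoured at large n", {
  prev <- c(G = 0.245, dG = 0.108, iG = 0.323, idG = 0.304, `N/A` = 0.020)
  labels <- withr::with_seed(123, draw_cell_labels(10000, prev))
  frac <- table(factor(labels, levels = names(prev))) / 10000
  se <- sqrt(prev * (1 - prev) / 10000)
  expect_true(all(abs(as.numeric(frac) - prev) <= 3 * se))
  expect_error(draw_cell_labels(10, c(G = 0.5, dG = 0.4)), "sum to 1")
})

test_that("sessions are reproducible, internally consistent, and round-trip", {
  cfg <- quick_config(seed = 9)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a, b)

  # population activity is the z-scored mean of the cell traces
  ratio <- cfg$cell_rate / cfg$master_rate
  pop <- colMeans(matrix(rowMeans(a$cells), nrow = ratio))
  expect_equal(cor(pop, a$session$activity_z), 1, tolerance = 1e-12)

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_session(a$session, tmp)
  back <- read_session(tmp)
  expect_equal(as.data.frame(back), as.data.frame(a$session),
               tolerance = 1e-12)
  expect_equal(session_events(back)$time_s, cfg$infusion_time)
})

test_that("a session without a transient yields no dominant glucose-derivative encoding", {
  cfg <- quick_config(seed = 21, n_cells = 30)
  cfg$glucose$amplitude <- 0
  sim <- simulate_session(cfg)
  expect_lt(diff(range(sim$session$glucose_mM)), 1)
  pred <- build_predictors(sim$session)
  fit <- bootstrap_contributions(pred$X, pred$y, iterations = 100, seed = 4)
  dglu <- fit$contributions$contribution_pct[
    fit$contributions$predictor == "d_glucose"]
  expect_lt(dglu, 50)
})
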