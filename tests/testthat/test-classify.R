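test_that("templates obey their construction identities", {
  tp <- make_templates()$templates
  expect_equal(tp$waveforms$iG, -tp$waveforms$G)
  expect_equal(tp$waveforms$idG, -tp$waveforms$dG)
  expect_equal(max(tp$time_min), 20, tolerance = 0.01)

  # constant glucose: G constant (centred to zero), dG ~ 0
  flatg <- rep(7.3, 3600)
  tf <- build_templates(flatg, seq(0, 3599), 1500)
  expect_equal(var(tf$waveforms$G), 0)
  expect_lt(max(abs(tf$waveforms$dG)), 1e-9)

  # dG crosses zero near the glucose peak
  sim <- make_templates()$sim
  tp2 <- build_templates(sim$session$glucose_mM, sim$session$time_s, 1500)
  peak_min <- tp2$time_min[which.max(tp2$waveforms$G)]
  sign_change <- tp2$time_min[which(diff(sign(tp2$waveforms$dG)) < 0)[1]]
  # re-smoothing the asymmetric (fast-rise, slow-decay) derivative drags
  # its zero-crossing past the peak by a few minutes; keep it within 5 min
  expect_lt(abs(sign_change - peak_min), 5)

  expect_error(build_templates(flatg[1:1800], seq(0, 1799), 1500),
               "post-infusion")
})

test_that("template construction commutes with a time shift of the infusion", {
  fx <- make_templates()
  g <- fx$sim$session$glucose_mM
  t <- fx$sim$session$time_s
  shifted <- build_templates(g, t + 300, fx$infusion + 300)
  expect_equal(shifted$waveforms, fx$templates$waveforms, tolerance = 1e-12)
})

test_that("single cells classify by maximum template correlation", {
  fx <- make_templates()
  tgrid <- fx$infusion + fx$templates$time_min * 60
  idg <- fx$templates$waveforms$idG
  noisy <- withr::with_seed(1, idg + 0.05 * rnorm(length(idg)))
  cl <- classify_cell(noisy, tgrid, fx$templates, fx$infusion)
  expect_equal(cl$class, "idG")
  expect_gt(cl$r_idG, 0.99)
  expect_equal(cl$alpha_per_template, 0.001 / 4)

  # sign identity: -G is exactly iG
  cl2 <- classify_cell(-fx$templates$waveforms$G, tgrid, fx$templates,
                       fx$infusion)
  expect_equal(cl2$class, "iG")
  expect_equal(cl2$r_iG, 1, tolerance = 1e-12)

  # constant trace: no-response with flag
  cl3 <- classify_cell(rep(2, length(tgrid)), tgrid, fx$templates,
                       fx$infusion)
  expect_equal(cl3$class, "N/A")
  expect_true(cl3$degenerate)

  # affine rescaling leaves the class untouched
  cl4 <- classify_cell(5 * noisy - 3, tgrid, fx$templates, fx$infusion)
  expect_equal(cl4$class, "idG")
  expect_equal(cl4$r_idG, cl$r_idG, tolerance = 1e-12)
})

test_that("white-noise traces land in the no-response class", {
  fx <- make_templates()
  n <- 6120  # 20 min at 5.1 Hz
  tgrid <- seq(fx$infusion, fx$infusion + 1200, length.out = n)
  na_rate <- withr::with_seed(17, {
    mean(replicate(60, {
      classify_cell(rnorm(n), tgrid, fx$templates, fx$infusion)$class
    }) == "N/A")
  })
  expect_gte(na_rate, 0.9)
})

test_that("negating every trace maps the classes by the sign symmetry", {
  cfg <- quick_config(seed = 14, n_cells = 60, noise_sd = 0.5)
  sim <- simulate_session(cfg)
  fx <- make_templates()
  a <- classify_batch(sim$cells, sim$cell_time, fx$templates, fx$infusion)
  b <- classify_batch(-sim$cells, sim$cell_time, fx$templates, fx$infusion)
  map <- c(G = "iG", iG = "G", dG = "idG", idG = "dG", `N/A` = "N/A")
  expect_equal(unname(map[a$cells$class]), b$cells$class)
})

test_that("batch classification recovers generator prevalences and averages sessions", {
  cfg <- quick_config(seed = 19, n_cells = 300,
                      prevalences = c(G = 0.25, dG = 0.11, iG = 0.33,
                                      idG = 0.31, `N/A` = 0))
  cfg$coupling_gains$slow_gain_mean <- 5
  cfg$coupling_gains$slow_gain_sd <- 0
  sim <- simulate_session(cfg)
  fx <- make_templates()
  cls <- classify_batch(sim$cells, sim$cell_time, fx$templates, fx$infusion)
  got <- setNames(cls$prevalence$fraction, cls$prevalence$class)
  want <- c(G = 0.25, dG = 0.11, iG = 0.33, idG = 0.31)
  se <- sqrt(want * (1 - want) / 300)
  for (cl in names(want)) {
    expect_lt(abs(got[[cl]] - want[[cl]]), 3 * se[[cl]] + 1e-9)
  }

  # same cell in two same-condition sessions: averaged, one output row
  two <- list(sim$cells[, 1:5], sim$cells[, 1:5] +
                withr::with_seed(1, matrix(rnorm(length(sim$cells[, 1:5])),
                                           ncol = 5)))
  avg <- classify_batch(two, sim$cell_time, fx$templates, fx$infusion)
  expect_equal(nrow(avg$cells), 5)
  direct <- classify_batch((two[[1]] + two[[2]]) / 2, sim$cell_time,
                           fx$templates, fx$infusion)
  expect_equal(avg$cells$class, direct$cells$class)

  expect_error(classify_batch(matrix(numeric(0), nrow = 10, ncol = 0),
                              sim$cell_time, fx$templates, fx$infusion),
               "non-empty")
})

test_that("running correlation classes follow the Spearman thresholds", {
  withr::with_seed(23, {
    speed <- pmax(0, as.numeric(arima.sim(list(ar = 0.8), 3000)))
    pos <- classify_running(sqrt(speed + 1), speed)
    expect_equal(pos$running_class, "positive")
    expect_equal(pos$rho, 1, tolerance = 1e-9)

    neg <- classify_running(-speed, speed)
    expect_equal(neg$running_class, "negative")
    expect_equal(neg$rho, -1, tolerance = 1e-9)

    cst <- classify_running(rep(1, 3000), speed)
    expect_equal(cst$running_class, "none")
    expect_true(cst$degenerate)

    # independent white noise: uncorrelated in about 95% of runs
    none_rate <- mean(replicate(200, {
      classify_running(rnorm(500), rnorm(500))$running_class == "none"
    }))
    expect_gt(none_rate, 0.9)
  })
})

test_that("multiplexing cross-tab counts cells once with consistent fractions", {
  mt <- crosstab_multiplex(rep("idG", 10), rep("positive", 10))
  expect_equal(mt$multiplexed_fraction, 1)
  expect_equal(sum(mt$table$fraction), 1)
  expect_equal(sum(mt$table$n), 10)
  expect_equal(mt$table$n[mt$table$glucose_class == "idG" &
                            mt$table$running_class == "positive"], 10)

  gl <- c("G", "N/A", "iG", "idG", "dG", "G")
  rn <- c("positive", "positive", "none", "negative", "none", "positive")
  mt2 <- crosstab_multiplex(gl, rn)
  expect_equal(sum(mt2$table$fraction), 1)
  expect_equal(mt2$multiplexed_fraction, 3 / 6)
  expect_error(crosstab_multiplex(gl, rn[-1]), "same cells")
})

test_that("joint glucose x running labels are recovered from the generator", {
  cfg <- quick_config(seed = 27, n_cells = 250)
  cfg$coupling_gains$slow_gain_mean <- 5
  cfg$coupling_gains$slow_gain_sd <- 0
  sim <- simulate_session(cfg)
  fx <- make_templates()
  cls <- classify_batch(sim$cells, sim$cell_time, fx$templates, fx$infusion)
  # glucose labels recovered essentially exactly at high SNR; the joint
  # table is then driven by the running arm, checked against its truth
  acc <- mean(cls$cells$class == sim$truth$class)
  expect_gt(acc, 0.9)
  run <- purrr::map_dfr(seq_len(ncol(sim$cells)), function(j)
    classify_running(sim$cells[, j], sim$running_cells))
  truly_coupled <- sim$truth$running_class != "none"
  expect_gt(mean(run$running_class[truly_coupled] ==
                   sim$truth$running_class[truly_coupled]), 0.9)
})

test_that("population reconstruction is the prevalence-weighted template sum", {
  fx <- make_templates()
  one <- reconstruct_population(fx$templates, c(idG = 1))
  expect_equal(one$value, fx$templates$waveforms$idG)

  zero <- reconstruct_population(fx$templates, c(G = 0.5, idG = 0.5),
                                 amplitudes = c(G = 0, dG = 0, iG = 0,
                                                idG = 0))
  expect_equal(zero$value, rep(0, length(zero$value)))

  expect_error(reconstruct_population(fx$templates, c(G = -0.1, idG = 1.1)),
               "non-negative")

  # at the reported class prevalences the reconstruction looks like the
  # derivative-inhibited template
  rec <- reconstruct_population(fx$templates,
                                c(idG = 0.31, iG = 0.33, G = 0.25,
                                  dG = 0.11))
  expect_gt(cor(rec$value, fx$templates$waveforms$idG), 0.8)
})
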