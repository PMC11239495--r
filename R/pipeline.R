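#' Run the full analysis pipeline on a (simulated or loaded) session
#'
#' Orchestrates every stage end to end: simulate (or accept) a session;
#' detrend and normalise the raw photometry trace; run the temporal
#' analyses (lagged cross-correlation of activity and glucose, linear
#' fits against glucose and its derivative, transient detection,
#' hysteresis loops against glucose and its derivative, canonical epoch
#' means, locomotion bouts, energy expenditure and RER summaries); fit
#' the bootstrap encoding model; build glucose templates from a held-out
#' session and classify the single cells (glucose class, running class,
#' multiplexing cross-tab, population reconstruction from recovered
#' prevalences). Deterministic given the configuration seeds.
#'
#' @param config A [sim_config()] describing the session to simulate, or
#'   a `session_sim` from [simulate_session()] to analyse as-is.
#' @param encode_iterations Bootstrap iterations for the encoding model.
#' @param encode_seed Seed for the chunk bootstrap.
#' @param family_alpha Family-wise alpha for cell classification.
#' @param template_seed_offset Seed offset of the held-out session whose
#'   glucose builds the classification templates (holdout rule: templates
#'   never come from the session being classified).
#' @param out_dir Optional directory; when given, stage outputs are
#'   written there (session CSV + JSON sidecar, cell matrix CSV,
#'   per-cell classification CSV, contribution CSV, report JSON).
#' @return An `analysis_report` list with one element per stage and a
#'   `provenance` block.
#' @export
run_pipeline <- function(config = sim_config(), encode_iterations = 200L,
                         encode_seed = NULL, family_alpha = 0.001,
                         template_seed_offset = 1000L, out_dir = NULL) {
  sim <- if (inherits(config, "session_sim")) config else
    simulate_session(config)
  cfg <- sim$config
  session <- sim$session
  t_inf <- infusion_time_of(session)
  base_win <- c(t_inf - 20 * 60, t_inf)
  dt <- grid_dt(session$time_s)
  if (is.null(encode_seed)) encode_seed <- cfg$seed + 1L

  # --- preprocessing of the raw photometry channel ---
  pp <- preprocess_photometry(sim$raw_f, session$time_s, base_win)

  # --- temporal analyses on the session channels ---
  # derivative of the 1.5-min-smoothed glucose: differentiating the raw
  # telemetry trace would amplify sensor noise far above the mM/min
  # signal scale
  dglu <- finite_derivative(moving_mean(session$glucose_mM, 90, dt), dt)
  xc <- lag_crosscorr(session$glucose_mM, session$activity_z,
                      max_lag = 600, dt = dt)
  fit_glu <- linfit(session$glucose_mM, session$activity_z)
  fit_dglu <- linfit(dglu, session$activity_z)
  transient <- tryCatch(
    detect_transient(session$glucose_mM, session$time_s, base_win),
    error = function(e) NULL
  )
  hyst_g <- hyst_dg <- NULL
  if (!is.null(transient)) {
    bounds <- c(transient$t_start, transient$t_end)
    hyst_g <- hysteresis_loop(session$activity_z, session$glucose_mM,
                              session$time_s, bounds)
    hyst_dg <- hysteresis_loop(session$activity_z, dglu,
                               session$time_s, bounds)
  }
  epochs <- epoch_means(session$activity_z, session$time_s, t_inf)
  bouts <- detect_bouts(sim$running_cells, cfg$locomotion$threshold,
                        dt = 1 / cfg$cell_rate)
  ee <- weir_ee(session$vo2_lmin, session$vco2_lmin)
  rer_s <- rer(session$vo2_lmin, session$vco2_lmin)
  pre <- session$time_s < t_inf
  metabolic <- tibble(
    quantity = c("ee_kcal_min", "rer"),
    pre_mean = c(mean(ee[pre]), mean(rer_s[pre])),
    post_mean = c(mean(ee[!pre]), mean(rer_s[!pre]))
  )

  # --- encoding model ---
  pred <- build_predictors(session)
  enc <- bootstrap_contributions(pred$X, pred$y,
                                 iterations = encode_iterations,
                                 seed = encode_seed)

  # --- single-cell classification against held-out templates ---
  holdout_cfg <- cfg
  holdout_cfg$seed <- cfg$seed + as.integer(template_seed_offset)
  holdout_cfg$glucose$noise_sd <- 0
  holdout <- simulate_session(holdout_cfg)
  templates <- build_templates(holdout$session$glucose_mM,
                               holdout$session$time_s, t_inf)
  cls <- classify_batch(sim$cells, sim$cell_time, templates, t_inf,
                        family_alpha = family_alpha)
  run_cls <- purrr::map_dfr(seq_len(ncol(sim$cells)), function(j) {
    classify_running(sim$cells[, j], sim$running_cells)
  })
  run_cls <- dplyr::bind_cols(tibble(cell_id = colnames(sim$cells)), run_cls)
  mux <- crosstab_multiplex(cls$cells$class, run_cls$running_class)
  prev4 <- setNames(cls$prevalence$fraction, cls$prevalence$class)
  prev4 <- prev4[template_classes]
  recon <- reconstruct_population(templates, prev4)

  report <- structure(
    list(
      session = session,
      preprocessing = list(trace = pp, model = attr(pp, "model")),
      temporal = list(crosscorr = xc, fit_glucose = fit_glu,
                      fit_glucose_derivative = fit_dglu,
                      transient = transient, hysteresis_glucose = hyst_g,
                      hysteresis_derivative = hyst_dg, epochs = epochs,
                      bouts = bouts, metabolic = metabolic),
      encoding = enc,
      classification = list(templates = templates, glucose = cls,
                            running = run_cls, multiplex = mux,
                            reconstruction = recon),
      provenance = list(config = cfg, encode_iterations = encode_iterations,
                        encode_seed = encode_seed,
                        family_alpha = family_alpha,
                        template_seed = holdout_cfg$seed)
    ),
    class = "analysis_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(session, file.path(out_dir, "session.csv"))
    write_cells(sim$cells, sim$cell_time, file.path(out_dir, "cells.csv"))
    readr::write_csv(cls$cells, file.path(out_dir, "classification.csv"))
    readr::write_csv(enc$contributions, file.path(out_dir, "contributions.csv"))
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# Flat numeric summary of a report (also what run_pipeline writes as JSON).
report_summary <- function(report) {
  enc_top <- rank_contributions(report$encoding)
  list(
    peak_lag_s = report$temporal$crosscorr$peak_lag,
    peak_r = report$temporal$crosscorr$peak_r,
    r2_vs_glucose = report$temporal$fit_glucose$r_squared,
    r2_vs_glucose_derivative = report$temporal$fit_glucose_derivative$r_squared,
    slope_vs_glucose_derivative = report$temporal$fit_glucose_derivative$slope,
    epoch_means = setNames(as.list(report$temporal$epochs$mean),
                           report$temporal$epochs$epoch),
    hysteresis_area_glucose =
      if (is.null(report$temporal$hysteresis_glucose)) NULL else
        report$temporal$hysteresis_glucose$signed_area,
    bout_count = report$temporal$bouts$count,
    r2_full_median = median(report$encoding$r2_full),
    top_predictor = enc_top$predictor[1L],
    top_contribution_pct = enc_top$contribution_pct[1L],
    prevalences = setNames(as.list(report$classification$glucose$prevalence$fraction),
                           report$classification$glucose$prevalence$class),
    multiplexed_fraction = report$classification$multiplex$multiplexed_fraction,
    seed = report$provenance$config$seed
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- report_summary(x)
  cat("<analysis_report>\n")
  cat(sprintf("  cross-correlation peak: r = %.2f at lag %+.0f s\n",
              s$peak_r, s$peak_lag_s))
  cat(sprintf("  R^2 activity ~ glucose: %.3f; ~ d[glucose]/dt: %.3f\n",
              s$r2_vs_glucose, s$r2_vs_glucose_derivative))
  cat(sprintf("  top encoding predictor: %s (%.1f%% of explained variance)\n",
              s$top_predictor, s$top_contribution_pct))
  cat(sprintf("  cell classes: %s\n",
              paste(sprintf("%s %.0f%%", names(s$prevalences),
                            100 * unlist(s$prevalences)), collapse = ", ")))
  cat(sprintf("  multiplexed (glucose x running): %.0f%%\n",
              100 * s$multiplexed_fraction))
  invisible(x)
}
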