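#' Build glucose-derived classification templates
#'
#' From a reference blood-glucose trace (conventionally from sessions held
#' out of the classification): smooth with a 1.5-min-window moving mean
#' (G); differentiate the smoothed trace and re-smooth with the same
#' filter (dG); negate for the inverted templates (iG = -G,
#' idG = -dG); crop to the first 20 min after the infusion. Each
#' waveform is z-scored over the cropped window (a constant waveform
#' falls back to centred zeros), which leaves Pearson classification
#' untouched and puts the templates in the z-units used for population
#' reconstruction.
#'
#' @param glucose Glucose trace (mM).
#' @param time Sample times (seconds).
#' @param infusion_time Infusion onset (seconds).
#' @param window_min Post-infusion template span in minutes (default 20).
#' @param smooth_s Moving-mean window in seconds (default 90 = 1.5 min).
#' @return A `template_set`: `time_min` (minutes post-infusion) and a
#'   `waveforms` list `G`, `dG`, `iG`, `idG` on that grid.
#' @export
build_templates <- function(glucose, time, infusion_time, window_min = 20,
                            smooth_s = 90) {
  assert_same_length(glucose, time)
  dt <- grid_dt(time)
  if (time[length(time)] < infusion_time + window_min * 60) {
    abort(sprintf("trace must cover at least %g min post-infusion", window_min))
  }
  g_sm <- moving_mean(glucose, smooth_s, dt)
  dg <- moving_mean(finite_derivative(g_sm, dt), smooth_s, dt)
  keep <- time >= infusion_time & time <= infusion_time + window_min * 60
  G <- zscore_vec(g_sm[keep], centre_only = TRUE)
  dG <- zscore_vec(dg[keep], centre_only = TRUE)
  structure(
    list(
      time_min = (time[keep] - infusion_time) / 60,
      waveforms = list(G = G, dG = dG, iG = -G, idG = -dG),
      construction = list(smooth_s = smooth_s, window_min = window_min,
                          dt = dt)
    ),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> G/dG/iG/idG over %.0f min post-infusion (%d samples, %.0f-s smoothing)\n",
              max(x$time_min), length(x$time_min), x$construction$smooth_s))
  invisible(x)
}

template_classes <- c("G", "dG", "iG", "idG")

# Align a cell trace to the template grid by linear interpolation.
align_to_templates <- function(trace, time, templates, infusion_time) {
  target <- infusion_time + templates$time_min * 60
  if (time[1L] > target[1L] + 1e-9 ||
      time[length(time)] < target[length(target)] - 1e-9) {
    abort("trace does not cover the template window")
  }
  approx(time, trace, xout = target)$y
}

#' Classify one cell against the glucose templates
#'
#' Pearson correlation (with a two-sided t-approximation p-value) of the
#' cell's activity, aligned to the first 20 min post-infusion, against
#' each of the four glucose templates. The cell is assigned to the
#' template with the maximum correlation, unless no template reaches
#' `p < family_alpha / 4` (Bonferroni over the four comparisons), in
#' which case it falls into the `N/A` (no-response) class. Ties in r are
#' broken in the fixed order G, dG, iG, idG.
#'
#' @param trace Cell activity trace.
#' @param time Sample times (seconds) of the trace.
#' @param templates A `template_set`.
#' @param infusion_time Infusion onset (seconds) for this recording.
#' @param family_alpha Family-wise alpha (default 0.001); the
#'   per-template threshold is `family_alpha / 4`.
#' @return One-row tibble: `class`, `r_G`, `r_dG`, `r_iG`, `r_idG`,
#'   `p_G`, ..., `alpha_per_template`, `degenerate` (TRUE when the trace
#'   or a template was constant).
#' @export
classify_cell <- function(trace, time, templates, infusion_time,
                          family_alpha = 0.001) {
  aligned <- align_to_templates(trace, time, templates, infusion_time)
  alpha <- family_alpha / length(template_classes)
  degenerate <- sd(aligned) == 0
  rs <- ps <- setNames(rep(NA_real_, 4L), template_classes)
  if (!degenerate) {
    for (cls in template_classes) {
      w <- templates$waveforms[[cls]]
      if (sd(w) == 0) next
      ct <- suppressWarnings(cor.test(aligned, w))
      rs[cls] <- unname(ct$estimate)
      ps[cls] <- ct$p.value
    }
  }
  any_sig <- any(ps < alpha, na.rm = TRUE)
  cls <- if (!any_sig || all(is.na(rs))) {
    "N/A"
  } else {
    template_classes[which.max(replace(rs, is.na(rs), -Inf))]
  }
  tibble(
    class = cls,
    r_G = rs[["G"]], r_dG = rs[["dG"]], r_iG = rs[["iG"]], r_idG = rs[["idG"]],
    p_G = ps[["G"]], p_dG = ps[["dG"]], p_iG = ps[["iG"]], p_idG = ps[["idG"]],
    alpha_per_template = alpha,
    degenerate = degenerate || all(is.na(rs))
  )
}

#' Classify a population of cells and summarise class prevalences
#'
#' Applies [classify_cell()] to each column of a cell-trace matrix. When
#' the same cell appears in several same-condition sessions (`cells` is a
#' list of matrices sharing column names), the sessions are averaged per
#' cell before classification.
#'
#' @param cells Matrix (rows = samples, columns = cells), or a list of
#'   such matrices from repeated same-condition sessions.
#' @param time Sample times (seconds) of the rows.
#' @param templates A `template_set`.
#' @param infusion_time Infusion onset (seconds).
#' @param family_alpha Family-wise alpha (default 0.001).
#' @return A `cell_classification` object: `cells` tibble (one row per
#'   cell: `cell_id`, `class`, correlations, p-values) and `prevalence`
#'   tibble (`class`, `n`, `fraction` over G, dG, iG, idG, N/A).
#' @export
classify_batch <- function(cells, time, templates, infusion_time,
                           family_alpha = 0.001) {
  if (is.list(cells) && !is.matrix(cells)) {
    if (length(cells) == 0L) abort("no cell matrices supplied")
    ids <- colnames(cells[[1L]])
    if (any(!purrr::map_lgl(cells, ~ identical(colnames(.x), ids)))) {
      abort("all session matrices must share identical cell IDs")
    }
    cells <- Reduce(`+`, cells) / length(cells)
  }
  if (!is.matrix(cells) || ncol(cells) == 0L) {
    abort("cells must be a non-empty matrix")
  }
  ids <- colnames(cells) %||% sprintf("cell_%03d", seq_len(ncol(cells)))
  rows <- purrr::map_dfr(seq_len(ncol(cells)), function(j) {
    classify_cell(cells[, j], time, templates, infusion_time, family_alpha)
  })
  rows <- dplyr::bind_cols(tibble(cell_id = ids), rows)
  classes <- factor(rows$class, levels = c(template_classes, "N/A"))
  prevalence <- tibble(
    class = levels(classes),
    n = as.integer(table(classes)),
    fraction = as.numeric(table(classes)) / nrow(rows)
  )
  structure(list(cells = rows, prevalence = prevalence,
                 family_alpha = family_alpha),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  cat("<cell_classification>", nrow(x$cells), "cells\n")
  print(x$prevalence)
  invisible(x)
}

#' Classify a cell's correlation with running
#'
#' Spearman correlation of whole-session 5-Hz activity against running
#' speed. Cells are positively correlated when `p < 0.05` and
#' `rho > 0.01`, negatively correlated when `p < 0.05` and
#' `rho < -0.01`, and uncorrelated otherwise.
#'
#' @param trace Cell activity at 5 Hz, whole session.
#' @param speed Running speed (cm/s) on the same grid.
#' @param alpha Significance threshold (default 0.05).
#' @param rho_min Minimal absolute rho (default 0.01).
#' @return One-row tibble `rho`, `p`, `running_class`, `degenerate`.
#' @export
classify_running <- function(trace, speed, alpha = 0.05, rho_min = 0.01) {
  assert_same_length(trace, speed)
  if (sd(trace) == 0 || sd(speed) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, running_class = "none",
                  degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(trace, speed, method = "spearman",
                                  exact = FALSE))
  rho <- unname(ct$estimate)
  p <- ct$p.value
  cls <- if (p < alpha && rho > rho_min) {
    "positive"
  } else if (p < alpha && rho < -rho_min) {
    "negative"
  } else {
    "none"
  }
  tibble(rho = rho, p = p, running_class = cls, degenerate = FALSE)
}

#' Cross-tabulate glucose classes against running classes
#'
#' The multiplexing table: counts and fractions over the 5 glucose
#' classes by 3 running classes, with the multiplexed fraction (cells
#' carrying both signals: non-`N/A` glucose class and non-`none` running
#' class).
#'
#' @param glucose_classes Character vector of glucose classes per cell.
#' @param running_classes Character vector of running classes per cell
#'   (same cells, same order).
#' @return A `multiplex_table`: `table` tibble (`glucose_class`,
#'   `running_class`, `n`, `fraction`), `multiplexed_fraction`, `n_cells`.
#' @export
crosstab_multiplex <- function(glucose_classes, running_classes) {
  n <- length(glucose_classes)
  if (n != length(running_classes)) {
    abort("glucose and running classifications must cover the same cells")
  }
  g <- factor(glucose_classes, levels = c(template_classes, "N/A"))
  r <- factor(running_classes, levels = c("positive", "negative", "none"))
  if (anyNA(g) || anyNA(r)) abort("unknown class label encountered")
  tab <- as.data.frame(table(glucose_class = g, running_class = r))
  tab <- as_tibble(tab)
  names(tab)[3L] <- "n"
  tab$fraction <- tab$n / n
  multiplexed <- mean(g != "N/A" & r != "none")
  structure(list(table = tab, multiplexed_fraction = multiplexed,
                 n_cells = n),
            class = "multiplex_table")
}

#' @export
print.multiplex_table <- function(x, ...) {
  cat(sprintf("<multiplex_table> %d cells; multiplexed fraction %.2f\n",
              x$n_cells, x$multiplexed_fraction))
  print(tidyr::pivot_wider(x$table[, 1:3],
                           names_from = "running_class", values_from = "n"))
  invisible(x)
}

#' Reconstruct the population response from class prevalences
#'
#' The prevalence-weighted sum of the (z-scored) glucose templates:
#' `sum_c prevalence_c * amplitude_c * waveform_c` on the template grid.
#' Recreates the population response from single-cell class composition.
#'
#' @param templates A `template_set`.
#' @param prevalences Named non-negative fractions over `G, dG, iG, idG`.
#' @param amplitudes Named per-class response amplitudes in z-units
#'   (default all 1).
#' @return Tibble `time_min`, `value` with attribute `"weights"`.
#' @export
reconstruct_population <- function(templates, prevalences,
                                   amplitudes = setNames(rep(1, 4),
                                                         template_classes)) {
  if (any(prevalences < 0)) abort("prevalences must be non-negative")
  cls <- intersect(template_classes, names(prevalences))
  if (length(cls) == 0L) abort("prevalences must name at least one class")
  value <- numeric(length(templates$time_min))
  for (cc in cls) {
    amp <- amplitudes[[cc]] %||% 1
    value <- value + prevalences[[cc]] * amp * templates$waveforms[[cc]]
  }
  out <- tibble(time_min = templates$time_min, value = value)
  attr(out, "weights") <- purrr::map_dbl(setNames(cls, cls), function(cc) {
    prevalences[[cc]] * (amplitudes[[cc]] %||% 1)
  })
  out
}
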