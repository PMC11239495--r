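#' Build the encoding-model design matrix from a session
#'
#' Conditions all predictors to a common slow timescale: each channel
#' (running, glucose, temperature, VO2, VCO2) and the activity response
#' are downsampled to 1-min bins (bin means), Savitzky-Golay filtered
#' (first-order, five-sample window), then the five time-derivative
#' columns are computed from the filtered signals, and every column and
#' the response are z-scored. Column order is fixed:
#' `running, glucose, temperature, vo2, vco2, d_running, d_glucose,
#' d_temperature, d_vo2, d_vco2`.
#'
#' @param session A `session_record` (at least 20 min long).
#' @param bin Bin width in seconds (default 60).
#' @return List: `X` (matrix, 10 z-scored columns), `y` (z-scored
#'   activity), `time_s` (bin centres), `collinearity` (predictor
#'   correlation matrix).
#' @export
build_predictors <- function(session, bin = 60) {
  validate_session(session)
  dt <- grid_dt(session$time_s)
  per <- round(bin / dt)
  n_bins <- floor(nrow(session) / per)
  if (n_bins * bin < 20 * 60) abort("session must be at least 20 min long")
  binned <- function(x) {
    colMeans(matrix(x[seq_len(n_bins * per)], nrow = per))
  }
  chans <- c(running = "running_cms", glucose = "glucose_mM",
             temperature = "temp_C", vo2 = "vo2_lmin", vco2 = "vco2_lmin")
  filtered <- purrr::imap(chans, function(col, nm) {
    v <- savgol(binned(session[[col]]), order = 1L, window = 5L)
    if (near_constant(v)) abort(sprintf("predictor column '%s' is constant", nm))
    v
  })
  derivs <- purrr::map(filtered, finite_derivative, dt = bin)
  cols <- c(filtered, setNames(derivs, paste0("d_", names(derivs))))
  bad <- names(cols)[vapply(cols, near_constant, logical(1))]
  if (length(bad) > 0L) {
    abort(paste0("predictor column(s) constant: ", paste(bad, collapse = ", ")))
  }
  X <- vapply(cols, zscore_vec, numeric(n_bins))
  y_raw <- savgol(binned(session$activity_z), order = 1L, window = 5L)
  if (near_constant(y_raw)) abort("response (activity) is constant")
  list(
    X = X,
    y = zscore_vec(y_raw),
    time_s = (seq_len(n_bins) - 0.5) * bin + session$time_s[1L],
    collinearity = cor(X)
  )
}

#' Ordinary least squares with intercept on a row subset
#'
#' The Gaussian identity-link fit at the core of the encoding model.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param rows Row indices to fit on (default all).
#' @return Named coefficient vector (`(Intercept)` first).
#' @export
fit_linear <- function(X, y, rows = seq_along(y)) {
  if (length(rows) < ncol(X) + 2L) {
    abort("need at least ncol(X) + 2 rows to fit")
  }
  A <- cbind(`(Intercept)` = 1, X[rows, , drop = FALSE])
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) abort("design matrix is rank deficient")
  fit <- qr.coef(qr_A, y[rows])
  setNames(as.numeric(fit), colnames(A))
}

#' Coefficient of determination on held-out data
#'
#' `1 - SS_res / SS_tot`. On validation data this can be negative (the
#' model predicts worse than the validation mean); it is reported as-is,
#' and clipping happens only at the contribution stage.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return R-squared (unclipped).
#' @export
r_squared <- function(y, yhat) {
  n <- assert_same_length(y, yhat)
  if (n < 2L) abort("r_squared() needs at least 2 values")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("response has zero variance")
  1 - sum((y - yhat)^2) / sst
}

# Random-phase tiling of 1..n into contiguous chunks of ~chunk_len rows.
chunk_indices <- function(n, chunk_len, phase) {
  edges <- unique(c(0L, seq(phase, n, by = chunk_len), n))
  edges <- edges[edges >= 0L & edges <= n]
  purrr::map2(edges[-length(edges)] + 1L, edges[-1L], seq)
}

#' Bootstrap leave-one-predictor-out relative contributions
#'
#' The encoding model's core procedure. Per iteration, the rows are tiled
#' into contiguous chunks of `chunk_fraction` of the experiment duration
#' (random phase, preserving temporal autocorrelation within folds);
#' chunks are randomly assigned to training (until at least
#' `train_fraction` of samples) and validation. The full model and one
#' partial model per left-out predictor are fit on the training rows;
#' each predictor's `delta R^2 = R^2_full - R^2_partial` is evaluated on
#' the validation rows and clipped at zero. Deltas are aggregated across
#' iterations by their median (means also reported) and normalized to
#' percent of the summed clipped deltas. If every median delta is zero
#' the contributions are reported as all zero with `all_zero = TRUE`
#' (no division).
#'
#' In `"leave_one_session_out"` mode each level of `sessions` is held out
#' once as the validation set (no bootstrap), confirming the
#' chunk-bootstrap ranking without resampling.
#'
#' @param X Predictor matrix (z-scored columns), e.g. from
#'   [build_predictors()].
#' @param y Response vector.
#' @param iterations Bootstrap iterations (default 2000).
#' @param chunk_fraction Chunk length as a fraction of the experiment
#'   duration (default 1/4).
#' @param train_fraction Fraction of samples assigned to training
#'   (default 0.7).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param mode `"chunk_bootstrap"` or `"leave_one_session_out"`.
#' @param sessions Factor of session labels per row (required for
#'   leave-one-session-out).
#' @return An `encoding_fit` object; see [tidy.encoding_fit()].
#' @export
bootstrap_contributions <- function(X, y, iterations = 2000L,
                                    chunk_fraction = 0.25,
                                    train_fraction = 0.7, seed = 1L,
                                    mode = c("chunk_bootstrap",
                                             "leave_one_session_out"),
                                    sessions = NULL) {
  mode <- match.arg(mode)
  n <- assert_same_length(y, X[, 1L])
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }

  eval_split <- function(train, val) {
    full <- fit_linear(X, y, train)
    yhat <- drop(cbind(1, X[val, , drop = FALSE]) %*% full)
    r2f <- r_squared(y[val], yhat)
    deltas <- vapply(seq_len(p), function(j) {
      cj <- fit_linear(X[, -j, drop = FALSE], y, train)
      yhj <- drop(cbind(1, X[val, -j, drop = FALSE]) %*% cj)
      max(r2f - r_squared(y[val], yhj), 0)
    }, numeric(1))
    list(r2 = r2f, deltas = deltas, coefs = full)
  }

  if (mode == "chunk_bootstrap") {
    chunk_len <- max(2L, round(n * chunk_fraction))
    n_chunks <- ceiling(n / chunk_len)
    if (n_chunks < 2L) abort("chunk_fraction leaves fewer than 2 chunks")
    results <- withr::with_seed(seed, {
      purrr::map(seq_len(iterations), function(i) {
        phase <- sample.int(chunk_len, 1L)
        chunks <- chunk_indices(n, chunk_len, phase %% chunk_len)
        ord <- sample(length(chunks))
        sizes <- cumsum(lengths(chunks)[ord])
        n_train <- max(1L, which(sizes >= train_fraction * n)[1L])
        if (n_train >= length(chunks)) n_train <- length(chunks) - 1L
        train <- unlist(chunks[ord[seq_len(n_train)]])
        val <- unlist(chunks[ord[-seq_len(n_train)]])
        eval_split(train, val)
      })
    })
  } else {
    if (is.null(sessions)) {
      abort("leave_one_session_out mode needs a `sessions` vector")
    }
    levs <- unique(sessions)
    if (length(levs) < 2L) abort("need at least 2 sessions to leave one out")
    results <- purrr::map(levs, function(s) {
      eval_split(which(sessions != s), which(sessions == s))
    })
    iterations <- length(levs)
  }

  delta_mat <- do.call(rbind, purrr::map(results, "deltas"))
  colnames(delta_mat) <- colnames(X)
  r2_full <- purrr::map_dbl(results, "r2")
  coef_mat <- do.call(rbind, purrr::map(results, "coefs"))

  med <- apply(delta_mat, 2L, median)
  mn <- colMeans(delta_mat)
  total <- sum(med)
  all_zero <- total <= 0
  pct <- if (all_zero) rep(0, p) else 100 * med / total

  structure(
    list(
      contributions = tibble(
        predictor = colnames(X),
        delta_r2_median = unname(med),
        delta_r2_mean = unname(mn),
        contribution_pct = unname(pct)
      ),
      r2_full = r2_full,
      delta_r2 = delta_mat,
      coefficients = coef_mat,
      collinearity = cor(X),
      all_zero = all_zero,
      spec = list(mode = mode, iterations = iterations,
                  chunk_fraction = chunk_fraction,
                  train_fraction = train_fraction, seed = seed, n = n)
    ),
    class = "encoding_fit"
  )
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> %s, %d iterations, n = %d; median full R^2 = %.3f%s\n",
              x$spec$mode, x$spec$iterations, x$spec$n, median(x$r2_full),
              if (x$all_zero) " [all contributions zero]" else ""))
  top <- rank_contributions(x)
  print(utils::head(top, 5L))
  invisible(x)
}

#' Rank predictors by relative contribution
#'
#' Descending order of relative contribution; ties broken alphabetically
#' by predictor name for determinism.
#'
#' @param fit An `encoding_fit`.
#' @return The contributions tibble, ordered, with a `rank` column.
#' @export
rank_contributions <- function(fit) {
  stopifnot(inherits(fit, "encoding_fit"))
  out <- dplyr::arrange(fit$contributions,
                        dplyr::desc(.data$contribution_pct),
                        .data$predictor)
  out$rank <- seq_len(nrow(out))
  out
}
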