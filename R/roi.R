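#' Construct an ROI mask
#'
#' A region of interest on the (2x2-binned) imaging frame: a set of pixel
#' coordinates with its session and plane provenance, optionally carrying
#' the ROI's activity trace for correlation-based matching.
#'
#' @param roi_id Identifier.
#' @param session_id Recording-session identifier.
#' @param plane 0-based imaging-plane index.
#' @param pixels Two-column matrix (row, col) of 1-based integer pixel
#'   coordinates.
#' @param dim Frame dimensions (default `c(256, 256)`).
#' @param trace Optional activity trace (numeric).
#' @param rate Trace sampling rate in Hz (default 5.1, the volumetric
#'   imaging rate).
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(roi_id, session_id, plane, pixels, dim = c(256L, 256L),
                     trace = NULL, rate = 5.1) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) abort("ROI mask must be non-empty")
  if (ncol(pixels) != 2L) abort("pixels must be a two-column (row, col) matrix")
  if (any(pixels < 1L) || any(pixels[, 1L] > dim[1L]) ||
      any(pixels[, 2L] > dim[2L])) {
    abort("pixel coordinates outside frame bounds")
  }
  pixels <- unique(pixels)
  structure(list(roi_id = roi_id, session_id = session_id,
                 plane = as.integer(plane), pixels = pixels, dim = dim,
                 trace = trace, rate = rate),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s (session %s, plane %d): %d px on %dx%d frame\n",
              x$roi_id, x$session_id, x$plane, nrow(x$pixels),
              x$dim[1L], x$dim[2L]))
  invisible(x)
}

# Disk offsets of Euclidean radius r (29 pixels at r = 3).
disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE])
}

#' Dilate an ROI mask by a disk
#'
#' Morphological dilation by a Euclidean disk (radius 3 by default, the
#' conventional contour expansion before overlap testing), clipped at the
#' frame edges.
#'
#' @param mask An `roi_mask`.
#' @param radius Dilation radius in pixels (default 3).
#' @return The dilated `roi_mask`.
#' @export
dilate_mask <- function(mask, radius = 3L) {
  stopifnot(inherits(mask, "roi_mask"))
  off <- disk_offsets(radius)
  pts <- unique(cbind(
    rep(mask$pixels[, 1L], each = nrow(off)) + off[, 1L],
    rep(mask$pixels[, 2L], each = nrow(off)) + off[, 2L]
  ))
  keep <- pts[, 1L] >= 1L & pts[, 1L] <= mask$dim[1L] &
    pts[, 2L] >= 1L & pts[, 2L] <= mask$dim[2L]
  out <- mask
  out$pixels <- pts[keep, , drop = FALSE]
  out
}

pixel_keys <- function(mask) {
  (mask$pixels[, 1L] - 1L) * mask$dim[2L] + mask$pixels[, 2L]
}

#' Overlap fraction of two (dilated) ROI masks
#'
#' `|A intersect B| / min(|A|, |B|)` on the supplied masks (dilate first
#' with [dilate_mask()] for the conventional expanded-contour test).
#' `denominator = "union"` gives Jaccard-style normalisation instead.
#'
#' @param a,b `roi_mask` objects on the same frame grid.
#' @param denominator `"min"` (default) or `"union"`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  if (!identical(a$dim, b$dim)) abort("masks must share the frame grid")
  ka <- pixel_keys(a)
  kb <- pixel_keys(b)
  inter <- length(intersect(ka, kb))
  den <- switch(denominator,
                min = min(length(ka), length(kb)),
                union = length(union(ka, kb)))
  inter / den
}

#' Best-lag Pearson correlation between two ROI traces
#'
#' Maximum Pearson correlation over integer-sample lags with
#' `|lag| < max_lag` seconds, and the lag attaining it (positive lag:
#' second trace delayed).
#'
#' @param trace_a,trace_b Equal-length traces.
#' @param rate Sampling rate in Hz (default 5.1).
#' @param max_lag Lag bound in seconds, exclusive (default 2).
#' @return List `r`, `lag_s`.
#' @export
best_lag_correlation <- function(trace_a, trace_b, rate = 5.1, max_lag = 2) {
  n <- assert_same_length(trace_a, trace_b)
  if (sd(trace_a) == 0 || sd(trace_b) == 0) {
    abort("constant trace: correlation undefined")
  }
  kmax <- ceiling(max_lag * rate) - 1L
  ks <- seq(-kmax, kmax)
  rs <- vapply(ks, function(k) {
    if (k >= 0) {
      a <- trace_a[seq_len(n - k)]
      b <- trace_b[seq_len(n - k) + k]
    } else {
      a <- trace_a[seq_len(n + k) - k]
      b <- trace_b[seq_len(n + k)]
    }
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, numeric(1))
  i <- which.max(rs)
  list(r = rs[i], lag_s = ks[i] / rate)
}

#' Decide whether two ROIs are the same cell
#'
#' Applies the five joining criteria: plane distance at most 1
#' (neighbouring planes), more than 5% overlap of the radius-3 dilated
#' masks, best-lag trace correlation above 0.90 at a lag under 2 s, and
#' support from at least 2 independent sessions. All evidence is
#' recorded whether or not the ROIs are joined.
#'
#' @param a,b `roi_mask` objects carrying traces.
#' @param sessions_supporting Number of independent sessions in which
#'   this pairing was observed.
#' @param overlap_min Overlap threshold (default 0.05, exclusive).
#' @param r_min Correlation threshold (default 0.90, exclusive).
#' @param max_lag Lag bound in seconds (default 2, exclusive).
#' @param min_sessions Minimum supporting sessions (default 2).
#' @param dilate_radius Contour expansion in pixels (default 3).
#' @return One-row tibble: `roi_a`, `roi_b`, `plane_distance`,
#'   `overlap_fraction`, `trace_r`, `best_lag_s`, `sessions_supporting`,
#'   `joined`.
#' @export
decide_join <- function(a, b, sessions_supporting,
                        overlap_min = 0.05, r_min = 0.90, max_lag = 2,
                        min_sessions = 2L, dilate_radius = 3L) {
  stopifnot(inherits(a, "roi_mask"), inherits(b, "roi_mask"))
  plane_dist <- abs(a$plane - b$plane)
  ov <- overlap_fraction(dilate_mask(a, dilate_radius),
                         dilate_mask(b, dilate_radius))
  lag <- best_lag_correlation(a$trace, b$trace, rate = a$rate,
                              max_lag = max_lag)
  joined <- plane_dist <= 1L && ov > overlap_min && lag$r > r_min &&
    abs(lag$lag_s) < max_lag && sessions_supporting >= min_sessions
  tibble(
    roi_a = a$roi_id, roi_b = b$roi_id,
    plane_distance = plane_dist,
    overlap_fraction = ov,
    trace_r = lag$r,
    best_lag_s = lag$lag_s,
    sessions_supporting = as.integer(sessions_supporting),
    joined = joined
  )
}

#' Merge joined ROIs into cell groups by connected components
#'
#' Treats joined pairs as edges of an undirected graph over all ROIs
#' mentioned in the decision table and returns its connected components:
#' each component is one putative cell. When traces are supplied, the
#' merged cell trace is the mean of the member traces.
#'
#' @param decisions Tibble of [decide_join()] rows (columns `roi_a`,
#'   `roi_b`, `joined`).
#' @param traces Optional named list of member traces.
#' @return List: `groups` tibble (`roi_id`, `cell_group`), `n_groups`,
#'   and `merged_traces` (named list, present when `traces` given).
#' @export
merge_components <- function(decisions, traces = NULL) {
  ids <- sort(unique(c(decisions$roi_a, decisions$roi_b)))
  g <- igraph::graph_from_data_frame(
    decisions[decisions$joined, c("roi_a", "roi_b")],
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[ids]
  groups <- tibble(roi_id = ids,
                   cell_group = sprintf("group_%03d", unname(membership)))
  merged <- NULL
  if (!is.null(traces)) {
    merged <- purrr::map(split(ids, groups$cell_group), function(members) {
      rowMeans(do.call(cbind, traces[members]))
    })
  }
  list(groups = groups, n_groups = comp$no, merged_traces = merged)
}
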