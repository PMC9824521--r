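# Heart-rate to R-R interval conversion and Lorenz (Poincare) plot summaries.
#
# Wrist devices report beats-per-minute at a coarse cadence (nominally one
# sample every 15 s) rather than individual beats, so each heart-rate sample
# is converted to one representative R-R interval: rri_ms = 60000 / bpm.
# Consecutive RRI pairs (RRI(t), RRI(t+1)) form the Lorenz plot; the spread
# of their projections onto the y = x and y = -x axes gives the ellipse whose
# area summarises short-term heart-rate variability.

#' Convert heart rate to R-R interval
#'
#' One heart-rate sample in beats per minute maps to the R-R interval (in
#' milliseconds) of a perfectly regular heart beating at that rate:
#' `rri_ms = 60 / bpm * 1000`.
#'
#' @param bpm Numeric vector of heart rates in beats per minute; all values
#'   must be finite and positive.
#' @return Numeric vector of R-R intervals in milliseconds.
#' @examples
#' hr_to_rri(60)   # 1000 ms
#' hr_to_rri(120)  # 500 ms
#' @export
hr_to_rri <- function(bpm) {
  if (!is.numeric(bpm)) stopf("bpm must be numeric")
  if (length(bpm) && (any(!is.finite(bpm)) || any(bpm <= 0)))
    stopf("bpm must be finite and > 0 (offending values at indices: %s)",
          paste(utils::head(which(!is.finite(bpm) | bpm <= 0), 5L), collapse = ", "))
  60 / bpm * 1000
}

#' Convert a timestamped heart-rate series to an RRI series
#'
#' @param samples Data frame with columns `timestamp` and `bpm`; timestamps
#'   must be strictly increasing.
#' @return Data frame with columns `timestamp` and `rri_ms`, same row order.
#' @export
series_to_rri <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!all(c("timestamp", "bpm") %in% names(samples)))
    stopf("samples must have columns 'timestamp' and 'bpm'")
  ts <- as_instant(samples$timestamp)
  if (nrow(samples) > 1L) {
    bad <- which(diff(as.numeric(ts)) <= 0)
    if (length(bad))
      stopf("timestamps not strictly increasing at indices: %s",
            paste(utils::head(bad + 1L, 10L), collapse = ", "))
  }
  data.frame(timestamp = ts, rri_ms = hr_to_rri(samples$bpm))
}

#' Build Lorenz-plot pairs from consecutive RRI samples
#'
#' Pairs `(RRI(t), RRI(t+1))` are formed only between consecutive samples
#' whose timestamps differ by at most `max_gap` seconds, so pairs never
#' bridge sensor dropouts (or, when called per activity segment, interval
#' boundaries). The default gap is twice the nominal 15 s device cadence.
#'
#' @param rri Data frame with columns `timestamp` and `rri_ms`, sorted by
#'   time, or a numeric vector of RRI values (then assumed contiguous).
#' @param max_gap Maximum allowed spacing in seconds between the two samples
#'   of a pair.
#' @return Two-column matrix with columns `a` (= RRI(t)) and `b` (= RRI(t+1));
#'   zero rows when fewer than two eligible samples exist.
#' @export
build_pairs <- function(rri, max_gap = 30) {
  if (is.numeric(rri) && is.null(dim(rri))) {
    v <- as.numeric(rri)
    n <- length(v)
    if (n < 2L) return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
    return(cbind(a = v[-n], b = v[-1L]))
  }
  stopifnot(is.data.frame(rri), all(c("timestamp", "rri_ms") %in% names(rri)))
  n <- nrow(rri)
  if (n < 2L) return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  t <- as.numeric(as_instant(rri$timestamp))
  ok <- diff(t) <= max_gap
  v <- as.numeric(rri$rri_ms)
  cbind(a = v[-n][ok], b = v[-1L][ok])
}

#' Lorenz-plot ellipse statistics of a set of RRI pairs
#'
#' Each pair `(a, b)` is projected onto the identity axis, `u = (a + b)/sqrt(2)`,
#' and the anti-identity axis, `v = (a - b)/sqrt(2)`. The statistics are
#' `m = mean(u)` (mean signed distance from the origin along y = x),
#' `delta_x = sd(u)`, `delta_neg_x = sd(v)` and the ellipse area
#' `S = pi * delta_x * delta_neg_x`. Standard deviations use the population
#' divisor (n) for consistency with classical Poincare SD1/SD2 moment
#' definitions, and are taken about the projections' own means so that a
#' constant series has zero area.
#'
#' @param pairs Matrix or data frame with two columns (RRI(t), RRI(t+1)) in ms.
#' @return An object of class `lorenz_stats`: list with `n_pairs`, `m`,
#'   `delta_x`, `delta_neg_x`, `area` and logical `defined`. With fewer than
#'   two pairs the numeric fields are `NA` and `defined` is `FALSE`.
#' @export
lorenz_stats <- function(pairs) {
  p <- as.matrix(pairs)
  if (length(p) && ncol(p) != 2L) stopf("pairs must have two columns")
  n <- nrow(p) %||% 0L
  if (is.null(n) || n < 2L) {
    out <- list(n_pairs = if (is.null(n)) 0L else n,
                m = NA_real_, delta_x = NA_real_, delta_neg_x = NA_real_,
                area = NA_real_, defined = FALSE)
    class(out) <- "lorenz_stats"
    return(out)
  }
  u <- (p[, 1L] + p[, 2L]) / sqrt(2)
  v <- (p[, 1L] - p[, 2L]) / sqrt(2)
  dx <- pop_sd(u)
  dnx <- pop_sd(v)
  out <- list(n_pairs = n, m = mean(u), delta_x = dx, delta_neg_x = dnx,
              area = pi * dx * dnx, defined = TRUE)
  class(out) <- "lorenz_stats"
  out
}

#' @export
print.lorenz_stats <- function(x, ...) {
  if (!x$defined) {
    cat("Lorenz plot statistics: insufficient data (", x$n_pairs, " pair(s))\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("Lorenz plot statistics (%d pairs)\n",
                     "  m (mean along y=x): %.2f ms\n",
                     "  delta_x:            %.2f ms\n",
                     "  delta_(-x):         %.2f ms\n",
                     "  ellipse area:       %.2f ms^2\n"),
              x$n_pairs, x$m, x$delta_x, x$delta_neg_x, x$area))
  invisible(x)
}

#' Lorenz-plot ellipse area
#'
#' Convenience wrapper around [lorenz_stats()] returning just the area, or
#' `NA` when fewer than two pairs are available.
#' @inheritParams lorenz_stats
#' @return Ellipse area in ms^2, or `NA_real_`.
#' @export
lorenz_area <- function(pairs) {
  s <- lorenz_stats(pairs)
  if (s$defined) s$area else NA_real_
}

#' Population variance of an RRI series
#'
#' @param rri Numeric vector of RRI values in ms, or a data frame with an
#'   `rri_ms` column.
#' @return Population variance in ms^2, or `NA_real_` with fewer than two
#'   samples.
#' @export
rri_variance <- function(rri) {
  v <- if (is.data.frame(rri)) as.numeric(rri$rri_ms) else as.numeric(rri)
  if (length(v) < 2L) return(NA_real_)
  pop_var(v)
}

#' Mean of an RRI series
#'
#' @inheritParams rri_variance
#' @return Mean RRI in ms, or `NA_real_` for an empty series.
#' @export
mean_rri <- function(rri) {
  v <- if (is.data.frame(rri)) as.numeric(rri$rri_ms) else as.numeric(rri)
  if (!length(v)) return(NA_real_)
  mean(v)
}
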