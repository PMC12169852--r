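# Temporal spectral decomposition: windowed z-scoring of harmonic
# coefficient time series, Ricker (Mexican-hat) continuous wavelet
# transform, and time-scale event extraction from the scalograms.

#' Z-score a time series over an analysis window
#'
#' Restricts `ts` to the window and normalizes by the window mean and
#' (population) standard deviation. Affine-invariant for positive scale.
#'
#' @param ts Numeric series.
#' @param times Sample times (defaults to the sample index).
#' @param window Length-2 numeric `[t_start, t_end]`, or `NULL` for the
#'   full series.
#' @return List with `values` (mean 0, sd 1), `times`, `indices` (into the
#'   input series).
#' @export
normalize_series <- function(ts, times = NULL, window = NULL) {
  times <- times %||% seq_along(ts)
  stopifnot(length(times) == length(ts))
  idx <- if (is.null(window)) seq_along(ts) else {
    stopifnot(length(window) == 2, window[1] < window[2])
    which(times >= window[1] & times <= window[2])
  }
  if (length(idx) < 3L) stopf("window must contain at least 3 samples")
  x <- ts[idx]
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))  # population sd
  if (s == 0) stopf("zero variance in window: degenerate series")
  list(values = (x - mu) / s, times = times[idx], indices = idx)
}

#' Ricker (Mexican-hat) wavelet
#'
#' `psi_s(x) = 2 / (sqrt(3 s) pi^(1/4)) (1 - (x/s)^2) exp(-x^2 / (2 s^2))`,
#' the negative-normalized second derivative of a Gaussian, unit L2 norm in
#' continuous time.
#'
#' @param x Evaluation points (same units as `scale`).
#' @param scale Wavelet width `s > 0`.
#' @export
ricker_wavelet <- function(x, scale) {
  stopifnot(scale > 0)
  a <- 2 / (sqrt(3 * scale) * pi^0.25)
  a * (1 - (x / scale)^2) * exp(-x^2 / (2 * scale^2))
}

#' Default geometric scale grid
#' @param n Number of time samples.
#' @param n_scales Number of scales (default 32).
#' @return Scales in frame units from 1 to `n/4`, geometrically spaced.
#' @export
default_scales <- function(n, n_scales = 32L) {
  smax <- max(n / 4, 2)
  exp(seq(log(1), log(smax), length.out = n_scales))
}

#' Ricker continuous wavelet transform (scalogram)
#'
#' `C(s, t) = sum_tau x(tau) psi_s(tau - t)` with zero padding outside the
#' window; linear in `x`. Scales and shifts are in frame units.
#'
#' @param x Z-scored series (see [normalize_series()]), or a list as
#'   returned by it.
#' @param scales Wavelet widths in frames; default [default_scales()].
#' @param times Sample times (hours); must be uniformly spaced.
#' @param series_id Optional label, e.g. `c(l = 0, m = 0)`.
#' @return Object of class `scalogram`: `scales`, `times`, `C` (matrix
#'   `[scale, time]`), `coi` (logical matrix marking the cone of influence
#'   where zero padding contaminates coefficients), `series_id`.
#' @export
ricker_cwt <- function(x, scales = NULL, times = NULL, series_id = NULL) {
  if (is.list(x)) {
    times <- times %||% x$times
    x <- x$values
  }
  n <- length(x)
  times <- times %||% seq_len(n)
  stopifnot(length(times) == n)
  if (n >= 3) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-8 * mean(dt))
      stopf("non-uniform sampling: resample before the wavelet transform")
  }
  scales <- scales %||% default_scales(n)
  stopifnot(all(scales > 0))
  idx <- seq_len(n)
  lag <- outer(idx, idx, "-")  # tau - t
  C <- matrix(NA_real_, length(scales), n)
  coi <- matrix(FALSE, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    C[si, ] <- as.vector(x %*% ricker_wavelet(lag, s))
    r <- sqrt(2) * s  # e-folding support of the Gaussian envelope
    coi[si, ] <- (idx - 1) < r | (n - idx) < r
  }
  structure(list(scales = scales, times = times, C = C, coi = coi,
                 series_id = series_id),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales x %d samples, |C| max %.3g\n",
              length(x$scales), length(x$times), max(abs(x$C))))
  invisible(x)
}

#' Extract dominant time-scale events from a scalogram
#'
#' Local maxima of `|C|` on the scale x time grid (8-neighborhood), with
#' non-maximum suppression: events closer than `min_separation` frames in
#' time to a stronger event are dropped. Ties break deterministically
#' toward earlier time, then smaller scale.
#'
#' @param scalogram A `scalogram`.
#' @param min_separation Minimum time separation between events, frames.
#' @param min_scale Ignore scales below this value (e.g. to query only
#'   coarse-scale structure); default keeps all scales.
#' @param exclude_coi Drop candidates inside the cone of influence, where
#'   zero padding contaminates the coefficients.
#' @return Data frame (`time_index`, `time`, `scale`, `coefficient`)
#'   sorted by decreasing `|coefficient|`.
#' @export
find_events <- function(scalogram, min_separation = 1L, min_scale = 0,
                        exclude_coi = TRUE) {
  A <- abs(scalogram$C)
  if (exclude_coi) A[scalogram$coi] <- 0
  keep_s <- which(scalogram$scales >= min_scale)
  ns <- nrow(A)
  nt <- ncol(A)
  cand <- list()
  for (si in keep_s) {
    for (ti in seq_len(nt)) {
      v <- A[si, ti]
      if (v == 0) next
      nb <- A[max(1, si - 1):min(ns, si + 1),
              max(1, ti - 1):min(nt, ti + 1)]
      if (v < max(nb)) next
      # strict on the earlier/smaller side so plateaus yield one event
      if (si > 1 && A[si - 1, ti] == v) next
      if (ti > 1 && A[si, ti - 1] == v) next
      cand[[length(cand) + 1L]] <- c(si, ti, scalogram$C[si, ti])
    }
  }
  if (!length(cand))
    return(data.frame(time_index = integer(0), time = numeric(0),
                      scale = numeric(0), coefficient = numeric(0)))
  cm <- do.call(rbind, cand)
  ord <- order(-abs(cm[, 3]), cm[, 2], cm[, 1])
  cm <- cm[ord, , drop = FALSE]
  kept <- logical(0)
  keep_rows <- integer(0)
  for (i in seq_len(nrow(cm))) {
    ti <- cm[i, 2]
    if (length(keep_rows) &&
        any(abs(cm[keep_rows, 2] - ti) < min_separation)) next
    keep_rows <- c(keep_rows, i)
  }
  cm <- cm[keep_rows, , drop = FALSE]
  data.frame(time_index = as.integer(cm[, 2]),
             time = scalogram$times[cm[, 2]],
             scale = scalogram$scales[cm[, 1]],
             coefficient = cm[, 3])
}
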