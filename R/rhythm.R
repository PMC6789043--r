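# Beat detection, interval-variability statistics, and the 95%-confidence
# Poincare ellipse used to quantify beat-to-beat instability.

#' Beat-event series
#'
#' @param beat_times Beat times in seconds, strictly increasing.
#' @return An object of class `beat_series` with `beat_times`, `intervals`
#'   (`BI_n`, successive differences) and `delta_bi`
#'   (`|BI_{n+1} - BI_n|`, absolute first differences of the intervals).
#' @export
beat_series <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L) stop("fewer than 2 beats detected")
  if (any(diff(beat_times) <= 0)) stop("beat_times must be strictly increasing")
  intervals <- diff(beat_times)
  structure(list(beat_times = beat_times, intervals = intervals,
                 delta_bi = abs(diff(intervals))),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, mean BI %.3f s, mean dBI %.3f s\n",
              length(x$beat_times), mean(x$intervals),
              if (length(x$delta_bi)) mean(x$delta_bi) else NA_real_))
  invisible(x)
}

#' Detect beats in a fluorescence or voltage trace
#'
#' Beat times are placed at transient peaks exceeding an adaptive prominence
#' threshold (half of the signal amplitude above the 10th-percentile
#' baseline), separated by a refractory period.
#'
#' @param trace A [fluor_trace] or [voltage_trace] (or any list with `time`
#'   and `value`).
#' @param refractory Minimum inter-beat separation in seconds.
#' @return A [beat_series].
#' @export
detect_beats <- function(trace, refractory = 0.25) {
  t <- trace$time; v <- trace$value
  b <- stats::quantile(v, 0.1, names = FALSE)
  amp <- max(v) - b
  if (amp <= 0 || !is.finite(amp)) stop("fewer than 2 beats detected")
  dt <- stats::median(diff(t))
  pk <- pracma::findpeaks(v, minpeakheight = b + 0.5 * amp,
                          minpeakdistance = max(1L, round(refractory / dt)))
  if (is.null(pk) || nrow(pk) < 2L) stop("fewer than 2 beats detected")
  beat_series(sort(t[pk[, 2]]))
}

#' Beat-interval variability statistics with a Poincare ellipse
#'
#' Computes the mean beat interval, the mean absolute change in beat
#' interval (`dBI`), the fraction of `dBI` strictly greater than
#' `threshold` (default 250 ms, the conventional arrhythmia flag), and the
#' 95%-confidence covariance ellipse of the lag-1 interval scatter
#' `(BI_n, BI_{n+1})`: centered at the componentwise mean, axes along the
#' eigenvectors of the sample covariance, half-lengths
#' `sqrt(qchisq(0.95, 2) * eigenvalue)`. The major/minor axis ratio is the
#' reported instability index (1 for uniform i.i.d. beating; larger under
#' lag-1 correlation).
#'
#' @param series A [beat_series] with at least 11 intervals (10 lag pairs).
#' @param threshold dBI threshold in seconds for the arrhythmic fraction.
#' @param confidence Ellipse coverage probability.
#' @return A list of class `rhythm_stats`: `mean_bi`, `mean_dbi`,
#'   `frac_dbi_above`, `threshold`, `ellipse` (a `poincare_ellipse` or
#'   `NULL` when the interval covariance is singular).
#' @export
variability_stats <- function(series, threshold = 0.250, confidence = 0.95) {
  stopifnot(inherits(series, "beat_series"))
  bi <- series$intervals
  m <- length(bi)
  if (m < 11L) stop("at least 11 intervals (10 lag pairs) are required")
  pairs <- cbind(bi[-m], bi[-1])
  S <- stats::cov(pairs)
  ellipse <- NULL
  if (!all(is.finite(S)) || min(diag(S)) <= 0 ||
      det(S) <= .Machine$double.eps * mean(diag(S))^2) {
    warning("interval covariance is singular; Poincare ellipse undefined")
  } else {
    ellipse <- poincare_ellipse(colMeans(pairs), S, confidence)
  }
  structure(list(mean_bi = mean(bi),
                 mean_dbi = mean(series$delta_bi),
                 frac_dbi_above = mean(series$delta_bi > threshold),
                 threshold = threshold,
                 n_pairs = m - 1L,
                 ellipse = ellipse),
            class = "rhythm_stats")
}

#' 95%-confidence covariance ellipse of a lag-1 interval scatter
#'
#' @param center Componentwise mean of the `(BI_n, BI_{n+1})` pairs.
#' @param cov 2x2 sample covariance.
#' @param confidence Coverage probability.
#' @return An object of class `poincare_ellipse` with `center`,
#'   `major_axis`/`minor_axis` (half-lengths, seconds), `angle` (radians,
#'   major-axis direction) and `axis_ratio` (major/minor, >= 1).
#' @export
poincare_ellipse <- function(center, cov, confidence = 0.95) {
  e <- eigen(cov, symmetric = TRUE)
  q <- stats::qchisq(confidence, df = 2)
  half <- sqrt(q * pmax(e$values, 0))
  structure(list(center = as.numeric(center),
                 major_axis = half[1], minor_axis = half[2],
                 angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 axis_ratio = half[1] / half[2],
                 confidence = confidence),
            class = "poincare_ellipse")
}

#' @export
print.poincare_ellipse <- function(x, ...) {
  cat(sprintf(
    "<poincare_ellipse> %.0f%% CI, center (%.3f, %.3f) s, axes %.3f/%.3f s, ratio %.3f\n",
    100 * x$confidence, x$center[1], x$center[2],
    x$major_axis, x$minor_axis, x$axis_ratio))
  invisible(x)
}

#' @export
print.rhythm_stats <- function(x, ...) {
  cat(sprintf("<rhythm_stats> mean BI %.3f s, mean dBI %.3f s, %.1f%% dBI > %g ms\n",
              x$mean_bi, x$mean_dbi, 100 * x$frac_dbi_above,
              1000 * x$threshold))
  if (!is.null(x$ellipse)) print(x$ellipse) else cat("  ellipse undefined\n")
  invisible(x)
}

#' Plot a Poincare lag scatter with its fitted ellipse
#'
#' @param x A [beat_series].
#' @param stats Optional precomputed [variability_stats()] result.
#' @param ... Passed to `plot`.
#' @export
plot.beat_series <- function(x, stats = NULL, ...) {
  bi <- x$intervals; m <- length(bi)
  graphics::plot(bi[-m], bi[-1], xlab = expression(BI[n] ~ "(s)"),
                 ylab = expression(BI[n + 1] ~ "(s)"), asp = 1, ...)
  if (is.null(stats) && m >= 11L) stats <- variability_stats(x)
  el <- stats$ellipse
  if (!is.null(el)) {
    th <- seq(0, 2 * pi, length.out = 181)
    R <- cbind(c(cos(el$angle), sin(el$angle)),
               c(-sin(el$angle), cos(el$angle)))
    pts <- t(R %*% rbind(el$major_axis * cos(th), el$minor_axis * sin(th)))
    graphics::lines(pts[, 1] + el$center[1], pts[, 2] + el$center[2],
                    col = "red3")
  }
  invisible(x)
}
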