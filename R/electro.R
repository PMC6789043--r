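# Action-potential and optical-wave repolarization metrics.

#' Action-potential metrics from a patch-clamp trace
#'
#' The upstroke is the point of maximum `dV/dt`. `APDx` is the time from the
#' upstroke to the (interpolated) crossing of
#' `peak - x% * (peak - resting)`; the repolarization reference is the
#' resting potential, not 0 mV. The resting potential is the mean of the
#' diastolic samples of a gap-free recording when one is provided (the 20%
#' most negative samples), otherwise the pre-stimulus mean. The
#' repolarization decay constant reuses the exponential fit machinery of
#' [fit_tau()] on the 10-90% repolarization window.
#'
#' @param trace A [voltage_trace] of kind `patch_ap` containing one evoked
#'   action potential (membrane potentials are assumed tip-potential
#'   corrected upstream).
#' @param gapfree Optional gap-free [voltage_trace] of spontaneous activity
#'   used for the maximum diastolic (resting) potential.
#' @param min_amplitude Minimum upstroke amplitude (mV) below which no AP is
#'   declared.
#' @return A list of class `ap_metrics`: `APD50`, `APD90` (ms),
#'   `peak_amplitude` (mV above resting), `peak`, `resting_potential` (mV),
#'   `upstroke_time` (s) and `tau_decay` (s, `NA` if the fit fails).
#' @export
ap_metrics <- function(trace, gapfree = NULL, min_amplitude = 10) {
  stopifnot(inherits(trace, "voltage_trace"), trace$kind == "patch_ap")
  t <- trace$time; v <- trace$value
  iu <- which.max(diff(v))
  t_up <- t[iu]
  ipk <- iu + which.max(v[iu:length(v)]) - 1L
  peak <- v[ipk]
  resting <- if (!is.null(gapfree)) {
    g <- gapfree$value
    mean(g[g <= stats::quantile(g, 0.2, names = FALSE)])
  } else if (iu > 1L) mean(v[1:iu]) else v[1]
  amp <- peak - resting
  if (amp < min_amplitude) stop("no AP detected: upstroke amplitude too small")
  after <- ipk:length(v)
  cross <- function(frac) {
    tc <- first_crossing(t, v, peak - frac * amp, after, "down")
    if (is.na(tc) && frac >= 0.9)
      stop("trace never repolarizes to 90%")
    tc - t_up
  }
  apd50 <- cross(0.5); apd90 <- cross(0.9)
  tau <- tryCatch(
    fit_tau(list(time = t[after], value = v[after]), f0 = resting)$tau,
    error = function(e) NA_real_)
  structure(list(APD50 = 1000 * apd50, APD90 = 1000 * apd90,
                 peak_amplitude = amp, peak = peak,
                 resting_potential = resting, upstroke_time = t_up,
                 tau_decay = tau),
            class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat(sprintf(
    "<ap_metrics> APD50 %.1f ms, APD90 %.1f ms, peak %.1f mV, rest %.1f mV, tau %.3g s\n",
    x$APD50, x$APD90, x$peak, x$resting_potential, x$tau_decay))
  invisible(x)
}

#' Wave metrics from an optical voltage-dye trace
#'
#' Per wave: amplitude (peak minus baseline), maximum depolarization rate
#' (max `dF/dt` on the upstroke), and the wave durations `WD50`/`WD90` --
#' the widths of the wave at the 50% and 90% repolarization levels
#' (interpolated up- and down-crossings of `peak - x% * amplitude`).
#' Per-wave values are averaged.
#'
#' @param trace A [voltage_trace] of kind `optical_wave` containing at least
#'   3 waves (a warning is issued below 3).
#' @return A list of class `wave_metrics`: `WD50`, `WD90` (ms), `amplitude`,
#'   `max_depol_rate` (units/s), `n_waves`, and the per-wave table in
#'   `$per_wave`.
#' @export
optical_wave_metrics <- function(trace) {
  stopifnot(inherits(trace, "voltage_trace"), trace$kind == "optical_wave")
  t <- trace$time; v <- trace$value
  peaks <- locate_peaks(t, v)
  if (length(peaks) == 0L) stop("no waves detected")
  if (length(peaks) < 3L) warning("fewer than 3 waves detected")
  b <- stats::quantile(v, 0.1, names = FALSE)
  dt <- stats::median(diff(t))
  bounds <- c(1L, floor((peaks[-length(peaks)] + peaks[-1]) / 2),
              length(v))
  rows <- lapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    seg <- bounds[i]:bounds[i + 1L]
    amp <- v[p] - b
    up_seg <- seg[seg <= p]
    rate <- if (length(up_seg) > 1L) max(diff(v[up_seg])) / dt else NA_real_
    width <- function(frac) {
      level <- v[p] - frac * amp
      tu <- first_crossing(t, v, level, up_seg[-length(up_seg)], "up")
      td <- first_crossing(t, v, level, seg[seg >= p], "down")
      td - tu
    }
    data.frame(wave = i, amplitude = amp, max_depol_rate = rate,
               WD50 = width(0.5), WD90 = width(0.9))
  })
  per_wave <- do.call(rbind, rows)
  structure(list(WD50 = 1000 * mean(per_wave$WD50, na.rm = TRUE),
                 WD90 = 1000 * mean(per_wave$WD90, na.rm = TRUE),
                 amplitude = mean(per_wave$amplitude),
                 max_depol_rate = mean(per_wave$max_depol_rate, na.rm = TRUE),
                 n_waves = nrow(per_wave), per_wave = per_wave),
            class = "wave_metrics")
}

#' @export
print.wave_metrics <- function(x, ...) {
  cat(sprintf(
    "<wave_metrics> %d waves: WD50 %.1f ms, WD90 %.1f ms, amplitude %.3g, max dF/dt %.3g /s\n",
    x$n_waves, x$WD50, x$WD90, x$amplitude, x$max_depol_rate))
  invisible(x)
}
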