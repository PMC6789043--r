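# Synthetic electrophysiology: stylized action potentials with analytically
# placed repolarization crossings, optical voltage waves with exact widths,
# and beat-event series from a stationary lag-1 Gaussian interval model.

#' Generate synthetic electrophysiology data
#'
#' Three modalities:
#' \describe{
#'   \item{`patch_ap`}{A single evoked action potential: resting potential,
#'     a steep linear upstroke, and a piecewise-linear repolarization whose
#'     50% and 90% crossings sit exactly `APD50`/`APD90` after the upstroke.}
#'   \item{`optical_wave`}{A train of normalized voltage-dye waves whose
#'     widths at the 50% and 90% repolarization levels equal `wd50`/`wd90`
#'     exactly.}
#'   \item{`beat_events`}{Beat intervals drawn from a stationary Gaussian
#'     AR(1) model whose population lag-1 correlation `rho` is derived from
#'     the preset's Poincare ellipse axis-ratio target via
#'     `ratio = sqrt((1 + rho) / (1 - rho))`.}
#' }
#'
#' @param preset Preset object or name. `patch_ap` reads `apd90` (ms);
#'   `beat_events` reads `poincare_ratio`.
#' @param kind One of `"patch_ap"`, `"optical_wave"`, `"beat_events"`.
#' @param n Number of waves (`optical_wave`) or beat intervals
#'   (`beat_events`, minimum 10).
#' @param noise A [noise_model()] added to voltage samples or beat intervals.
#' @param sample_rate Samples per second for voltage traces.
#' @param apd50_frac `APD50` as a fraction of `APD90` (plateau shape; the
#'   source reports only `APD90`).
#' @param rest,peak Resting and peak potential, mV (`patch_ap`).
#' @param wave_period,wave_rise,wd50,wd90 Optical-wave timing in seconds;
#'   widths are measured at the 50%/90% repolarization levels. No wave
#'   duration is printed in the source, so these are synthetic defaults.
#' @param mean_bi,sd_bi Mean and marginal SD of the beat intervals, seconds.
#' @param lag_cov Optional 2x2 covariance of successive intervals
#'   `(BI_n, BI_{n+1})`; overrides the preset-derived correlation. Must be
#'   symmetric positive-definite with equal diagonal (stationarity).
#' @param seed Integer seed for `beat_events`.
#' @return A list with `trace` ([voltage_trace]) or `series`
#'   ([beat_series]) plus a `truth` list of the planted parameters.
#' @export
gen_electro <- function(preset = "WT_12D_GlcFA",
                        kind = c("patch_ap", "optical_wave", "beat_events"),
                        n = 5L, noise = noise_model("none"),
                        sample_rate = 1e4, apd50_frac = 0.8,
                        rest = -75, peak = 40,
                        wave_period = 1, wave_rise = 0.08,
                        wd50 = 0.40, wd90 = 0.70,
                        mean_bi = 1.2, sd_bi = 0.12,
                        lag_cov = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(noise, "noise_model"))
  switch(kind,
    patch_ap = gen_patch_ap(preset, sample_rate, apd50_frac, rest, peak, noise),
    optical_wave = gen_optical_wave(n, sample_rate, wave_period, wave_rise,
                                    wd50, wd90, noise),
    beat_events = gen_beat_events(preset, n, mean_bi, sd_bi, lag_cov,
                                  noise, seed))
}

gen_patch_ap <- function(preset, sample_rate, apd50_frac, rest, peak, noise) {
  preset <- cp_preset(preset)
  apd90 <- preset_value(preset, "apd90") / 1000  # ms -> s
  apd50 <- apd50_frac * apd90
  stopifnot(apd50 < apd90, peak > rest)
  dt <- 1 / sample_rate
  up_dur <- dt                       # single-sample upstroke: max dV/dt is
                                     # unambiguous and marks the onset exactly
  t_up <- round(0.05 / dt) * dt      # upstroke onset, on the sample grid
  amp <- peak - rest
  anchors_t <- c(0, t_up, t_up + up_dur,
                 t_up + apd50, t_up + apd90, t_up + apd90 + 0.05)
  anchors_v <- c(rest, rest, peak,
                 peak - 0.5 * amp, peak - 0.9 * amp, rest)
  t_end <- t_up + apd90 + 0.15
  time <- seq(0, t_end, by = dt)
  v <- stats::approx(anchors_t, anchors_v, xout = time, rule = 2)$y
  v <- apply_noise(v, noise)
  list(trace = voltage_trace(time, v, "patch_ap"),
       truth = list(preset = preset$name, apd50 = apd50 * 1000,
                    apd90 = apd90 * 1000, rest = rest, peak = peak,
                    upstroke_time = t_up, amplitude = amp))
}

gen_optical_wave <- function(n, sample_rate, period, rise, wd50, wd90, noise) {
  if (wd50 <= 0.5 * rise || wd90 - wd50 <= 0.4 * rise)
    stop("wave widths incompatible with the rise time")
  if (0.1 * rise + wd90 + 0.06 >= period)
    stop("wave period too short for the requested widths")
  dt <- 1 / sample_rate
  onsets <- 0.2 + (seq_len(n) - 1L) * period
  time <- seq(0, 0.2 + n * period, by = dt)
  v <- numeric(length(time))
  for (t0 in onsets) {
    at <- c(t0, t0 + rise,
            t0 + 0.5 * rise + wd50, t0 + 0.1 * rise + wd90,
            t0 + 0.1 * rise + wd90 + 0.05)
    av <- c(0, 1, 0.5, 0.1, 0)
    seg <- time >= t0 & time <= at[5]
    v[seg] <- stats::approx(at, av, xout = time[seg])$y
  }
  v <- apply_noise(v, noise)
  list(trace = voltage_trace(time, v, "optical_wave"),
       truth = list(n_waves = n, wd50 = wd50, wd90 = wd90, amplitude = 1,
                    max_depol_rate = 1 / rise, onsets = onsets))
}

gen_beat_events <- function(preset, n, mean_bi, sd_bi, lag_cov, noise, seed) {
  if (n < 10L) stop("beat_events requires n >= 10 intervals")
  if (!is.null(lag_cov)) {
    lag_cov <- as.matrix(lag_cov)
    if (!isTRUE(all.equal(lag_cov, t(lag_cov))) ||
        any(eigen(lag_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("lag covariance must be symmetric positive-definite")
    if (abs(lag_cov[1, 1] - lag_cov[2, 2]) > 1e-8 * lag_cov[1, 1])
      stop("stationarity requires equal variances in the lag covariance")
    sd_bi <- sqrt(lag_cov[1, 1])
    rho <- lag_cov[1, 2] / lag_cov[1, 1]
  } else {
    ratio <- preset_value(cp_preset(preset), "poincare_ratio")
    rho <- (ratio^2 - 1) / (ratio^2 + 1)
  }
  if (abs(rho) >= 1) stop("lag-1 correlation must lie in (-1, 1)")
  x <- with_seed(seed, {
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    if (n > 1) {
      innov <- stats::rnorm(n - 1, sd = sqrt(1 - rho^2))
      for (i in 2:n) z[i] <- rho * z[i - 1] + innov[i - 1]
    }
    z
  })
  intervals <- mean_bi + sd_bi * x
  intervals <- apply_noise(intervals, noise)
  if (any(intervals <= 0))
    stop("interval model produced non-positive intervals; reduce sd_bi")
  series <- beat_series(beat_times = cumsum(c(0.5, intervals)))
  list(series = series,
       truth = list(rho = rho, sd_bi = sd_bi, mean_bi = mean_bi,
                    pop_axis_ratio = sqrt((1 + rho) / (1 - rho)),
                    intervals = intervals))
}
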