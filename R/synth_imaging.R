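# Synthetic calcium-imaging stacks: a single beating cell on a dark
# background, with beat-locked fluorescence transients and known ground truth.

#' Generate a synthetic calcium-imaging stack
#'
#' Simulates a single cell (bright disc) on a darker background. In-cell
#' pixels follow `F0 + (F - F0) * w(t)` where `w` rises linearly to 1 over
#' the time-to-peak and then relaxes exponentially with constant `tau`
#' (truncated so each beat ends exactly on baseline before the next
#' upstroke); background pixels sit at a constant level. Optional additive
#' Gaussian noise. All generation parameters, the true cell mask, the
#' analytic in-cell trace and per-beat transient metrics are returned as
#' ground truth.
#'
#' @param preset Preset object or name carrying `ca_fold` (peak/baseline
#'   fluorescence ratio) and `ca_tau` (s); see [cp_presets()].
#' @param dim Image size in pixels, `c(rows, cols)`.
#' @param pixel_size Micrometers per pixel.
#' @param frame_rate Frames per second; must be at least 20.
#' @param pacing_hz Stimulation frequency in Hz (0.5 or 1 in the source
#'   protocol); one transient per pacing period.
#' @param n_beats Number of beats; at least 5.
#' @param t_peak Time from upstroke onset to peak, seconds. Kept a multiple
#'   of the frame period so the analytic peak falls on a sampled frame.
#' @param baseline_hold Flat baseline between the end of relaxation and the
#'   next upstroke, seconds.
#' @param f0 Baseline in-cell intensity (arbitrary units).
#' @param background Constant background intensity.
#' @param cell_radius Cell radius in pixels; default scales with image size.
#' @param noise A [noise_model()].
#' @return A list of class `ca_stack_sim` with elements `stack`
#'   ([ca_stack]), `mask` (logical matrix), and `truth` (analytic trace,
#'   per-beat [transient metrics][transient_metrics()], and all parameters).
#' @export
gen_imaging <- function(preset = "WT_12D_GlcFA",
                        dim = c(48L, 48L), pixel_size = 0.5,
                        frame_rate = 50, pacing_hz = 0.5, n_beats = 5L,
                        t_peak = 0.16, baseline_hold = 0.34,
                        f0 = 100, background = 10,
                        cell_radius = round(min(dim) * 0.33),
                        noise = noise_model("none")) {
  preset <- cp_preset(preset)
  fold <- preset_value(preset, "ca_fold")
  tau <- preset_value(preset, "ca_tau")
  check_pos(pacing_hz, "pacing_hz")
  check_pos(frame_rate, "frame_rate")
  if (frame_rate < 20) stop("frame_rate must be at least 20 fps")
  if (n_beats < 5L) stop("duration too short: at least 5 beats are required")
  stopifnot(inherits(noise, "noise_model"))

  period <- 1 / pacing_hz
  dt <- 1 / frame_rate
  # snap the waveform anchors onto the frame grid so peaks are sampled exactly
  t_peak <- round(t_peak / dt) * dt
  lead_in <- round(0.4 / dt) * dt
  decay <- period - t_peak - baseline_hold
  if (decay <= 3 * dt)
    stop("pacing period too short for the transient shape")
  n_frames <- ceiling((lead_in + n_beats * period) / dt) + 1L
  time <- (seq_len(n_frames) - 1L) * dt
  onsets <- lead_in + (seq_len(n_beats) - 1L) * period

  w <- numeric(n_frames)
  for (on in onsets) w <- w + transient_shape(time, on, t_peak, tau, decay)
  # f0 and the fold are defined on the background-corrected scale, so the
  # planted in-cell intensity rides on top of the background level
  f_amp <- f0 * (fold - 1)
  cell_value <- background + f0 + f_amp * w

  rows <- dim[1]; cols <- dim[2]
  cx <- (rows + 1) / 2; cy <- (cols + 1) / 2
  rr <- outer(seq_len(rows), rep(1, cols)) - cx
  cc <- outer(rep(1, rows), seq_len(cols)) - cy
  mask <- (rr^2 + cc^2) <= cell_radius^2

  frames <- array(background, dim = c(n_frames, rows, cols))
  idx <- which(mask)
  for (ti in seq_len(n_frames)) {
    fr <- frames[ti, , ]
    fr[idx] <- cell_value[ti]
    frames[ti, , ] <- fr
  }
  frames <- array(apply_noise(as.numeric(frames), noise), dim = dim(frames))

  t50 <- transient_shape_relax_time(0.5, tau, decay)
  t90 <- transient_shape_relax_time(0.9, tau, decay)
  beat_truth <- data.frame(
    beat = seq_len(n_beats), onset = onsets, F0 = f0, F = f0 * fold,
    fold = fold, T_peak = t_peak, T50R = t50, T90R = t90,
    R_peak = f_amp / t_peak, R50R = 0.5 * f_amp / t50,
    R90R = 0.9 * f_amp / t90, tau = tau
  )

  structure(list(
    stack = ca_stack(frames, frame_rate, pixel_size),
    mask = mask,
    truth = list(
      trace = fluor_trace(time, f0 + f_amp * w,
                          background_corrected = TRUE),
      cell_value = cell_value, background = background,
      metrics = beat_truth,
      params = list(preset = preset$name, fold = fold, tau = tau,
                    pacing_hz = pacing_hz, frame_rate = frame_rate,
                    t_peak = t_peak, decay = decay, f0 = f0,
                    n_beats = n_beats, noise = noise)
    )), class = "ca_stack_sim")
}

#' @export
print.ca_stack_sim <- function(x, ...) {
  cat(sprintf("<ca_stack_sim> preset %s: ", x$truth$params$preset))
  print(x$stack)
  invisible(x)
}
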