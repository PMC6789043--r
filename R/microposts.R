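# Micropost traction mechanics: deflections -> total twitch force, twitch
# velocity and mechanical power.

#' Micropost recording container
#'
#' @param positions Numeric array `frames x posts x 2` of post-top (x, y)
#'   positions in micrometers.
#' @param rest_positions Optional `posts x 2` matrix of undeflected
#'   positions. When missing they are estimated later from the frame at the
#'   10th percentile of total deflection (diastole).
#' @param frame_rate Frames per second.
#' @param k_post Post bending stiffness in nN/um (calibrated platform value
#'   56.5 by default).
#' @param spacing Center-to-center post spacing in micrometers (6 by
#'   default).
#' @return An object of class `micropost_recording`.
#' @export
micropost_recording <- function(positions, rest_positions = NULL,
                                frame_rate, k_post = 56.5, spacing = 6) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3] == 2L)
  check_pos(k_post, "k_post")
  check_pos(frame_rate, "frame_rate")
  if (dim(positions)[2] < 1L) stop("at least one post is required")
  if (!is.null(rest_positions)) {
    rest_positions <- as.matrix(rest_positions)
    if (nrow(rest_positions) != dim(positions)[2])
      stop("post-count mismatch between positions and rest_positions")
  }
  structure(list(positions = positions, rest_positions = rest_positions,
                 frame_rate = frame_rate, k_post = k_post, spacing = spacing),
            class = "micropost_recording")
}

#' @export
print.micropost_recording <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<micropost_recording> %d posts, %d frames at %g fps, k = %g nN/um\n",
              d[2], d[1], x$frame_rate, x$k_post))
  invisible(x)
}

#' Per-post deflection magnitudes
#'
#' `Delta_i(t)` is the Euclidean distance between each post's position and
#' its rest position. Rest positions not supplied with the recording are
#' taken from the frame at the 10th percentile of provisional total
#' deflection (a diastolic frame).
#'
#' @param rec A [micropost_recording].
#' @return A `frames x posts` matrix of deflections in micrometers, with the
#'   rest positions used in `attr(, "rest_positions")`.
#' @export
compute_deflections <- function(rec) {
  stopifnot(inherits(rec, "micropost_recording"))
  pos <- rec$positions
  nf <- dim(pos)[1]; np <- dim(pos)[2]
  px <- matrix(pos[, , 1], nf, np)
  py <- matrix(pos[, , 2], nf, np)
  rest <- rec$rest_positions
  if (is.null(rest)) {
    cx <- colMeans(px); cy <- colMeans(py)
    prov <- sqrt(sweep(px, 2, cx)^2 + sweep(py, 2, cy)^2)
    tot <- rowSums(prov)
    i_rest <- which.min(abs(tot - stats::quantile(tot, 0.1, names = FALSE)))
    rest <- cbind(px[i_rest, ], py[i_rest, ])
  }
  defl <- sqrt(sweep(px, 2, rest[, 1])^2 + sweep(py, 2, rest[, 2])^2)
  attr(defl, "rest_positions") <- rest
  defl
}

#' Twitch force, velocity and power from post deflections
#'
#' The total force trace is `F(t) = sum_i k_post * Delta_i(t)`. The twitch
#' force is its systolic peak minus the diastolic baseline (10th
#' percentile); the absolute peak is also reported. Twitch velocity is the
#' contraction-phase peak of the total deflection rate
#' `d/dt sum_i Delta_i(t)` (um/s), and power is the contraction-phase peak
#' of force times that rate, in femtowatts (`nN * um/s = fW`).
#'
#' @param deflections `frames x posts` deflection matrix (um), e.g. from
#'   [compute_deflections()].
#' @param k_post Post stiffness, nN/um.
#' @param frame_rate Frames per second.
#' @return A list of class `twitch_metrics`: `twitch_force` (nN),
#'   `peak_force` (nN, absolute), `baseline_force` (nN), `twitch_velocity`
#'   (um/s), `power` (fW) and the per-frame `force_trace`.
#' @export
twitch_metrics <- function(deflections, k_post = 56.5, frame_rate) {
  if (k_post <= 0) stop("k_post must be positive")
  check_pos(frame_rate, "frame_rate")
  deflections <- as.matrix(deflections)
  force <- rowSums(deflections) * k_post
  if (diff(range(force)) <= .Machine$double.eps^0.5 * max(1, max(force)))
    stop("constant deflections: no beat detected")
  baseline <- stats::quantile(force, 0.1, names = FALSE)
  total_defl <- rowSums(deflections)
  vel <- c(NA_real_, diff(total_defl)) * frame_rate
  contracting <- which(!is.na(vel) & vel > 0)
  twitch_velocity <- if (length(contracting)) max(vel[contracting]) else 0
  power <- if (length(contracting))
    max(force[contracting] * vel[contracting]) else 0
  structure(list(twitch_force = max(force) - baseline,
                 peak_force = max(force),
                 baseline_force = baseline,
                 twitch_velocity = twitch_velocity,
                 power = power,
                 force_trace = force,
                 k_post = k_post, frame_rate = frame_rate),
            class = "twitch_metrics")
}

#' @export
print.twitch_metrics <- function(x, ...) {
  cat(sprintf(
    "<twitch_metrics> twitch force %.2f nN (peak %.2f, baseline %.2f), velocity %.2f um/s, power %.2f fW\n",
    x$twitch_force, x$peak_force, x$baseline_force, x$twitch_velocity,
    x$power))
  invisible(x)
}

#' Generate a synthetic micropost recording
#'
#' Posts sit on a grid with the given spacing; each post deflects along +x
#' with the same transient shape as the calcium generator (linear rise,
#' truncated exponential relaxation returning exactly to rest between
#' beats), scaled so the peak total force `sum_i k * Delta_i` equals the
#' preset twitch-force target.
#'
#' @param preset Preset object or name carrying `twitch_force` (nN).
#' @param n_posts Number of posts under the cell (>= 1).
#' @param k Post stiffness, nN/um.
#' @param spacing Post spacing, um.
#' @param frame_rate Frames per second.
#' @param pacing_hz Beats per second.
#' @param n_beats Number of beats.
#' @param t_peak,tau Contraction rise time and relaxation constant, seconds.
#'   When `t_peak` is `NULL` and the preset also prints a `power` target,
#'   the rise time is derived from it: the contraction-phase peak of
#'   force x total deflection velocity equals `F^2 / (k * t_peak)` for this
#'   twitch shape, so `t_peak = F^2 / (k * power)` makes the generated
#'   recording consistent with both printed group means.
#' @param noise A [noise_model()] applied to the position coordinates (um).
#' @return A list of class `micropost_sim` with `recording`
#'   ([micropost_recording]) and `truth` (per-post peak deflection, the
#'   deflection waveforms, peak total force, and parameters).
#' @export
gen_micropost <- function(preset = "EV", n_posts = 4L, k = 56.5, spacing = 6,
                          frame_rate = 100, pacing_hz = 1, n_beats = 3L,
                          t_peak = NULL, tau = 0.25,
                          noise = noise_model("none")) {
  preset <- cp_preset(preset)
  target <- preset_value(preset, "twitch_force")
  if (n_posts < 1L) stop("at least one post is required")
  check_pos(k, "k")
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(t_peak)) {
    t_peak <- if ("power" %in% names(preset$parameters))
      target^2 / (k * preset_value(preset, "power")) else 0.15
  }
  period <- 1 / pacing_hz
  dt <- 1 / frame_rate
  t_peak <- round(t_peak / dt) * dt
  decay <- period - t_peak - 0.2
  if (decay <= 3 * dt) stop("pacing period too short for the twitch shape")
  time <- seq(0, 0.3 + n_beats * period, by = dt)
  w <- numeric(length(time))
  onsets <- round(0.3 / dt) * dt + (seq_len(n_beats) - 1L) * period
  for (on in onsets) w <- w + transient_shape(time, on, t_peak, tau, decay)
  amp_per_post <- target / (k * n_posts)   # equal load sharing
  side <- ceiling(sqrt(n_posts))
  gx <- ((seq_len(n_posts) - 1L) %% side) * spacing
  gy <- ((seq_len(n_posts) - 1L) %/% side) * spacing
  rest <- cbind(gx, gy)
  pos <- array(0, dim = c(length(time), n_posts, 2))
  defl <- outer(w, rep(amp_per_post, length.out = n_posts))
  pos[, , 1] <- matrix(rest[, 1], length(time), n_posts, byrow = TRUE) + defl
  pos[, , 2] <- matrix(rest[, 2], length(time), n_posts, byrow = TRUE)
  pos <- array(apply_noise(as.numeric(pos), noise), dim = dim(pos))
  rec <- micropost_recording(pos, rest_positions = rest,
                             frame_rate = frame_rate, k_post = k,
                             spacing = spacing)
  list(recording = rec,
       truth = list(preset = preset$name, peak_force = target,
                    peak_power = target^2 / (k * t_peak),
                    peak_deflection = amp_per_post, waveform = defl,
                    time = time,
                    params = list(n_posts = n_posts, k = k, tau = tau,
                                  t_peak = t_peak, pacing_hz = pacing_hz)))
}
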