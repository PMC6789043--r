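# Core time-series containers shared by the imaging, electrophysiology and
# rhythm modules.

#' Fluorescence trace
#'
#' A uniformly or non-uniformly sampled fluorescence time series, optionally
#' background-corrected, as produced by [extract_trace()] or the generators.
#'
#' @param time Time points in seconds, strictly increasing.
#' @param value Fluorescence values (arbitrary units), same length as `time`.
#' @param background_corrected Logical flag.
#' @param mask Optional binary cell mask the trace was averaged over.
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(time, value, background_corrected = FALSE, mask = NULL) {
  stopifnot(length(time) == length(value))
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("time must be strictly increasing")
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 background_corrected = isTRUE(background_corrected),
                 mask = mask),
            class = "fluor_trace")
}

#' Voltage trace
#'
#' @param time Time points in seconds (uniform sampling).
#' @param value Membrane potential in mV (`patch_ap`, `patch_gapfree`) or
#'   normalized fluorescence (`optical_wave`).
#' @param kind One of `"patch_ap"`, `"patch_gapfree"`, `"optical_wave"`.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(time, value,
                          kind = c("patch_ap", "patch_gapfree", "optical_wave")) {
  kind <- match.arg(kind)
  stopifnot(length(time) == length(value))
  if (length(time) > 2L) {
    dt <- diff(time)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
      stop("voltage traces must be uniformly sampled")
  }
  structure(list(time = as.numeric(time), value = as.numeric(value), kind = kind),
            class = "voltage_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d samples over %.3g s%s\n",
              length(x$time), diff(range(x$time)),
              if (x$background_corrected) ", background-corrected" else ""))
  invisible(x)
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> [%s] %d samples over %.3g s\n",
              x$kind, length(x$time), diff(range(x$time))))
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(time_s = x$time, value = x$value)
}

#' @export
as.data.frame.voltage_trace <- function(x, ...) {
  data.frame(time_s = x$time, value = x$value, kind = x$kind)
}

#' @export
plot.fluor_trace <- function(x, ...) {
  graphics::plot(x$time, x$value, type = "l", xlab = "time (s)",
                 ylab = "fluorescence (a.u.)", ...)
  invisible(x)
}

#' @export
plot.voltage_trace <- function(x, ...) {
  ylab <- if (x$kind == "optical_wave") "dF (norm.)" else "Vm (mV)"
  graphics::plot(x$time, x$value, type = "l", xlab = "time (s)", ylab = ylab, ...)
  invisible(x)
}

#' Image stack container
#'
#' @param frames 3-D numeric array, time x rows x cols.
#' @param frame_rate Frames per second; a warning is issued below 20 fps,
#'   which undersamples transient relaxation.
#' @param pixel_size Pixel edge length in micrometers.
#' @return An object of class `ca_stack`.
#' @export
ca_stack <- function(frames, frame_rate, pixel_size = 1) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[1] < 2L) stop("an image stack needs at least 2 frames")
  check_pos(frame_rate, "frame_rate")
  check_pos(pixel_size, "pixel_size")
  if (frame_rate < 20)
    warning("frame_rate below 20 fps undersamples transient kinetics")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "ca_stack")
}

#' @export
print.ca_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<ca_stack> %d frames of %dx%d px at %g fps (%g um/px)\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

# Piecewise transient shape shared by the calcium and micropost generators:
# flat baseline, linear rise to 1 over `rise`, then a truncated exponential
# relaxation with constant `tau` that reaches exactly 0 after `decay`
# (a*exp(-s/tau) + c with c chosen so the beat ends on baseline; the decay
# constant seen by an offset-free exponential fit is still tau).
transient_shape <- function(t, onset, rise, tau, decay) {
  s <- t - onset
  w <- numeric(length(t))
  up <- s >= 0 & s < rise
  w[up] <- s[up] / rise
  dn <- s >= rise & s <= rise + decay
  k <- exp(-decay / tau)
  w[dn] <- (exp(-(s[dn] - rise) / tau) - k) / (1 - k)
  w
}

# Analytic per-beat metrics of transient_shape: time from peak to the
# crossing of `frac` relaxation of the amplitude.
transient_shape_relax_time <- function(frac, tau, decay) {
  k <- exp(-decay / tau)
  -tau * log((1 - frac) * (1 - k) + k)
}
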