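# Calcium-transient analysis: cell segmentation and background-corrected
# trace extraction from an image stack, per-beat kinetic metrics, and the
# exponential relaxation (tau) fit.

#' Extract a background-corrected fluorescence trace from an image stack
#'
#' The cell boundary is found once on the temporal-maximum projection:
#' global Otsu threshold, largest connected component, morphological closing.
#' The trace is the per-frame mean intensity inside that mask minus a
#' per-frame background estimate (median of pixels outside the mask dilated
#' by 5 px).
#'
#' @param stack A [ca_stack].
#' @param closing_size,dilate_px Structuring-element sizes in pixels for the
#'   morphological closing of the mask and the background exclusion zone.
#' @return A [fluor_trace] with the detected mask in `$mask` and the
#'   per-frame background in `attr(, "background")`. A warning flags masks
#'   touching every image border (likely truncated cell).
#' @export
extract_trace <- function(stack, closing_size = 5L, dilate_px = 5L) {
  stopifnot(inherits(stack, "ca_stack"))
  frames <- stack$frames
  proj <- apply(frames, c(2, 3), max)
  rng <- range(proj)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop("no foreground detected: degenerate intensity range")
  norm <- (proj - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (!any(bw) || all(bw))
    stop("no foreground detected: threshold degenerate")
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  sizes <- tabulate(as.integer(lab))
  mask <- matrix(as.integer(lab) == which.max(sizes), nrow(proj), ncol(proj))
  mask <- EBImage::closing(EBImage::Image(mask),
                           EBImage::makeBrush(closing_size, "disc")) > 0.5
  if (any(mask[1, ]) && any(mask[nrow(mask), ]) &&
      any(mask[, 1]) && any(mask[, ncol(mask)]))
    warning("cell mask touches all image borders; trace may be truncated")
  excl <- EBImage::dilate(EBImage::Image(mask),
                          EBImage::makeBrush(2L * dilate_px + 1L, "disc")) > 0.5
  if (all(excl)) stop("no background pixels left after mask dilation")
  n_frames <- dim(frames)[1]
  value <- numeric(n_frames); bg <- numeric(n_frames)
  midx <- which(mask); bidx <- which(!excl)
  for (ti in seq_len(n_frames)) {
    fr <- frames[ti, , ]
    bg[ti] <- stats::median(fr[bidx])
    value[ti] <- mean(fr[midx]) - bg[ti]
  }
  tr <- fluor_trace((seq_len(n_frames) - 1L) / stack$frame_rate, value,
                    background_corrected = TRUE, mask = mask)
  attr(tr, "background") <- bg
  tr
}

# Locate transient peaks: above half-amplitude over the 10th-percentile
# baseline, separated by a refractory period (0.6 of the pacing period when
# pacing is known).
locate_peaks <- function(t, v, pacing_hz = NULL, refractory = 0.25) {
  b <- stats::quantile(v, 0.1, names = FALSE)
  amp <- max(v) - b
  if (amp <= 0) return(integer(0))
  dt <- stats::median(diff(t))
  sep <- if (is.null(pacing_hz)) refractory else 0.6 / pacing_hz
  pk <- pracma::findpeaks(v, minpeakheight = b + 0.5 * amp,
                          minpeakdistance = max(1L, round(sep / dt)))
  if (is.null(pk)) integer(0) else sort(pk[, 2])
}

#' Per-beat calcium-transient kinetics
#'
#' For each detected transient: baseline `F0` (mean of the 100 ms preceding
#' the upstroke onset), peak `F`, fold change `F/F0`, time-to-peak `T_peak`
#' (upstroke onset to peak), times from peak to 50% and 90% recovery of
#' `F - F0` (`T50R`, `T90R`, sub-sample interpolated), and the rates
#' `R_peak = (F - F0)/T_peak`, `R50R = 0.5 (F - F0)/T50R`,
#' `R90R = 0.9 (F - F0)/T90R`. The upstroke onset is the last sample below
#' `F0 + 5%` of the amplitude before the peak. Per-beat values and their
#' average are returned; a warning is issued when fewer than 4 transients
#' are available for averaging.
#'
#' The fold change `F/F0` is the primary amplitude metric; the relative
#' change `(F - F0)/F0` is reported alongside as `dF_over_F0`.
#'
#' @param trace A background-corrected [fluor_trace].
#' @param pacing_hz Optional stimulation frequency; when given, beats are
#'   segmented by the pacing period, otherwise by peak detection with a
#'   0.25 s refractory period.
#' @param baseline_window Length of the pre-onset baseline window, seconds.
#' @return An object of class `transient_metrics`: a data frame with one row
#'   per beat (plus window columns `t_peak_abs`, `t90_abs` bounding the
#'   relaxation) and the across-beat means in `attr(, "average")`.
#' @export
transient_metrics <- function(trace, pacing_hz = NULL, baseline_window = 0.1) {
  t <- trace$time; v <- trace$value
  peaks <- locate_peaks(t, v, pacing_hz)
  if (length(peaks) == 0L) stop("no transients detected")
  if (length(peaks) < 4L)
    warning("fewer than 4 transients detected; averages may be unstable")
  dt <- stats::median(diff(t))
  prev_bound <- c(1L, peaks[-length(peaks)])
  rows <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    seg <- prev_bound[i]:p
    f0 <- min(v[seg])            # provisional baseline for onset search
    Fpk <- v[p]
    onset_idx <- NA_integer_
    for (pass in 1:2) {
      thr <- f0 + 0.05 * (Fpk - f0)
      below <- seg[v[seg] <= thr & seg < p]
      if (!length(below)) { onset_idx <- seg[1]; break }
      onset_idx <- max(below)    # last sub-threshold sample before the peak
      win <- t >= t[onset_idx] - baseline_window & t <= t[onset_idx]
      f0_new <- mean(v[win])
      if (abs(f0_new - f0) <= 1e-9 * max(1, abs(f0))) { f0 <- f0_new; break }
      f0 <- f0_new
    }
    amp <- Fpk - f0
    t_peak <- t[p] - t[onset_idx]
    after <- p:(if (i < length(peaks)) peaks[i + 1L] - 1L else length(v))
    t50 <- first_crossing(t, v, Fpk - 0.5 * amp, after, "down") - t[p]
    t90 <- first_crossing(t, v, Fpk - 0.9 * amp, after, "down") - t[p]
    rows[[i]] <- data.frame(
      beat = i, F0 = f0, F = Fpk, fold = Fpk / f0, dF_over_F0 = amp / f0,
      T_peak = t_peak, T50R = t50, T90R = t90,
      R_peak = amp / t_peak, R50R = 0.5 * amp / t50, R90R = 0.9 * amp / t90,
      t_onset_abs = t[onset_idx], t_peak_abs = t[p], t90_abs = t[p] + t90)
  }
  out <- do.call(rbind, rows)
  if (anyNA(out$T90R))
    warning("some transients never cross 90% recovery; T90R marked NA")
  num <- c("F0", "F", "fold", "dF_over_F0", "T_peak", "T50R", "T90R",
           "R_peak", "R50R", "R90R")
  attr(out, "average") <- colMeans(out[num], na.rm = TRUE)
  class(out) <- c("transient_metrics", "data.frame")
  out
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf("<transient_metrics> %d beats\n", nrow(x)))
  print.data.frame(round(as.data.frame(x)[, 1:11], 4), row.names = FALSE)
  avg <- attr(x, "average")
  cat(sprintf("average: fold %.3f, T_peak %.3f s, T50R %.3f s, T90R %.3f s\n",
              avg["fold"], avg["T_peak"], avg["T50R"], avg["T90R"]))
  invisible(x)
}

#' @export
summary.transient_metrics <- function(object, ...) attr(object, "average")

#' Fit the exponential relaxation constant tau
#'
#' Least-squares fit of `A * exp(-t / tau) + C` to the relaxation phase of a
#' transient, restricted to samples between the 10% and 90% relaxation
#' crossings (measured on the amplitude above `f0`). The window passed in
#' must span the peak to at least 90% recovery.
#'
#' @param segment A [fluor_trace] (or any `time`/`value` list) windowed from
#'   the transient peak to at least 90% recovery.
#' @param f0 Baseline fluorescence defining the relaxation fractions;
#'   defaults to the window minimum.
#' @return A list of class `tau_fit`: `tau` (seconds), `A`, `C`, `rss`,
#'   `n` (samples fitted). Errors if fewer than 3 samples fall in the fit
#'   window or the segment does not decay.
#' @export
fit_tau <- function(segment, f0 = NULL) {
  t <- segment$time; v <- segment$value
  ip <- which.max(v)
  if (ip >= length(v) - 2L)
    stop("segment does not decay: tau fit not possible")
  t <- t[ip:length(t)] - t[ip]; v <- v[ip:length(v)]
  if (is.null(f0)) f0 <- min(v)
  Fpk <- v[1]; amp <- Fpk - f0
  if (amp <= 0) stop("segment does not decay: tau fit not possible")
  rel <- (Fpk - v) / amp                 # relaxation fraction, 0 at peak
  in_win <- which(rel >= 0.10 & rel <= 0.90)
  if (length(in_win) < 3L)
    stop("fewer than 3 samples between the 10% and 90% relaxation crossings")
  tw <- t[in_win]; vw <- v[in_win]
  i50 <- which(rel >= 0.5)[1]
  tau0 <- if (is.na(i50)) diff(range(tw)) else t[i50] / log(2)
  fit <- tryCatch(
    minpack.lm::nlsLM(vw ~ A * exp(-tw / tau) + C,
                      start = list(A = amp, tau = max(tau0, 1e-3), C = f0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("tau fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0)
    stop("non-decaying segment: fitted tau is not positive")
  structure(list(tau = cf[["tau"]], A = cf[["A"]], C = cf[["C"]],
                 rss = sum(stats::resid(fit)^2), n = length(in_win)),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("<tau_fit> tau = %.4f s (A = %.3g, C = %.3g, n = %d, rss = %.3g)\n",
              x$tau, x$A, x$C, x$n, x$rss))
  invisible(x)
}

#' Window a trace around one transient's relaxation
#'
#' Convenience helper returning the peak-to-90%-recovery window of beat `i`
#' from a [transient_metrics()] table, ready for [fit_tau()].
#'
#' @param trace The [fluor_trace] the metrics were computed from.
#' @param metrics A `transient_metrics` object.
#' @param beat Beat number.
#' @param pad Extra seconds kept after the 90% crossing.
#' @return A [fluor_trace] window.
#' @export
relaxation_window <- function(trace, metrics, beat = 1L, pad = 0.05) {
  row <- metrics[metrics$beat == beat, ]
  if (nrow(row) != 1L) stop("no such beat in the metrics table")
  t_end <- if (is.na(row$t90_abs)) max(trace$time) else row$t90_abs + pad
  keep <- trace$time >= row$t_peak_abs & trace$time <= t_end
  fluor_trace(trace$time[keep], trace$value[keep],
              background_corrected = trace$background_corrected)
}
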