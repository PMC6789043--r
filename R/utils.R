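# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Additive noise model for the synthetic generators
#'
#' @param kind "none" for deterministic generation or "gaussian" for additive
#'   white noise with standard deviation `sd` (same units as the signal).
#' @param sd Noise standard deviation; must be non-negative.
#' @param seed Optional integer seed making the noise reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian"), sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("noise sd must be a single non-negative number")
  if (kind == "none") sd <- 0
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_model")
}

#' @noRd
apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "none" || noise$sd == 0) return(x)
  with_seed(noise$seed, x + stats::rnorm(length(x), sd = noise$sd))
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model>", x$kind,
      if (x$kind != "none") sprintf("sd = %g", x$sd),
      if (!is.null(x$seed)) sprintf("seed = %d", x$seed), "\n")
  invisible(x)
}

# Linear interpolation of the first crossing of `level` between samples
# i and i+1 of (t, v), searching indices `idx` (ordered). `direction` is
# "down" for a downward crossing (v[i] >= level > v[i+1]) or "up".
# Returns NA_real_ when no crossing occurs.
first_crossing <- function(t, v, level, idx, direction = c("down", "up")) {
  direction <- match.arg(direction)
  for (i in idx) {
    if (i >= length(v)) break
    a <- v[i]; b <- v[i + 1L]
    hit <- if (direction == "down") (a >= level && b < level)
           else (a <= level && b > level)
    if (hit) {
      f <- (level - a) / (b - a)
      return(t[i] + f * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

# Stop unless x is a single finite positive number.
check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a single positive number", name))
  invisible(x)
}
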