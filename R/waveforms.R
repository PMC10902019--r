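#' Sampled periodic waveform
#'
#' One cardiac cycle of a physical quantity sampled on a uniform phase grid.
#' The phase grid is `(0:(n-1))/n`, i.e. n points covering `[0, 1)`; the last
#' sample immediately precedes the wrap back to phase 0 of the next cycle.
#'
#' @param values numeric vector of at least 16 samples, all finite.
#' @param period cardiac cycle duration in seconds (> 0).
#' @param units units tag, one of `"cm/s"`, `"mL/min"`, `"kg/s"`, `"mm"`, `"Pa"`.
#' @return an object of class `sampled_waveform` with fields `phase`,
#'   `values`, `period`, `units`.
#' @export
sampled_waveform <- function(values, period, units) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 16L) stop("a sampled_waveform needs at least 16 samples, got ", n)
  if (!all(is.finite(values))) stop("waveform samples must all be finite")
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0)
    stop("period must be a single positive number of seconds")
  units <- match.arg(units, c("cm/s", "mL/min", "kg/s", "mm", "Pa", "Pa.s"))
  structure(
    list(phase = seq(0, 1, length.out = n + 1L)[-(n + 1L)],
         values = values, period = period, units = units),
    class = "sampled_waveform"
  )
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat(sprintf("<sampled_waveform> %d points, period %.3f s, units %s\n",
              length(x$values), x$period, x$units))
  cat(sprintf("  range [%.4g, %.4g], time average %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
plot.sampled_waveform <- function(x, ...) {
  graphics::plot(x$phase, x$values, type = "l", xlab = "cardiac phase",
                 ylab = x$units, ...)
  invisible(x)
}

is_waveform <- function(x) inherits(x, "sampled_waveform")

stopifnot_waveform <- function(x, units = NULL, what = "waveform") {
  if (!is_waveform(x)) stop(what, " must be a sampled_waveform")
  if (!is.null(units) && x$units != units)
    stop(what, " must have units '", units, "', got '", x$units, "'")
  invisible(x)
}

#' Time average of a waveform
#'
#' Mean of the samples over the uniform phase grid, which equals the
#' period-weighted time mean of the underlying periodic signal.
#'
#' @param w a [sampled_waveform()].
#' @return scalar in the same units as `w`.
#' @export
time_average <- function(w) {
  stopifnot_waveform(w)
  mean(w$values)
}

#' Resample a periodic waveform onto a new uniform phase grid
#'
#' Periodic cubic-spline interpolation; used internally when waveforms on
#' different grids must be combined.
#'
#' @param w a [sampled_waveform()].
#' @param n_points target number of phase samples.
#' @return a [sampled_waveform()] with `n_points` samples.
#' @export
resample_waveform <- function(w, n_points) {
  stopifnot_waveform(w)
  if (length(w$values) == n_points) return(w)
  grid <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  vals <- periodic_spline_eval(w$phase, w$values, grid)
  sampled_waveform(vals, w$period, w$units)
}

# Interpolating periodic cubic spline: wrap one full period on each side so
# the fit is smooth across the phase 1 -> 0 seam, then evaluate on `xout`.
periodic_spline_eval <- function(phase, values, xout) {
  x <- c(phase - 1, phase, phase + 1)
  y <- rep(values, 3L)
  stats::spline(x, y, xout = xout, method = "fmm")$y
}

# Smoothing spline for one cycle with periodic padding. Smoothing is picked
# by GCV but capped: if the smoothed curve departs from the raw samples by
# more than 1% RMS of the signal range, fall back to interpolation so that
# clean input waveforms pass through unchanged.
smooth_cycle <- function(phase, values, xout) {
  k <- max(4L, ceiling(length(values) / 4))
  n <- length(values)
  x <- c(phase[(n - k + 1L):n] - 1, phase, phase[1:k] + 1)
  y <- c(values[(n - k + 1L):n], values, values[1:k])
  fit <- try(stats::smooth.spline(x, y), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    rng <- diff(range(values))
    scale <- if (rng > 0) rng else max(abs(values), 1)
    rms <- sqrt(mean((stats::predict(fit, phase)$y - values)^2))
    if (rms <= 0.01 * scale) return(stats::predict(fit, xout)$y)
  }
  stats::spline(x, y, xout = xout, method = "fmm")$y
}

#' Peak-aligned ensemble average of cardiac cycles
#'
#' Each cycle is smoothed with a spline, resampled to `n_points` on the unit
#' phase grid, circularly shifted so that its global maximum sits at
#' `alignment_phase`, and the cycles are then averaged pointwise. The output
#' period is the arithmetic mean of the input periods.
#'
#' @param cycles list of one or more [sampled_waveform()] objects (one cardiac
#'   cycle each; units must agree).
#' @param n_points number of points on the output phase grid (default 200).
#' @param alignment_phase phase in `[0, 1)` at which the systolic peak is
#'   placed (default 0.25).
#' @return an object of class `ensemble_waveform`: a list with `waveform`
#'   (a [sampled_waveform()]), `n_cycles` and `alignment_phase`.
#' @export
ensemble_average <- function(cycles, n_points = 200L, alignment_phase = 0.25) {
  if (!is.list(cycles) || length(cycles) == 0L)
    stop("cycles must be a non-empty list of sampled_waveform objects")
  lapply(cycles, stopifnot_waveform, what = "each cycle")
  units <- unique(vapply(cycles, function(c) c$units, character(1)))
  if (length(units) != 1L) stop("all cycles must share one units tag")
  if (alignment_phase < 0 || alignment_phase >= 1)
    stop("alignment_phase must lie in [0, 1)")
  n_points <- as.integer(n_points)
  grid <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  target <- (round(alignment_phase * n_points) %% n_points) + 1L

  aligned <- vapply(cycles, function(cy) {
    v <- smooth_cycle(cy$phase, cy$values, grid)
    shift <- (target - which.max(v)) %% n_points
    if (shift > 0) v <- c(v[(n_points - shift + 1L):n_points], v[1:(n_points - shift)])
    v
  }, numeric(n_points))
  avg <- rowMeans(matrix(aligned, nrow = n_points))
  period <- mean(vapply(cycles, function(c) c$period, numeric(1)))

  structure(
    list(waveform = sampled_waveform(avg, period, units),
         n_cycles = length(cycles), alignment_phase = alignment_phase),
    class = "ensemble_waveform"
  )
}

#' @export
print.ensemble_waveform <- function(x, ...) {
  cat(sprintf("<ensemble_waveform> average of %d cycle(s), peak at phase %.2f\n",
              x$n_cycles, x$alignment_phase))
  print(x$waveform)
  invisible(x)
}

#' Duplex ultrasound recording at one extracranial artery
#'
#' @param artery one of `"LICA"`, `"RICA"`, `"LVA"`, `"RVA"` (left/right
#'   internal carotid and vertebral arteries).
#' @param cycles list of per-cycle velocity-envelope waveforms (cm/s, all
#'   values non-negative; antegrade flow only).
#' @param diameter_mm time-averaged lumen diameter in mm (> 0).
#' @return an object of class `duplex_recording`.
#' @export
duplex_recording <- function(artery, cycles, diameter_mm) {
  artery <- match.arg(artery, c("LICA", "RICA", "LVA", "RVA"))
  if (!is.list(cycles) || length(cycles) < 1L)
    stop("cycles must be a non-empty list")
  for (cy in cycles) {
    stopifnot_waveform(cy, units = "cm/s", what = "each envelope cycle")
    if (any(cy$values < 0))
      stop("envelope samples must be non-negative (antegrade protocol)")
  }
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("diameter_mm must be positive")
  structure(list(artery = artery, cycles = cycles, diameter_mm = diameter_mm),
            class = "duplex_recording")
}

#' Convert a velocity envelope to volumetric flow assuming Poiseuille flow
#'
#' The Doppler envelope is the instantaneous peak velocity; under a parabolic
#' (Poiseuille) profile the cross-sectional mean is half the peak, so
#' \eqn{Q(t) = f \, V_{env}(t) \, \pi (D/2)^2} with envelope factor
#' \eqn{f = 1/2} by default.
#'
#' @param envelope an `ensemble_waveform` or [sampled_waveform()] in cm/s with
#'   non-negative values.
#' @param diameter_mm lumen diameter in mm (> 0).
#' @param envelope_factor envelope-to-mean velocity factor (default 0.5;
#'   set to 1 if the envelope already is the cross-sectional mean velocity).
#' @return a [sampled_waveform()] in mL/min.
#' @export
poiseuille_flow <- function(envelope, diameter_mm, envelope_factor = 0.5) {
  if (inherits(envelope, "ensemble_waveform")) envelope <- envelope$waveform
  stopifnot_waveform(envelope, units = "cm/s", what = "envelope")
  if (any(envelope$values < 0)) stop("envelope values must be non-negative")
  if (!is.finite(diameter_mm) || diameter_mm <= 0)
    stop("diameter_mm must be positive")
  area_cm2 <- pi * (diameter_mm / 20)^2          # mm -> cm radius
  q <- envelope_factor * envelope$values * area_cm2 * 60  # cm3/s -> mL/min
  sampled_waveform(q, envelope$period, "mL/min")
}

#' Total cerebral blood flow
#'
#' Sum over the supplied arteries (normally LICA, RICA, LVA, RVA) of the time
#' average of each volumetric flow waveform.
#'
#' @param flows non-empty list of flow waveforms in mL/min.
#' @return tCBF in mL/min.
#' @export
total_cbf <- function(flows) {
  if (!is.list(flows) || length(flows) == 0L)
    stop("flows must be a non-empty list of waveforms")
  sum(vapply(flows, function(w) {
    stopifnot_waveform(w, units = "mL/min", what = "each flow")
    time_average(w)
  }, numeric(1)))
}

#' Convert volumetric flow to mass flow
#'
#' Pointwise \eqn{\dot m(t) = \rho Q(t)} with unit conversion from mL/min to
#' m^3/s, for prescription at solver inlet boundaries.
#'
#' @param q flow waveform in mL/min.
#' @param density fluid density in kg/m^3 (default 1050, whole blood).
#' @return a [sampled_waveform()] in kg/s.
#' @export
to_mass_flow <- function(q, density = 1050) {
  stopifnot_waveform(q, units = "mL/min", what = "q")
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  sampled_waveform(q$values * 1e-6 / 60 * density, q$period, "kg/s")
}

#' Convert mass flow back to volumetric flow
#'
#' Inverse of [to_mass_flow()].
#'
#' @param m mass flow waveform in kg/s.
#' @param density fluid density in kg/m^3.
#' @return a [sampled_waveform()] in mL/min.
#' @export
from_mass_flow <- function(m, density = 1050) {
  stopifnot_waveform(m, units = "kg/s", what = "m")
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  sampled_waveform(m$values / density * 60 / 1e-6, m$period, "mL/min")
}
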