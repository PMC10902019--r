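#' Simulated TCD-style envelope along the M1 segment
#'
#' Emulates transcranial-Doppler insonation of the MCA M1 segment: at each
#' phase point, the maximal velocity is taken at each of several stations
#' spaced along the M1 path and averaged across stations. Default three
#' stations at 25/50/75% of the path length; in a quasi-1D network with a
#' uniform M1 the stations coincide, but the interface mirrors the
#' constrained-plane extraction used against 3D simulations.
#'
#' @param sol a `network_solution`.
#' @param m1_segment_ids ids of the M1 segments, in path order.
#' @param station_fractions station positions as fractions of the total M1
#'   path length (default `c(0.25, 0.50, 0.75)`).
#' @return a [sampled_waveform()] of the station-averaged maximal velocity,
#'   cm/s.
#' @export
m1_envelope <- function(sol, m1_segment_ids,
                        station_fractions = c(0.25, 0.50, 0.75)) {
  if (length(station_fractions) == 0L) stop("need at least one station")
  if (any(station_fractions < 0 | station_fractions > 1))
    stop("station fractions must lie in [0, 1]")
  idx <- match(m1_segment_ids, sol$segments$id)
  if (anyNA(idx))
    stop("unknown segment id(s): ",
         paste(m1_segment_ids[is.na(idx)], collapse = ", "))
  len <- sol$segments$length_mm[idx]
  cum <- cumsum(len) / sum(len)
  # station at fraction f lies in the first segment whose cumulative length
  # fraction reaches f
  station_seg <- idx[vapply(station_fractions,
                            function(f) which(cum >= f - 1e-12)[1], integer(1))]
  env <- colMeans(matrix(abs(sol$v_max[station_seg, , drop = FALSE]),
                         nrow = length(station_seg)))
  sampled_waveform(env, sol$period, "cm/s")
}

#' Velocity waveform metrics
#'
#' Extracts the three standard TCD envelope metrics from a peak-aligned
#' velocity waveform: systolic (cycle maximum), time-averaged (cycle mean)
#' and end-diastolic velocity. End diastole is by default the final phase
#' sample of the peak-aligned cycle (the instant immediately preceding the
#' systolic upstroke); alternatively the minimum over the final portion of
#' the cycle.
#'
#' @param envelope velocity waveform in cm/s (peak-aligned).
#' @param end_diastolic `"last"` (default) or `"min_tail"`.
#' @param tail_fraction portion of the cycle scanned by `"min_tail"`
#'   (default 0.2).
#' @return an object of class `velocity_metrics`: named numeric vector with
#'   elements `systolic`, `time_averaged`, `end_diastolic` (cm/s).
#' @export
extract_metrics <- function(envelope, end_diastolic = c("last", "min_tail"),
                            tail_fraction = 0.2) {
  if (inherits(envelope, "ensemble_waveform")) envelope <- envelope$waveform
  stopifnot_waveform(envelope, units = "cm/s", what = "envelope")
  end_diastolic <- match.arg(end_diastolic)
  v <- envelope$values
  n <- length(v)
  ed <- if (end_diastolic == "last") v[n] else {
    k <- max(1L, ceiling(tail_fraction * n))
    min(v[(n - k + 1L):n])
  }
  structure(c(systolic = max(v), time_averaged = mean(v), end_diastolic = ed),
            class = "velocity_metrics")
}

#' @export
print.velocity_metrics <- function(x, ...) {
  cat(sprintf("<velocity_metrics> systolic %.2f, time-averaged %.2f, end-diastolic %.2f cm/s\n",
              x[["systolic"]], x[["time_averaged"]], x[["end_diastolic"]]))
  invisible(x)
}

#' Relative change of velocity metrics between conditions
#'
#' Per-metric percent change \eqn{\Delta\% = 100 (stim - rest)/rest}. Invariant
#' to any multiplicative bias applied consistently to both conditions — the
#' mechanism by which relative changes cancel a consistent within-subject
#' measurement bias.
#'
#' @param rest metrics at rest (all entries must be positive).
#' @param stimulus metrics under the stimulus condition.
#' @return an object of class `metric_delta`: named numeric vector of percent
#'   changes for `systolic`, `time_averaged`, `end_diastolic`.
#' @export
relative_change <- function(rest, stimulus) {
  need <- c("systolic", "time_averaged", "end_diastolic")
  rest <- unclass(rest)[need]
  stimulus <- unclass(stimulus)[need]
  if (anyNA(rest) || anyNA(stimulus)) stop("metrics must contain ", paste(need, collapse = ", "))
  if (any(rest <= 0)) stop("relative change requires all rest metrics > 0")
  structure(100 * (stimulus - rest) / rest, class = "metric_delta")
}

#' @export
print.metric_delta <- function(x, ...) {
  cat(sprintf("<metric_delta> systolic %+.1f%%, time-averaged %+.1f%%, end-diastolic %+.1f%%\n",
              x[["systolic"]], x[["time_averaged"]], x[["end_diastolic"]]))
  invisible(x)
}

#' Write a metrics table to CSV
#'
#' Long-form table `participant,condition,source,systolic_cm_s,time_avg_cm_s,
#' end_diastolic_cm_s` with source `"CFD"` or `"TCD"`.
#'
#' @param rows data frame in the layout above (see [study_metric_table()]).
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
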