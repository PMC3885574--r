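## Eight thermogram shape/feature metrics computed on final-stage records:
## area, width at half height, height, T_max, first-moment temperature,
## the 60-65 and 68-72 degC window amplitudes and their ratio.

#' First-moment temperature of a thermogram
#'
#' The area-weighted mean temperature of the denaturation profile — its
#' geometric centre:
#' \deqn{T_{FM} = \frac{\int T\, C_p^{ex}(T)\, dT}{\int C_p^{ex}(T)\, dT}}
#' over 45-90 degC, by the trapezoidal rule on the common grid.  Unlike the
#' peak-maximum temperature it responds to redistribution of thermogram area
#' even when the main peak position is unchanged.
#'
#' @param scan final-stage [thermogram()].
#' @return first-moment temperature, degC.
#' @export
first_moment_temperature <- function(scan) {
  require_stage(scan, "final")
  total <- trapz(scan$temperatures, scan$values)
  stop_if_not(total > 0, "total thermogram area must be positive")
  trapz(scan$temperatures, scan$temperatures * scan$values) / total
}

#' Width of the denaturation envelope at half height
#'
#' Half height refers to the global maximum.  The width is the temperature
#' span between the first and last crossings of the half-height level, each
#' located by linear interpolation between the bracketing grid points; for
#' multimodal envelopes it therefore spans the whole region where the
#' profile exceeds half the maximum.
#'
#' @param scan final-stage [thermogram()].
#' @return width, degC.
#' @export
width_at_half_height <- function(scan) {
  require_stage(scan, "final")
  v <- scan$values
  t <- scan$temperatures
  h <- max(v)
  stop_if_not(h > 0, "thermogram maximum must be positive")
  half <- h / 2
  above <- v >= half
  stop_if_not(!above[1] && !above[length(above)],
              "curve does not fall below half height on both flanks within 45-90 degC")
  cross_up <- which(!above[-length(above)] & above[-1])    # below -> at/above
  cross_dn <- which(above[-length(above)] & !above[-1])    # at/above -> below
  stop_if_not(length(cross_up) >= 1 && length(cross_dn) >= 1,
              "no half-height crossings found")
  i <- cross_up[1]
  t_first <- t[i] + (half - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  j <- cross_dn[length(cross_dn)]
  t_last <- t[j] + (half - v[j]) / (v[j + 1] - v[j]) * (t[j + 1] - t[j])
  t_last - t_first
}

#' Amplitudes of the primary and secondary transitions
#'
#' The primary transition amplitude is the maximum excess heat capacity in
#' 60-65 degC, the secondary in 68-72 degC, and their ratio is the
#' main/second transition amplitude ratio.  Window maxima (rather than
#' values at fixed temperatures) are robust to small peak drift.
#'
#' @param scan final-stage [thermogram()].
#' @param window1,window2 the two transition windows, degC.
#' @return named list: `cp_peak1`, `cp_peak2`, `ratio` (NA if `cp_peak2`
#'   is not positive).
#' @export
peak_window_amplitudes <- function(scan, window1 = c(60, 65),
                                   window2 = c(68, 72)) {
  require_stage(scan, "final")
  t <- scan$temperatures
  p1 <- max(scan$values[t >= window1[1] & t <= window1[2]])
  p2 <- max(scan$values[t >= window2[1] & t <= window2[2]])
  ratio <- if (p2 > 0) p1 / p2 else NA_real_
  if (is.na(ratio)) {
    warning("secondary transition amplitude is not positive; ratio undefined")
  }
  list(cp_peak1 = p1, cp_peak2 = p2, ratio = ratio)
}

#' Compute the eight thermogram shape and feature metrics
#'
#' Area (trapezoidal integral over 45-90 degC, cal/g), width at half height
#' (degC), height (global maximum, cal/(degC g)), temperature of the peak
#' maximum T_max (ties broken to the lowest temperature, degC), first-moment
#' temperature T_FM (degC), the primary (60-65 degC) and secondary
#' (68-72 degC) transition amplitudes and their ratio.
#'
#' @param scan final-stage [thermogram()].
#' @return one-row data.frame: sample_id, group, area, width, height, t_max,
#'   t_fm, cp_peak1, cp_peak2, ratio.
#' @export
compute_metrics <- function(scan) {
  require_stage(scan, "final")
  stop_if_not(max(scan$values) > 0, "thermogram has no positive signal")
  t <- scan$temperatures
  v <- scan$values
  amps <- peak_window_amplitudes(scan)
  data.frame(
    sample_id = scan$sample_id,
    group = scan$group,
    area = trapz(t, v),
    width = width_at_half_height(scan),
    height = max(v),
    t_max = t[which.max(v)],          # which.max returns the first maximum
    t_fm = first_moment_temperature(scan),
    cp_peak1 = amps$cp_peak1,
    cp_peak2 = amps$cp_peak2,
    ratio = amps$ratio,
    stringsAsFactors = FALSE
  )
}

#' Metric table for a list of final thermograms
#'
#' @param scans named list of final-stage thermograms.
#' @return data.frame, one row per sample.
#' @export
compute_metric_table <- function(scans) {
  do.call(rbind, lapply(scans, compute_metrics))
}
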