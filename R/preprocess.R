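## Thermogram records and the fixed preprocessing pipeline:
## raw -> reference_subtracted -> normalized -> baseline_corrected -> final.

.STAGES <- c("raw", "reference_subtracted", "normalized",
             "baseline_corrected", "final")

#' Construct a thermogram record
#'
#' A thermogram is a signal on a strictly increasing temperature grid with a
#' processing-stage tag.  Raw records are in cal/degC (whole-cell heat
#' capacity); from the `normalized` stage on the values are excess specific
#' heat capacity in cal/(degC g).
#'
#' @param sample_id sample identifier.
#' @param temperatures strictly increasing grid, degC.
#' @param values finite signal values, one per grid point.
#' @param stage one of raw, reference_subtracted, normalized,
#'   baseline_corrected, final.
#' @param group clinical group label or `NA`.
#' @param protein_conc total protein concentration, g/L (optional until
#'   normalisation).
#' @return object of class `thermogram`.
#' @export
thermogram <- function(sample_id, temperatures, values, stage = "raw",
                       group = NA_character_, protein_conc = NA_real_) {
  stop_if_not(length(temperatures) == length(values),
              "temperatures and values must have equal length")
  stop_if_not(all(diff(temperatures) > 0),
              "temperatures must be strictly increasing")
  stop_if_not(all(is.finite(values)), "values must be finite")
  stop_if_not(stage %in% .STAGES, "unknown processing stage")
  structure(list(sample_id = sample_id, temperatures = as.numeric(temperatures),
                 values = as.numeric(values), stage = stage, group = group,
                 protein_conc = protein_conc),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram %s | group %s | stage %s | %d pts, %.1f-%.1f degC>\n",
              x$sample_id, x$group, x$stage, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

require_stage <- function(scan, stage) {
  stop_if_not(inherits(scan, "thermogram"), "input must be a thermogram")
  stop_if_not(scan$stage == stage,
              sprintf("thermogram must be at stage '%s' (got '%s')",
                      stage, scan$stage))
}

#' Subtract the buffer reference scan
#'
#' Corrects for the instrumental baseline by subtracting a matched buffer
#' reference scan.  When the grids differ, the buffer is linearly
#' interpolated onto the sample grid.
#'
#' @param sample,buffer raw-stage [thermogram()] records.
#' @return reference_subtracted thermogram on the sample grid.
#' @export
subtract_reference <- function(sample, buffer) {
  require_stage(sample, "raw")
  require_stage(buffer, "raw")
  lo <- max(min(sample$temperatures), min(buffer$temperatures))
  hi <- min(max(sample$temperatures), max(buffer$temperatures))
  stop_if_not(lo <= 45 && hi >= 90,
              "sample/buffer temperature overlap does not cover 45-90 degC")
  buf <- stats::approx(buffer$temperatures, buffer$values,
                       xout = sample$temperatures, rule = 2)$y
  thermogram(sample$sample_id, sample$temperatures, sample$values - buf,
             stage = "reference_subtracted", group = sample$group,
             protein_conc = sample$protein_conc)
}

#' Normalise for total protein concentration
#'
#' Divides the reference-subtracted signal (cal/degC) by the protein mass in
#' the calorimeter cell — concentration times cell volume — yielding excess
#' specific heat capacity in cal/(degC g).
#'
#' @param scan reference_subtracted [thermogram()].
#' @param protein_conc total protein concentration, g/L; defaults to the
#'   record's own `protein_conc`.
#' @param cell_volume_uL cell volume in microlitres (default 135, the
#'   thermal sensing volume).
#' @return normalized thermogram.
#' @export
normalize_concentration <- function(scan, protein_conc = scan$protein_conc,
                                    cell_volume_uL = 135) {
  require_stage(scan, "reference_subtracted")
  stop_if_not(is.numeric(protein_conc) && is.finite(protein_conc) &&
                protein_conc > 0, "protein_conc must be positive")
  mass_g <- protein_conc * cell_volume_uL * 1e-6
  thermogram(scan$sample_id, scan$temperatures, scan$values / mass_g,
             stage = "normalized", group = scan$group,
             protein_conc = protein_conc)
}

#' Correct a non-zero sample baseline with a linear fit
#'
#' Fits a least-squares line through the points in two anchor windows that
#' flank the denaturation envelope (defaults 45-50 and 85-90 degC) and
#' subtracts it everywhere.
#'
#' @param scan normalized [thermogram()].
#' @param pre_window,post_window numeric length-2 temperature windows, degC;
#'   both must lie inside the grid and outside the 55-80 degC envelope core.
#' @return list with `corrected` (baseline_corrected thermogram) and
#'   `baseline` (named vector: intercept, slope).
#' @export
correct_linear_baseline <- function(scan, pre_window = c(45, 50),
                                    post_window = c(85, 90)) {
  require_stage(scan, "normalized")
  check_window <- function(w, name) {
    stop_if_not(length(w) == 2 && w[1] < w[2], paste(name, "must be [lo, hi]"))
    stop_if_not(w[1] >= min(scan$temperatures) && w[2] <= max(scan$temperatures),
                paste(name, "must lie inside the temperature grid"))
    stop_if_not(w[2] <= 55 || w[1] >= 80,
                paste(name, "must lie outside the 55-80 degC envelope"))
  }
  check_window(pre_window, "pre_window")
  check_window(post_window, "post_window")
  t <- scan$temperatures
  in_anchor <- (t >= pre_window[1] & t <= pre_window[2]) |
               (t >= post_window[1] & t <= post_window[2])
  stop_if_not(sum(t >= pre_window[1] & t <= pre_window[2]) >= 2 &&
                sum(t >= post_window[1] & t <= post_window[2]) >= 2,
              "each anchor window must contain at least 2 grid points")
  fit <- stats::lm.fit(cbind(1, t[in_anchor]), scan$values[in_anchor])
  coefs <- fit$coefficients
  corrected <- scan$values - (coefs[1] + coefs[2] * t)
  list(
    corrected = thermogram(scan$sample_id, t, corrected,
                           stage = "baseline_corrected", group = scan$group,
                           protein_conc = scan$protein_conc),
    baseline = c(intercept = unname(coefs[1]), slope = unname(coefs[2]))
  )
}

#' Truncate and resample onto the common analysis grid
#'
#' The 45-90 degC range spans the complete plasma denaturation profile; all
#' downstream analyses use this window on a common uniform grid.
#'
#' @param scan baseline_corrected [thermogram()].
#' @param range temperature range, degC (default `c(45, 90)`).
#' @param step grid step, degC (default 0.1).
#' @return final-stage thermogram on `seq(range[1], range[2], by = step)`.
#' @export
truncate_and_resample <- function(scan, range = c(45, 90), step = 0.1) {
  require_stage(scan, "baseline_corrected")
  stop_if_not(min(scan$temperatures) <= range[1] &&
                max(scan$temperatures) >= range[2],
              "scan does not cover the requested range")
  grid <- seq(range[1], range[2], by = step)
  vals <- stats::approx(scan$temperatures, scan$values, xout = grid)$y
  thermogram(scan$sample_id, grid, vals, stage = "final",
             group = scan$group, protein_conc = scan$protein_conc)
}

#' Run the full preprocessing pipeline on one sample/buffer pair
#'
#' Reference subtraction, concentration normalisation, linear baseline
#' correction and truncation to the common 45-90 degC grid, in the fixed
#' order.
#'
#' @param sample,buffer raw [thermogram()] records.
#' @param protein_conc g/L; defaults to the sample record's value.
#' @param pre_window,post_window baseline anchor windows (see
#'   [correct_linear_baseline()]).
#' @param cell_volume_uL calorimeter cell volume, uL.
#' @param range,step final grid (see [truncate_and_resample()]).
#' @return final-stage thermogram.
#' @export
process_thermogram <- function(sample, buffer,
                               protein_conc = sample$protein_conc,
                               pre_window = c(45, 50),
                               post_window = c(85, 90),
                               cell_volume_uL = 135,
                               range = c(45, 90), step = 0.1) {
  x <- subtract_reference(sample, buffer)
  x <- normalize_concentration(x, protein_conc, cell_volume_uL)
  x <- correct_linear_baseline(x, pre_window, post_window)$corrected
  truncate_and_resample(x, range, step)
}

#' Average duplicate final-stage thermograms of one sample
#'
#' Duplicate DSC scans are combined by pointwise averaging after full
#' preprocessing, so one curve per sample enters the group statistics.
#'
#' @param scans list of final-stage thermograms on a common grid.
#' @return final-stage thermogram.
#' @export
average_thermograms <- function(scans) {
  stop_if_not(length(scans) >= 1, "no scans to average")
  for (s in scans) require_stage(s, "final")
  t0 <- scans[[1]]$temperatures
  for (s in scans[-1]) {
    stop_if_not(length(s$temperatures) == length(t0) &&
                  max(abs(s$temperatures - t0)) < 1e-9,
                "scans must share a common grid")
  }
  vals <- rowMeans(vapply(scans, function(s) s$values,
                          numeric(length(t0))))
  thermogram(scans[[1]]$sample_id, t0, vals, stage = "final",
             group = scans[[1]]$group, protein_conc = scans[[1]]$protein_conc)
}

#' Process every sample of a simulated or loaded cohort
#'
#' @param cohort list with `manifest` and `records` as returned by
#'   [simulate_cohort()] or [read_cohort()].
#' @param ... passed to [process_thermogram()].
#' @return named list of final-stage thermograms.
#' @export
process_cohort <- function(cohort, ...) {
  out <- lapply(cohort$records, function(r) {
    process_thermogram(r$sample, r$buffer, ...)
  })
  names(out) <- names(cohort$records)
  out
}
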