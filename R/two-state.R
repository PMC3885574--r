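#' Two-state excess heat capacity of a single denaturation transition
#'
#' Evaluates the excess specific heat capacity of a two-state
#' (native/denatured) protein unfolding transition at temperature `t`.
#' The van't Hoff enthalpy controls the sharpness of the transition and the
#' specific calorimetric enthalpy its total area, so that the curve
#' integrates to `dh_cal` (cal per gram of the component).
#'
#' The model is
#' \deqn{C_p^{ex}(T) = \Delta H_{cal} \frac{\Delta H_{vH}}{R T^2}
#'       \frac{K}{(1+K)^2}, \quad
#'       K = \exp\left[-\frac{\Delta H_{vH}}{R}
#'       \left(\frac{1}{T} - \frac{1}{T_m}\right)\right]}
#' with absolute temperatures and R = 1.987 cal/(mol K).
#'
#' @param t temperature(s) in degrees Celsius.
#' @param spec a [transition_spec()].
#' @return excess specific heat capacity, cal/(degC g), same length as `t`.
#' @examples
#' sp <- transition_spec("albumin", tm = 62.2, dh_vh = 1.5e5, dh_cal = 5.4,
#'                       mass_fraction = 1)
#' two_state_excess_heat_capacity(62.2, sp)
#' @export
two_state_excess_heat_capacity <- function(t, spec) {
  stop_if_not(is.numeric(t) && all(is.finite(t)),
              "temperature grid must be finite numeric")
  tk <- t + 273.15
  tmk <- spec$tm + 273.15
  k <- exp(-(spec$dh_vh / .R_GAS) * (1 / tk - 1 / tmk))
  spec$dh_cal * (spec$dh_vh / (.R_GAS * tk^2)) * k / (1 + k)^2
}

#' Specify one denaturation transition
#'
#' @param label component name (e.g. "albumin").
#' @param tm midpoint temperature, degC; must lie in (20, 110).
#' @param dh_vh van't Hoff enthalpy, cal/mol; > 0.
#' @param dh_cal specific calorimetric enthalpy, cal per gram of this
#'   component; > 0.
#' @param mass_fraction fraction of total protein mass carried by this
#'   component, in `[0, 1]`.
#' @return a `transition_spec` list.
#' @export
transition_spec <- function(label, tm, dh_vh, dh_cal, mass_fraction) {
  stop_if_not(tm > 20 && tm < 110, "tm must lie in (20, 110) degC")
  stop_if_not(dh_vh > 0, "dh_vh must be positive")
  stop_if_not(dh_cal > 0, "dh_cal must be positive")
  stop_if_not(mass_fraction >= 0 && mass_fraction <= 1,
              "mass_fraction must lie in [0, 1]")
  structure(list(label = label, tm = tm, dh_vh = dh_vh, dh_cal = dh_cal,
                 mass_fraction = mass_fraction),
            class = "transition_spec")
}

#' Specify a plasma protein mixture for thermogram simulation
#'
#' A mixture is a weighted superposition of two-state transitions plus an
#' instrumental linear baseline and additive Gaussian noise.  Disease is
#' modelled by two knobs: `albumin_shift` raises the midpoint of the primary
#' (albumin-like, ~62 degC) transition, and `redistribution` moves a fraction
#' of the primary transition's mass to the secondary (~70 degC) transition —
#' the thermal-stabilisation mechanism that produces a negative difference
#' lobe near 62 degC and positive lobes at higher temperature.
#'
#' @param transitions list of [transition_spec()]; mass fractions must sum
#'   to 1 (within 1e-9).
#' @param primary,secondary labels of the primary and secondary transitions.
#' @param albumin_shift degC added to the primary transition midpoint.
#' @param redistribution fraction of primary-transition mass moved to the
#'   secondary transition; in `[0, 1)`.
#' @param baseline_offset,baseline_slope linear instrumental baseline,
#'   cal/(degC g) and cal/(degC^2 g).
#' @param noise_sd additive Gaussian noise sd, cal/(degC g); >= 0.
#' @return a `mixture_spec` list.
#' @export
mixture_spec <- function(transitions, primary = "albumin",
                         secondary = "globulins",
                         albumin_shift = 0, redistribution = 0,
                         baseline_offset = 0, baseline_slope = 0,
                         noise_sd = 0) {
  stop_if_not(length(transitions) >= 1, "at least one transition required")
  fr <- vapply(transitions, function(x) x$mass_fraction, numeric(1))
  stop_if_not(abs(sum(fr) - 1) <= 1e-9, "mass fractions must sum to 1")
  stop_if_not(redistribution >= 0 && redistribution < 1,
              "redistribution must lie in [0, 1)")
  stop_if_not(noise_sd >= 0, "noise_sd must be non-negative")
  labs <- vapply(transitions, function(x) x$label, character(1))
  stop_if_not(primary %in% labs, "primary label not found among transitions")
  structure(list(transitions = transitions, primary = primary,
                 secondary = secondary, albumin_shift = albumin_shift,
                 redistribution = redistribution,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope, noise_sd = noise_sd),
            class = "mixture_spec")
}

## Apply the disease knobs: shift the primary midpoint and move mass from
## the primary to the secondary transition.  Returns a plain transition list.
effective_transitions <- function(mixture) {
  tr <- mixture$transitions
  labs <- vapply(tr, function(x) x$label, character(1))
  ip <- match(mixture$primary, labs)
  is <- match(mixture$secondary, labs)
  if (mixture$albumin_shift != 0) tr[[ip]]$tm <- tr[[ip]]$tm + mixture$albumin_shift
  r <- mixture$redistribution
  if (r > 0 && !is.na(is)) {
    moved <- r * tr[[ip]]$mass_fraction
    tr[[ip]]$mass_fraction <- tr[[ip]]$mass_fraction - moved
    tr[[is]]$mass_fraction <- tr[[is]]$mass_fraction + moved
  }
  tr
}

#' Noise-free specific excess heat capacity of a mixture
#'
#' The weighted superposition of the mixture's two-state transitions after
#' applying `albumin_shift` and `redistribution`, with no baseline or noise.
#'
#' @param mixture a [mixture_spec()].
#' @param grid temperature grid, degC.
#' @return cal/(degC g) values on `grid`.
#' @export
mixture_excess_heat_capacity <- function(mixture, grid) {
  tr <- effective_transitions(mixture)
  val <- numeric(length(grid))
  for (x in tr) {
    val <- val + x$mass_fraction * two_state_excess_heat_capacity(grid, x)
  }
  val
}

#' Default healthy-control plasma mixture
#'
#' Five transitions: a dominant albumin-like transition at 62.2 degC
#' carrying about 55% of the area, a globulin-like secondary transition at
#' 70 degC, and three minor shoulders between 51 and 83 degC.  The mass
#' fractions and enthalpies are calibrated so the processed control
#' thermogram has area near 4.94 cal/g, first-moment temperature near
#' 66.3 degC, peak maximum at 62.2 degC and a main/second transition
#' amplitude ratio near 2.2 — the published healthy-control profile values.
#'
#' @param albumin_shift,redistribution,noise_sd see [mixture_spec()].
#' @return a `mixture_spec`.
#' @export
control_mixture <- function(albumin_shift = 0, redistribution = 0,
                            noise_sd = 0.005) {
  transitions <- list(
    transition_spec("shoulder_low",  tm = 53.0, dh_vh = 1.20e5, dh_cal = 4.85,
                    mass_fraction = 0.02),
    transition_spec("albumin",       tm = 62.2, dh_vh = 1.64e5, dh_cal = 5.44,
                    mass_fraction = 0.50),
    transition_spec("globulins",     tm = 70.0, dh_vh = 1.20e5, dh_cal = 4.4286,
                    mass_fraction = 0.35),
    transition_spec("shoulder_mid",  tm = 75.5, dh_vh = 1.10e5, dh_cal = 7.857,
                    mass_fraction = 0.07),
    transition_spec("shoulder_high", tm = 81.5, dh_vh = 1.20e5, dh_cal = 4.05,
                    mass_fraction = 0.06)
  )
  mixture_spec(transitions, primary = "albumin", secondary = "globulins",
               albumin_shift = albumin_shift, redistribution = redistribution,
               noise_sd = noise_sd)
}

#' Default per-group disease effects for the five clinical groups
#'
#' Albumin midpoint shifts of 0/1.5/1.5/2.5/3.5 degC with monotonically
#' increasing mass redistribution from the primary to the secondary
#' transition, emulating the progressive thermogram change from healthy
#' control through LSIL, HSIL and Stage I to advanced Stage II-IV disease.
#'
#' @return data.frame with columns `group`, `albumin_shift`, `redistribution`.
#' @export
default_group_effects <- function() {
  data.frame(
    group = clinical_groups(),
    albumin_shift = c(0, 1.5, 1.5, 2.5, 3.5),
    redistribution = c(0, 0.02, 0.05, 0.15, 0.45),
    stringsAsFactors = FALSE
  )
}

#' The five clinical group labels
#'
#' Healthy controls, low-grade squamous intraepithelial lesions (CIN 1),
#' high-grade lesions (CIN 2-3), early invasive carcinoma (FIGO Stage I)
#' and advanced invasive carcinoma (FIGO Stage II-IV).
#'
#' @return character vector of length 5.
#' @export
clinical_groups <- function() {
  c("control", "LSIL", "HSIL", "StageI", "StageII_IV")
}

#' Default cohort group sizes
#'
#' The study breakdown: 4 controls, 3 LSIL (CIN 1), 29 HSIL (CIN 2, CIN 2-3
#' and CIN 3 pooled), 14 Stage I and 21 Stage II-IV.
#'
#' @return named integer vector.
#' @export
default_group_sizes <- function() {
  c(control = 4L, LSIL = 3L, HSIL = 29L, StageI = 14L, StageII_IV = 21L)
}

#' Simulate one plasma DSC scan with its matched buffer reference
#'
#' The sample scan is the mixture's specific excess heat capacity scaled by
#' the protein mass in the calorimeter cell, plus a linear instrumental
#' baseline and i.i.d. Gaussian noise; the buffer scan carries the same
#' baseline with independent noise.  Both are raw-stage thermogram records
#' in cal/degC, ready for the preprocessing pipeline.
#'
#' @param mixture a [mixture_spec()].
#' @param grid uniform temperature grid covering at least 45-90 degC;
#'   default 20-110 degC at 0.1 degC (the instrument scan range).
#' @param seed integer seed for the noise stream.
#' @param sample_id sample identifier.
#' @param group clinical group label or `NA`.
#' @param protein_conc total protein concentration in the cell, g/L.
#' @param cell_volume_uL calorimeter cell volume, microlitres (default the
#'   135 uL thermal sensing volume).
#' @return list with elements `sample` and `buffer` (raw [thermogram()]
#'   records) and `protein_conc`.
#' @export
simulate_plasma_thermogram <- function(mixture,
                                       grid = seq(20, 110, by = 0.1),
                                       seed = 1L,
                                       sample_id = "S1",
                                       group = NA_character_,
                                       protein_conc = 2.8,
                                       cell_volume_uL = 135) {
  stop_if_not(all(diff(grid) > 0), "temperature grid must be strictly increasing")
  steps <- diff(grid)
  stop_if_not(max(abs(steps - steps[1])) < 1e-8, "temperature grid must be uniform")
  stop_if_not(min(grid) <= 45 && max(grid) >= 90,
              "grid must cover the 45-90 degC denaturation window")
  mass_g <- protein_conc * cell_volume_uL * 1e-6  # g of protein in the cell
  specific <- mixture_excess_heat_capacity(mixture, grid)
  baseline <- (mixture$baseline_offset + mixture$baseline_slope * grid) * mass_g
  with_seed(seed, {
    noise_sample <- stats::rnorm(length(grid), sd = mixture$noise_sd * mass_g)
    noise_buffer <- stats::rnorm(length(grid), sd = mixture$noise_sd * mass_g)
    list(
      sample = thermogram(sample_id, grid, specific * mass_g + baseline + noise_sample,
                          stage = "raw", group = group,
                          protein_conc = protein_conc),
      buffer = thermogram(paste0(sample_id, "_buffer"), grid,
                          baseline + noise_buffer, stage = "raw",
                          group = group, protein_conc = protein_conc),
      protein_conc = protein_conc
    )
  })
}

#' Specify one clinical group of a simulated cohort
#'
#' @param group_label one of [clinical_groups()].
#' @param n_samples number of samples; >= 1.
#' @param mixture a [mixture_spec()] for the group.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(group_label, n_samples, mixture) {
  stop_if_not(group_label %in% clinical_groups(),
              "group_label must be one of the five clinical groups")
  stop_if_not(is.numeric(n_samples) && n_samples >= 1,
              "n_samples must be at least 1")
  structure(list(group_label = group_label, n_samples = as.integer(n_samples),
                 mixture = mixture),
            class = "cohort_spec")
}

#' Default cohort specification
#'
#' One [cohort_spec()] per clinical group using [control_mixture()] modified
#' by [default_group_effects()], with the study group sizes (or a common
#' `n_per_group`).
#'
#' @param n_per_group optional common group size; default the study sizes.
#' @param shifts,redistributions optional length-5 overrides of the per-group
#'   albumin shift (degC) and redistribution fraction.
#' @param noise_sd per-scan noise sd, cal/(degC g).
#' @return list of `cohort_spec`.
#' @export
default_cohort_specs <- function(n_per_group = NULL, shifts = NULL,
                                 redistributions = NULL, noise_sd = 0.005) {
  eff <- default_group_effects()
  if (!is.null(shifts)) eff$albumin_shift <- shifts
  if (!is.null(redistributions)) eff$redistribution <- redistributions
  sizes <- if (is.null(n_per_group)) default_group_sizes()
           else stats::setNames(rep(as.integer(n_per_group), 5), clinical_groups())
  lapply(seq_len(nrow(eff)), function(i) {
    cohort_spec(eff$group[i], sizes[[eff$group[i]]],
                control_mixture(albumin_shift = eff$albumin_shift[i],
                                redistribution = eff$redistribution[i],
                                noise_sd = noise_sd))
  })
}

#' Simulate a full thermogram cohort
#'
#' Deterministic given `seed`: each sample draws its own substream seed from
#' the master seed, so generated cohorts are reproducible under subsetting.
#' Per-sample biological variability jitters the group's albumin shift,
#' redistribution and protein concentration; the instrumental baseline is
#' drawn per scan from small uniform ranges.
#'
#' @param specs list of [cohort_spec()] with unique group labels.
#' @param seed master integer seed.
#' @param grid temperature grid (see [simulate_plasma_thermogram()]).
#' @param shift_jitter_sd per-sample sd of the albumin shift, degC.
#' @param redist_jitter_sd per-sample sd of the redistribution fraction.
#' @param conc_mean,conc_sd per-sample protein concentration distribution, g/L.
#' @param baseline_offset_range,baseline_slope_range uniform ranges for the
#'   per-scan instrumental baseline, cal/(degC g) and cal/(degC^2 g).
#' @return list with `manifest` (data.frame: sample_id, group, protein_conc)
#'   and `records` (named list of `list(sample=, buffer=)` raw thermograms).
#' @export
simulate_cohort <- function(specs, seed = 1L,
                            grid = seq(20, 110, by = 0.1),
                            shift_jitter_sd = 0.2,
                            redist_jitter_sd = 0.015,
                            conc_mean = 2.8, conc_sd = 0.2,
                            baseline_offset_range = c(-0.05, 0.05),
                            baseline_slope_range = c(-5e-4, 5e-4)) {
  labs <- vapply(specs, function(s) s$group_label, character(1))
  stop_if_not(!anyDuplicated(labs), "duplicate group labels in cohort specs")
  manifest <- list()
  records <- list()
  idx <- 0L
  for (s in specs) {
    for (j in seq_len(s$n_samples)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", s$group_label, j)
      sseed <- derive_seed(seed, idx)
      draws <- with_seed(sseed, list(
        shift = stats::rnorm(1, s$mixture$albumin_shift, shift_jitter_sd),
        redist = stats::rnorm(1, s$mixture$redistribution, redist_jitter_sd),
        conc = stats::rnorm(1, conc_mean, conc_sd),
        b0 = stats::runif(1, baseline_offset_range[1], baseline_offset_range[2]),
        b1 = stats::runif(1, baseline_slope_range[1], baseline_slope_range[2])
      ))
      mix <- s$mixture
      mix$albumin_shift <- draws$shift
      mix$redistribution <- min(max(draws$redist, 0), 0.95)
      mix$baseline_offset <- draws$b0
      mix$baseline_slope <- draws$b1
      conc <- max(draws$conc, 0.5)
      records[[sid]] <- simulate_plasma_thermogram(
        mix, grid = grid, seed = derive_seed(sseed, 1L), sample_id = sid,
        group = s$group_label, protein_conc = conc
      )
      manifest[[idx]] <- data.frame(sample_id = sid, group = s$group_label,
                                    protein_conc = conc,
                                    stringsAsFactors = FALSE)
    }
  }
  list(manifest = do.call(rbind, manifest), records = records)
}
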