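## Synthetic MALDI-TOF peptide spectra: Gaussian peaks at a planted panel of
## peptide masses with group-dependent means, nuisance peaks common to all
## groups, a decaying chemical-matrix baseline and additive noise.

#' The MS study group labels
#'
#' Healthy controls, CIN 2 lesions and invasive cervical carcinoma.
#'
#' @return character vector of length 3.
#' @export
ms_groups <- function() c("Control", "CIN 2", "Cerv Ca")

## Convert an abundance pattern string (the classifier grammar) into group
## mean intensities on a base scale: absent groups 0; each ">" step divides
## the mean by fold_step; "=" keeps it.
pattern_to_means <- function(pattern, groups = ms_groups(), base = 100,
                             fold_step = 3) {
  means <- stats::setNames(rep(NA_real_, length(groups)), groups)
  parts <- trimws(strsplit(pattern, ";")[[1]])
  absent <- sub("^Absent in ", "", parts[startsWith(parts, "Absent in")])
  means[absent] <- 0
  chain <- parts[!startsWith(parts, "Absent in")]
  if (length(chain)) {
    chain <- chain[length(chain)]  # the ordering chain is the last clause
    toks <- trimws(strsplit(chain, "(?<=.)(?=[>=])|(?<=[>=])", perl = TRUE)[[1]])
    level <- base
    prev_op <- NULL
    for (tok in toks) {
      if (tok %in% c(">", "=")) {
        prev_op <- tok
      } else {
        if (!is.null(prev_op) && prev_op == ">") level <- level / fold_step
        means[tok] <- level
        prev_op <- NULL
      }
    }
  }
  means[is.na(means)] <- 0
  means
}

#' Construct one planted peptide panel entry
#'
#' @param mz peptide mass-to-charge, within 900-3000 Th.
#' @param pattern group abundance pattern string in the classifier grammar,
#'   e.g. `"Absent in Control; Cerv Ca = CIN 2"`.
#' @param fraction sample fraction the peptide belongs to (FX1-FX4 plasma
#'   fractions or urine); metadata only.
#' @param base peak amplitude of the most abundant group.
#' @param groups group labels.
#' @return a `peptide_panel_entry` list with fields `mz`, `group_means`,
#'   `pattern`, `fraction`.
#' @export
peptide_panel_entry <- function(mz, pattern, fraction = "FX2", base = 100,
                                groups = ms_groups()) {
  stop_if_not(mz >= 900 && mz <= 3000, "panel mass must lie in 900-3000 Th")
  means <- pattern_to_means(pattern, groups = groups, base = base)
  stop_if_not(all(means >= 0), "intensities must be non-negative")
  structure(list(mz = mz, group_means = means, pattern = pattern,
                 fraction = fraction),
            class = "peptide_panel_entry")
}

#' Default panel of 15 differentially abundant peptides
#'
#' The 15 peptide masses (900-3000 m/z) reported as differentially abundant
#' between control, CIN 2 and cervical-cancer samples across the plasma
#' fractions and urine, each with its group abundance pattern.  Two
#' control-only peptides are expressed in the canonical grammar
#' (`"Absent in Cerv Ca; Absent in CIN 2; Control"`).
#'
#' @return list of [peptide_panel_entry()].
#' @export
default_peptide_panel <- function() {
  ctrl_only <- "Absent in Cerv Ca; Absent in CIN 2; Control"
  entries <- list(
    list(904.53,  "FX3",   "Absent in Control; Cerv Ca = CIN 2"),
    list(1097.49, "urine", "CIN 2 = Control>Cerv Ca"),
    list(1126.503,"urine", "CIN 2>Cerv Ca>Control"),
    list(1192.67, "FX3",   "Absent in Control; Cerv Ca = CIN 2"),
    list(1236.56, "urine", "CIN 2>Control>Cerv Ca"),
    list(1425.65, "urine", "Absent in Control; CIN 2>Cerv Ca"),
    list(1524.71, "urine", "CIN 2>Cerv Ca = Control"),
    list(1530.91, "FX1",   "Absent in CIN 2; Cerv Ca = Control"),
    list(1587.97, "urine", "CIN 2>Control>Cerv Ca"),
    list(1746.78, "FX1",   "Control>Cerv Ca = CIN 2"),
    list(1943.93, "FX2",   ctrl_only),
    list(2080.98, "FX2",   ctrl_only),
    list(2209.06, "FX2",   "Control>Cerv Ca = CIN 2"),
    list(2228.05, "FX2",   "Absent in CIN 2; Control>Cerv Ca"),
    list(2271.13, "FX2",   "Control>Cerv Ca = CIN 2")
  )
  lapply(entries, function(e) peptide_panel_entry(e[[1]], e[[3]], e[[2]]))
}

#' Simulate a MALDI-TOF cohort of peptide spectra
#'
#' Each spectrum is a raster of intensities on a uniform m/z grid:
#' Gaussian peaks at the planted panel masses (group mean times a lognormal
#' per-sample biological factor times a lognormal per-spot factor), nuisance
#' peaks at random masses with means common to all groups, a smooth
#' exponentially decaying chemical baseline, and additive Gaussian noise
#' clipped at zero.  Samples are spotted in `replicates` spots.
#'
#' @param panel list of [peptide_panel_entry()]; non-empty.
#' @param groups group labels (default [ms_groups()]).
#' @param n_per_group samples per group.
#' @param replicates spots per sample (default 3).
#' @param seed master integer seed.
#' @param fraction fraction label attached to all spectra.
#' @param n_nuisance number of nuisance peptide peaks common to all groups.
#' @param mz_range,mz_step raster range and step, Th.
#' @param peak_sd Gaussian peak width (sd), Th.
#' @param bio_sdlog,spot_sdlog lognormal sd (log scale) of the per-sample
#'   biological factor and the per-spot factor.
#' @param baseline_amp,baseline_scale chemical baseline amplitude and decay
#'   length: `baseline_amp * exp(-(mz - mz_range[1]) / baseline_scale)`.
#' @param noise_sd additive noise sd per raster point.
#' @return list with `spectra` (list of `spectrum` objects: sample_id,
#'   group, fraction, replicate, mz, intensity), `sample_sheet` (data.frame)
#'   and `nuisance_mz` (the nuisance peak masses).
#' @export
simulate_maldi_cohort <- function(panel = default_peptide_panel(),
                                  groups = ms_groups(),
                                  n_per_group = 4, replicates = 3,
                                  seed = 1L, fraction = "FX2",
                                  n_nuisance = 200,
                                  mz_range = c(900, 3000), mz_step = 0.1,
                                  peak_sd = 0.3,
                                  bio_sdlog = 0.2, spot_sdlog = 0.15,
                                  baseline_amp = 20, baseline_scale = 400,
                                  noise_sd = 1.0) {
  stop_if_not(length(panel) >= 1, "peptide panel must be non-empty")
  stop_if_not(replicates >= 1, "replicates must be at least 1")
  panel_mz <- vapply(panel, function(e) e$mz, numeric(1))
  stop_if_not(all(panel_mz >= mz_range[1] & panel_mz <= mz_range[2]),
              "panel masses must lie within the m/z range")
  mz <- seq(mz_range[1], mz_range[2], by = mz_step)
  baseline <- baseline_amp * exp(-(mz - mz_range[1]) / baseline_scale)

  ## Nuisance panel: identical mean structure in every group, masses kept
  ## at least 2 Th away from the planted masses.
  nuis <- with_seed(derive_seed(seed, 0L), {
    cand <- stats::runif(4 * n_nuisance, mz_range[1] + 5, mz_range[2] - 5)
    keep <- vapply(cand, function(m) min(abs(m - panel_mz)) > 2, logical(1))
    m <- cand[keep][seq_len(n_nuisance)]
    list(mz = m, mean = stats::rlnorm(n_nuisance, meanlog = log(50), sdlog = 1))
  })

  add_peak <- function(intensity, center, amp) {
    if (amp <= 0) return(intensity)
    lo <- max(1L, floor((center - 5 * peak_sd - mz_range[1]) / mz_step) + 1L)
    hi <- min(length(mz), ceiling((center + 5 * peak_sd - mz_range[1]) / mz_step) + 1L)
    idx <- lo:hi
    intensity[idx] <- intensity[idx] +
      amp * exp(-((mz[idx] - center)^2) / (2 * peak_sd^2))
    intensity
  }

  spectra <- list()
  sheet <- list()
  sidx <- 0L
  for (g in groups) {
    for (j in seq_len(n_per_group)) {
      sidx <- sidx + 1L
      sid <- sprintf("%s_%02d", gsub("\\s+", "", g), j)
      sseed <- derive_seed(seed, sidx)
      ## Per-sample biological factors for planted and nuisance peaks.
      bio <- with_seed(sseed, list(
        panel = stats::rlnorm(length(panel), sdlog = bio_sdlog),
        nuis = stats::rlnorm(n_nuisance, sdlog = bio_sdlog)
      ))
      for (rep_i in seq_len(replicates)) {
        rseed <- derive_seed(sseed, rep_i)
        intensity <- with_seed(rseed, {
          spot_panel <- stats::rlnorm(length(panel), sdlog = spot_sdlog)
          spot_nuis <- stats::rlnorm(n_nuisance, sdlog = spot_sdlog)
          y <- baseline + stats::rnorm(length(mz), sd = noise_sd)
          for (k in seq_along(panel)) {
            amp <- panel[[k]]$group_means[[g]] * bio$panel[k] * spot_panel[k]
            y <- add_peak(y, panel[[k]]$mz, amp)
          }
          for (k in seq_len(n_nuisance)) {
            amp <- nuis$mean[k] * bio$nuis[k] * spot_nuis[k]
            y <- add_peak(y, nuis$mz[k], amp)
          }
          pmax(y, 0)
        })
        spectra[[length(spectra) + 1L]] <- structure(
          list(sample_id = sid, group = g, fraction = fraction,
               replicate = rep_i, mz = mz, intensity = intensity),
          class = "spectrum"
        )
      }
      sheet[[sidx]] <- data.frame(sample_id = sid, group = g,
                                  fraction = fraction,
                                  stringsAsFactors = FALSE)
    }
  }
  list(spectra = spectra, sample_sheet = do.call(rbind, sheet),
       nuisance_mz = nuis$mz)
}
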