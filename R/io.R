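## Plain-text interchange: two-column thermogram TSVs with a cohort
## manifest, and three-column MALDI peak-list TSVs with a sample sheet.

#' Write a thermogram to a two-column TSV
#'
#' Columns `temperature_C` and `signal`.
#'
#' @param scan a [thermogram()].
#' @param path output file.
#' @export
write_thermogram_tsv <- function(scan, path) {
  utils::write.table(
    data.frame(temperature_C = scan$temperatures, signal = scan$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
}

#' Read a thermogram from a two-column TSV
#'
#' @param path input file with columns `temperature_C`, `signal`.
#' @param sample_id,stage,group,protein_conc record metadata.
#' @return a [thermogram()].
#' @export
read_thermogram_tsv <- function(path, sample_id = basename(path),
                                stage = "raw", group = NA_character_,
                                protein_conc = NA_real_) {
  d <- utils::read.delim(path)
  thermogram(sample_id, d$temperature_C, d$signal, stage = stage,
             group = group, protein_conc = protein_conc)
}

#' Write a simulated cohort to disk
#'
#' One sample TSV and one buffer TSV per sample plus a manifest TSV with
#' columns sample_id, group, sample_file, buffer_file, protein_conc_g_per_L.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$sample_file <- paste0(man$sample_id, "_sample.tsv")
  man$buffer_file <- paste0(man$sample_id, "_buffer.tsv")
  names(man)[names(man) == "protein_conc"] <- "protein_conc_g_per_L"
  for (i in seq_len(nrow(man))) {
    rec <- cohort$records[[man$sample_id[i]]]
    write_thermogram_tsv(rec$sample, file.path(dir, man$sample_file[i]))
    write_thermogram_tsv(rec$buffer, file.path(dir, man$buffer_file[i]))
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(manifest_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest TSV.
#' @return list with `manifest` and `records`, as from [simulate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.delim(manifest_path)
  dir <- dirname(manifest_path)
  records <- lapply(seq_len(nrow(man)), function(i) {
    list(
      sample = read_thermogram_tsv(file.path(dir, man$sample_file[i]),
                                   sample_id = man$sample_id[i],
                                   group = man$group[i],
                                   protein_conc = man$protein_conc_g_per_L[i]),
      buffer = read_thermogram_tsv(file.path(dir, man$buffer_file[i]),
                                   sample_id = paste0(man$sample_id[i], "_buffer"),
                                   group = man$group[i],
                                   protein_conc = man$protein_conc_g_per_L[i])
    )
  })
  names(records) <- man$sample_id
  manifest <- data.frame(sample_id = man$sample_id, group = man$group,
                         protein_conc = man$protein_conc_g_per_L,
                         stringsAsFactors = FALSE)
  list(manifest = manifest, records = records)
}

#' Write MALDI spectra as three-column peak-list TSVs
#'
#' One file `<sample>_<fraction>.tsv` per sample-fraction with columns
#' mz, intensity, replicate, plus a sample sheet TSV.
#'
#' @param maldi output of [simulate_maldi_cohort()].
#' @param dir output directory.
#' @return the sample sheet path, invisibly.
#' @export
write_maldi_cohort <- function(maldi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(maldi$spectra, function(s) s$sample_id, character(1))
  sheet <- maldi$sample_sheet
  sheet$file <- paste0(sheet$sample_id, "_", sheet$fraction, ".tsv")
  for (i in seq_len(nrow(sheet))) {
    specs <- maldi$spectra[ids == sheet$sample_id[i]]
    d <- do.call(rbind, lapply(specs, function(s) {
      data.frame(mz = s$mz, intensity = s$intensity, replicate = s$replicate)
    }))
    utils::write.table(d, file.path(dir, sheet$file[i]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(sheet_path)
}

#' Read MALDI spectra written by [write_maldi_cohort()]
#'
#' @param sheet_path path to the sample sheet TSV.
#' @return list with `spectra` and `sample_sheet`.
#' @export
read_maldi_cohort <- function(sheet_path) {
  sheet <- utils::read.delim(sheet_path)
  dir <- dirname(sheet_path)
  spectra <- list()
  for (i in seq_len(nrow(sheet))) {
    d <- utils::read.delim(file.path(dir, sheet$file[i]))
    for (r in sort(unique(d$replicate))) {
      dr <- d[d$replicate == r, ]
      spectra[[length(spectra) + 1L]] <- structure(
        list(sample_id = sheet$sample_id[i], group = sheet$group[i],
             fraction = sheet$fraction[i], replicate = r,
             mz = dr$mz, intensity = dr$intensity),
        class = "spectrum"
      )
    }
  }
  list(spectra = spectra,
       sample_sheet = sheet[, c("sample_id", "group", "fraction")])
}
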