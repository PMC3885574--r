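Package: dscMS
Title: Plasma Thermogram and MALDI-TOF Peptidome Analysis of Cervical Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing differential scanning calorimetry (DSC)
    thermograms of blood plasma and MALDI-TOF peptidome spectra across
    clinical groups. Implements thermogram preprocessing (buffer reference
    subtraction, protein-concentration normalisation, linear baseline
    correction, truncation to the 45-90 degree denaturation window), eight
    thermogram shape metrics including the first-moment temperature,
    group-level mean/SD and difference curves, box summaries and pairwise
    Mann-Whitney U tests; and a peptidome pipeline with spectral baseline
    subtraction, m/z binning, replicate averaging, mean-centred or Pareto
    scaling, PCA and discriminant PCA, differential t-tests and group
    abundance pattern calls. Includes synthetic-data generators that emulate
    multi-transition plasma denaturation profiles and MALDI-TOF peptide
    spectra so the full workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
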