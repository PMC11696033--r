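Package: diadeconv
Title: Spectrum-Centric Deconvolution of diaPASEF Data into Pseudo-MS/MS Spectra
Version: 0.1.0
Authors@R:
    person("diadeconv", "developers", email = "diadeconv@example.org",
           role = c("aut", "cre"))
Description: Detects precursor and fragment ion features in three dimensions
    (m/z, retention time, ion mobility) from diaPASEF-style data-independent
    acquisition runs and assembles precursor-resolved pseudo-MS/MS spectra
    written as DDA-like mzML. Includes a synthetic diaPASEF run simulator with
    ground-truth manifests, sparse 2D (m/z x 1/K0) feature detection with
    Gaussian fitting, extracted-ion-chromatogram tracing with Savitzky-Golay /
    Z-score segmentation of elongated peaks, averagine-based isotope grouping
    and charge assignment, Pearson-correlation precursor-fragment clustering,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
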