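Package: sipquant
Title: Single-Cell Stable Isotope Probing Quantification for Methanotroph
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification chain for single-cell stable isotope probing (SIP)
    of methane-oxidizing bacteria in lake water incubations. Accumulates and
    drift-corrects multi-mass secondary ion (nanoSIMS) count images, measures
    region-of-interest 13C/12C ratios and atom percent with Poisson counting
    statistics, converts FISH-derived filament morphometry into biovolumes and
    cell densities, upscales 13C atom-percent excess to per-cell and
    population-level methane-carbon uptake rates, computes bulk methane
    oxidation rates from 13C-DIC tracer time series and dissolved methane from
    headspace equilibration, and screens oligonucleotide FISH probes against
    16S rRNA targets by minimal mismatch counting. Includes seed-deterministic
    generators for synthetic ion-image fields, tracer series and probe targets
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
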