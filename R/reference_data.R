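#' Previously reported lake methanotroph population measurements
#'
#' Loads the bundled table of previously reported population-level
#' measurements for filamentous (*Crenothrix*-type) and unicellular
#' gamma-proteobacterial methanotrophs from stable-isotope-probing
#' incubations of two stratified Swiss lakes: per-population 13C at%
#' (mean ± s.d., n), average biovolume, per-cell methane-carbon uptake,
#' cell counts, total population biovolume and population uptake, together
#' with the labeling percentage and incubation time used. Values are as
#' printed in the original report (2--4 significant figures); they serve as
#' inputs for validating the upscaling arithmetic of
#' [build_population_table()], [population_uptake()] and
#' [total_population_biovolume()].
#'
#' @return data frame, one row per population.
#' @export
lake_populations <- function() {
  path <- system.file("extdata", "lake_populations.csv", package = "sipquant",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
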