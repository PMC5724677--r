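#' Community-specific taurine release rates from two ocean cruises
#'
#' Per-chamber taurine release-rate observations for mixed crustacean
#' mesozooplankton assemblages from the Gulf of Alaska (GoA; large
#' copepod-amphipod assemblages, six stations, 24 h incubations) and the
#' North Atlantic (NA; small mixed copepod community, one station,
#' triplicate 24 h incubations). Each row carries the regression window
#' (`t_c_h` of `t_i_h`), the fit quality (`r_squared`), the number of
#' incubated individuals (`n_total`), the per-individual and per-carbon
#' release rates, and the percentage composition of the dominant taxa
#' (amphipods *Themisto* and *Vibilia* and the copepod *Neocalanus
#' cristatus* in the GoA; *Acartia*, *Calanus* and *Centropages* in the NA).
#'
#' @return Tibble with one row per incubation chamber.
#' @seealso [species_release_rates()], [summarize_rates()]
#' @export
community_release_rates <- function() {
  read_extdata("community_release_rates.csv")
}

#' Species-specific taurine release rates from single-species incubations
#'
#' Triplicate 8 h incubations of four North Atlantic copepod taxa
#' (*Calanus*, *Acartia*, *Clausocalanus*, *Centropages*), with regression
#' window, fit quality and normalised release rates per chamber.
#'
#' @return Tibble with one row per incubation chamber.
#' @export
species_release_rates <- function() {
  read_extdata("species_release_rates.csv")
}

#' Regional inputs for bulk release and turnover estimates
#'
#' Mean community per-individual release rates (nmol individual^-1 d^-1),
#' epipelagic copepod abundance ranges (individuals L^-1) and mean ambient
#' dissolved free taurine concentrations (upper 100 m, nM) for the Gulf of
#' Alaska and the North Atlantic. The abundance ranges are reconstructed
#' from published bulk-rate ranges divided by the per-individual rate
#' (literature abundance compilations are not redistributed here); treat
#' them as a documented example configuration, not primary data.
#'
#' @return Tibble with one row per region.
#' @seealso [turnover_table()]
#' @export
turnover_inputs <- function() {
  read_extdata("turnover_inputs.csv")
}

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tauflux", mustWork = TRUE)
  # "NA" is a region label (North Atlantic), never a missing value; missing
  # cells are empty in the shipped tables
  tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "")
  )
}
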