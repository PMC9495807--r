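# Published summary tables from a 25-station copepod survey conducted in the
# waters northeast of Taiwan during the prevailing northeast monsoon (autumn).
# The raw station-by-taxon matrix of that survey was not deposited; these
# per-group and per-taxon summaries are what the package's verification
# utilities (consistency solver, dominance arithmetic) and the synthetic
# generator defaults are built on.

survey_file <- function(name) {
  path <- system.file("extdata", name, package = "copindval")
  if (path == "") stop("shipped data file not found: ", name)
  path
}

#' Published indicator-species table (group-mean abundance and IndVal)
#'
#' Per indicator taxon and water-mass group: printed mean abundance
#' (ind m^-3) and IndVal (%).  Absent entries (taxon not recorded in the
#' group) are NA.
#'
#' @return data.frame with columns `species`, `abundance_A`, `indval_A`,
#'   `abundance_B`, `indval_B`, `abundance_C`, `indval_C`.
#' @export
survey_indval <- function() {
  read.csv(survey_file("ne_taiwan_indval.csv"), check.names = FALSE,
           stringsAsFactors = FALSE)
}

#' Published dominance table (MA, RA, OR of the dominant taxa)
#' @return data.frame with columns `taxon`, `MA`, `RA`, `OR`.
#' @export
survey_dominance <- function() {
  read.csv(survey_file("ne_taiwan_dominance.csv"), stringsAsFactors = FALSE)
}

#' Published order-level composition (species counts and mean abundances)
#' @return data.frame with columns `order`, `n_species` (NA where the survey
#'   printed only a combined share), `mean_abundance`, `mean_abundance_sd`.
#' @export
survey_order_composition <- function() {
  read.csv(survey_file("ne_taiwan_order_composition.csv"),
           stringsAsFactors = FALSE)
}

#' Published per-group hydrographic profiles (mean and SD)
#' @return data.frame per group A/B/C: temperature, salinity, dissolved
#'   oxygen and pH means and SDs.
#' @export
survey_env_profiles <- function() {
  read.csv(survey_file("ne_taiwan_env_groups.csv"), stringsAsFactors = FALSE)
}

#' Published survey-level summary quantities
#' @return named numeric vector (station count, species counts, total mean
#'   abundance and its SD, station-total range, per-group abundance
#'   means/SDs).
#' @export
survey_summary <- function() {
  df <- read.csv(survey_file("ne_taiwan_survey.csv"), stringsAsFactors = FALSE)
  setNames(df$value, df$key)
}
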