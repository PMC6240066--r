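# Packaged lookup tables. All are editable CSVs under inst/extdata; each
# loader accepts a user-supplied path so local species lists can replace the
# packaged synthetic stand-ins (the shipped species parameters are plausible
# but synthetic values, flagged by filename).

.read_lookup <- function(file, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", file, package = "reefregimes",
                        mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Fish species lookup: length-weight parameters and functional groups
#'
#' One row per species: family, trophic label, one of the five fish
#' functional groups (browsers, grazers, scrapers, predators, secondary),
#' allometric length-weight parameters \code{a} (g cm^-b) and \code{b}, a
#' typical total length (cm) used by the synthetic survey generator, and a
#' schooling flag. The packaged table is a synthetic stand-in.
#'
#' @param path Optional path to a replacement CSV with the same columns.
#' @return data.frame.
#' @export
species_lookup <- function(path = NULL)
  .read_lookup("species_lookup_synthetic.csv", path)

#' Species excluded from biomass calculations
#'
#' Species whose life history makes visual-survey counts unreliable (cryptic,
#' nocturnal, pelagic schooling) plus manta rays; removed before biomass
#' aggregation.
#'
#' @param path Optional path to a replacement CSV (columns species, reason).
#' @return data.frame.
#' @export
exclusion_list <- function(path = NULL)
  .read_lookup("exclusions_synthetic.csv", path)

#' Benthic category to functional-group lookup
#'
#' Maps raw benthic survey categories onto the five cover groups: coral,
#' macroalgae, turf, crustose coralline algae (cca), other cover.
#'
#' @param path Optional path to a replacement CSV.
#' @return data.frame with columns category, functional_group.
#' @export
benthic_lookup <- function(path = NULL)
  .read_lookup("benthic_lookup.csv", path)

#' Coral species life-history trait lookup
#'
#' Classifies coral species as competitive, stress-tolerant, generalist or
#' weedy for regime composition summaries. The packaged table is a synthetic
#' stand-in covering common Hawaiian taxa.
#'
#' @param path Optional path to a replacement CSV.
#' @return data.frame with columns species, trait_class.
#' @export
coral_trait_lookup <- function(path = NULL)
  .read_lookup("coral_traits_synthetic.csv", path)
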