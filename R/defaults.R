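# Packaged fixture-scale lexicons. These are small curated tables for
# demonstration, testing and synthesis — not a rebuild of any large
# multi-source food database.

#' Packaged fixture food lexicon
#'
#' About fifty common foods with per-100 g nutrients (kcal, grams) and
#' category tags, including multiword entries ("sweet potato",
#' "orange juice").
#'
#' @return A food lexicon (`caloscope_lexicon`).
#' @export
default_food_lexicon <- function() {
  load_food_lexicon(system.file("extdata", "food_lexicon.csv",
                                package = "caloscope", mustWork = TRUE))
}

#' Packaged fixture activity lexicon
#'
#' Common activities with kcal burned per mention at the 80.7 kg reference
#' body weight.
#'
#' @return An activity lexicon (`caloscope_lexicon`).
#' @export
default_activity_lexicon <- function() {
  load_activity_lexicon(system.file("extdata", "activity_lexicon.csv",
                                    package = "caloscope", mustWork = TRUE))
}

#' Canadian provincial population shares
#'
#' Percentage population shares used for population-share summaries: Ontario
#' 38.3, Quebec 23.2, rest of Canada 38.5 (2016 census shares).
#'
#' @return Named numeric vector (percent, sums to 100).
#' @export
canada_population_shares <- function() {
  df <- utils::read.csv(system.file("extdata", "population_shares_ca.csv",
                                    package = "caloscope", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  stats::setNames(df$population, df$region)
}
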