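# The threatened forest bird pool behind the richness variable: species
# listed under the EU Birds Directive Annex I or the European Red List that
# are associated with forest habitat, plus locally distributed subspecies.

#' Threatened forest bird species pool
#'
#' The candidate pool of 27 threatened forest bird species and 9 subspecies
#' with local distributions. Three of the 27 species were never observed in
#' the 2008-2012 reporting period (Scottish crossbill, Azores bullfinch,
#' Krueper's nuthatch), leaving 24 species to count richness over.
#'
#' @return tibble of `common_name`, `scientific_name`, `rank`
#'   (`"species"`/`"subspecies"`), `observed`.
#' @export
threatened_forest_birds <- function() {
  species <- tibble::tribble(
    ~common_name, ~scientific_name, ~observed,
    "Arctic warbler", "Phylloscopus borealis", TRUE,
    "Black woodpecker", "Dryocopus martius", TRUE,
    "Brambling", "Fringilla montifringilla", TRUE,
    "Collared flycatcher", "Ficedula albicollis", TRUE,
    "Corsican nuthatch", "Sitta whiteheadi", TRUE,
    "Eurasian eagle-owl", "Bubo bubo", TRUE,
    "Eurasian pygmy owl", "Glaucidium passerinum", TRUE,
    "Eurasian three-toed woodpecker", "Picoides tridactylus", TRUE,
    "European honey buzzard", "Pernis apivorus", TRUE,
    "Fieldfare", "Turdus pilaris", TRUE,
    "Great grey owl", "Strix nebulosa", TRUE,
    "Grey-headed woodpecker", "Picus canus", TRUE,
    "Hazel grouse", "Bonasa bonasia", TRUE,
    "Middle spotted woodpecker", "Dendrocopos medius", TRUE,
    "Northern hawk-owl", "Surnia ulula", TRUE,
    "Red kite", "Milvus milvus", TRUE,
    "Red-breasted flycatcher", "Ficedula parva", TRUE,
    "Redwing", "Turdus iliacus", TRUE,
    "Rustic bunting", "Emberiza rustica", TRUE,
    "Semicollared flycatcher", "Ficedula semitorquata", TRUE,
    "Tengmalm's owl", "Aegolius funereus", TRUE,
    "Ural owl", "Strix uralensis", TRUE,
    "Western capercaillie", "Tetrao urogallus", TRUE,
    "White-backed woodpecker", "Dendrocopos leucotos", TRUE,
    "Scottish crossbill", "Loxia scotica", FALSE,
    "Azores bullfinch", "Pyrrhula murina", FALSE,
    "Krueper's nuthatch", "Sitta krueperi", FALSE
  )
  species$rank <- "species"
  subspecies <- tibble::tribble(
    ~common_name, ~scientific_name, ~observed,
    "Coal tit (Cyprus)", "Parus ater cypriotes", TRUE,
    "Eurasian sparrowhawk (Madeira)", "Accipiter nisus granti", TRUE,
    "Fair Isle wren", "Troglodytes fridariensis", TRUE,
    "Gran Canaria blue chaffinch", "Fringilla teydea polatzeki", TRUE,
    "Great spotted woodpecker (Tenerife)",
    "Dendrocopos major canariensis", TRUE,
    "Great spotted woodpecker (Gran Canaria)",
    "Dendrocopos major thanneri", TRUE,
    "Northern goshawk (Corsica-Sardinia)",
    "Accipiter gentilis arrigonii", TRUE,
    "Short-toed tree-creeper (Cyprus)",
    "Certhia brachydactyla dorotheae", TRUE,
    "Tenerife blue chaffinch", "Fringilla teydea teydea", TRUE
  )
  subspecies$rank <- "subspecies"
  dplyr::bind_rows(species, subspecies)[, c("common_name",
                                            "scientific_name", "rank",
                                            "observed")]
}

#' Drop species never observed in the reporting period
#'
#' @param species_pool tibble as from [threatened_forest_birds()].
#' @return the observed subset (24 species and 9 subspecies for the
#'   default pool).
#' @export
filter_observed_species <- function(species_pool = threatened_forest_birds()) {
  species_pool[species_pool$observed, , drop = FALSE]
}
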