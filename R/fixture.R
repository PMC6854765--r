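#' Curated apolipoprotein presence/absence fixture
#'
#' Returns the packaged 30-species x 10-member presence/absence matrix for
#' the exchangeable apolipoprotein family (ApoA-I, ApoA-II, ApoA-IV,
#' ApoA-V, ApoC-I, ApoC-IA, ApoC-II, ApoC-III, ApoC-IV, ApoE) together
#' with the ladder-shaped species tree it was scored on.
#'
#' The species set uses representative taxa per clade: 1 cartilaginous
#' fish, 1 holostean (spotted gar), 4 teleosts, 1 coelacanth, 1 amphibian,
#' 5 saurians (3 of them birds), platypus, opossum, and 15 eutherians
#' spanning Perissodactyla, Cetartiodactyla, Carnivora, Glires and
#' Primates. Presence follows the rule "present in every taxon from the
#' member's origin clade onward", with the documented lineage losses:
#' ApoC-I, ApoC-II and ApoE in birds; ApoC-I additionally in
#' Cetartiodactyla and platypus; ApoA-V in platypus; and ApoC-IA (present
#' only in nonhuman primates) in humans, where its gene is a pseudogene.
#'
#' @return A list with components `matrix` (a [phyletic_matrix], 30 taxa x
#'   10 characters) and `tree` (a [rooted_tree] whose internal nodes are
#'   labeled with clade names).
#' @examples
#' fx <- apo_fixture()
#' dim(fx$matrix)
#' @export
apo_fixture <- function() {
  mpath <- system.file("extdata", "apo_presence_matrix.tsv",
                       package = "apoevol", mustWork = TRUE)
  tpath <- system.file("extdata", "apo_species_tree.nwk",
                       package = "apoevol", mustWork = TRUE)
  list(matrix = read_matrix(mpath), tree = read_newick(tpath))
}
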