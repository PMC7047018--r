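## Species roles in the study design:
##  - outgroup pair (BOP clade): Oryza, Brachypodium
##  - anchor reference for RBH orthology: Sorghum
##  - WGD lineages carrying retained duplicate pairs: Zea, Eragrostis
##  - target species sequenced by long reads (no reference genome):
##    Chasmanthium, Dichanthelium, Hymenachne

#' Species labels by role
#'
#' @return Character vectors of species labels.
#' @name species_roles
NULL

#' @rdname species_roles
#' @export
target_species <- function() c("Chasmanthium", "Dichanthelium", "Hymenachne")

#' @rdname species_roles
#' @export
reference_species <- function() {
  c("Oryza", "Brachypodium", "Oropetium", "Eragrostis", "Pennisetum",
    "Setaria", "Sorghum", "Zea")
}

#' @rdname species_roles
#' @export
outgroup_species <- function() c("Oryza", "Brachypodium")

#' @rdname species_roles
#' @export
anchor_species <- function() "Sorghum"

#' @rdname species_roles
#' @export
wgd_lineages <- function() c("Zea", "Eragrostis")

SPECIES_TOPOLOGY <- paste0(
  "((Oryza,Brachypodium),((Oropetium,Eragrostis),(Chasmanthium,",
  "((Dichanthelium,(Pennisetum,Setaria)),(Hymenachne,(Sorghum,Zea))))));"
)

#' Literature consensus species tree for the 11 study taxa
#'
#' Rooted 11-taxon tree: the BOP outgroup pair (rice, brachypodium) sister
#' to all PACMAD taxa; Chloridoideae (Oropetium, Eragrostis) sister to the
#' Panicoideae; Chasmanthium earliest-diverging panicoid; Dichanthelium
#' with the Paniceae (Pennisetum, Setaria); Hymenachne sister to the
#' Andropogoneae (Sorghum, Zea).
#'
#' @param branch_length Expected substitutions/site applied to every branch
#'   (default 0.05). A vector is recycled over the tree's edges in `ape`
#'   edge order.
#' @return An object of class `phylo` (rooted, 11 leaves).
#' @examples
#' tr <- species_tree()
#' ape::is.monophyletic(tr, c("Oryza", "Brachypodium"))
#' @export
species_tree <- function(branch_length = 0.05) {
  tr <- ape::read.tree(text = SPECIES_TOPOLOGY)
  tr$edge.length <- rep_len(branch_length, nrow(tr$edge))
  tr
}
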