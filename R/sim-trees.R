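## One rooted NNI move on a phylo object. Candidate edges are internal
## edges (child is an internal node) whose parent is not the root and whose
## child is not the MRCA of the protected pair, so the protected cherry can
## never be broken and a single move always changes exactly one
## bipartition (unrooted Robinson-Foulds distance 2).
nni_once <- function(tr, protect = outgroup_species()) {
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  protect_mrca <- ape::getMRCA(tr, protect)
  child <- tr$edge[, 2]
  parent <- tr$edge[, 1]
  cand <- which(child > ntip & parent != root & child != protect_mrca)
  if (length(cand) == 0L) stop("no eligible internal edge for NNI")
  e <- cand[sample.int(length(cand), 1L)]
  v <- child[e]
  p <- parent[e]
  ## sibling of v under p, and a random child of v
  sib_edges <- which(parent == p & child != v)
  s_edge <- sib_edges[sample.int(length(sib_edges), 1L)]
  v_children <- which(parent == v)
  c_edge <- v_children[sample.int(length(v_children), 1L)]
  ## swap subtrees: c moves under p, s moves under v; normalize the edge
  ## matrix through a newick round-trip so downstream traversals see a
  ## canonical ape ordering
  tr$edge[s_edge, 1] <- v
  tr$edge[c_edge, 1] <- p
  ape::read.tree(text = ape::write.tree(tr))
}

#' Simulate gene trees with controlled discordance
#'
#' Each gene tree starts as a copy of the species tree. With probability
#' `discord_rate` it is perturbed by `nni_moves` random
#' nearest-neighbour-interchange moves on internal edges, never disrupting
#' the outgroup pair, so the outgroup-rooting step downstream remains
#' applicable to every simulated gene tree. Deterministic for a fixed
#' config seed; per-gene substreams mean the first k trees are identical
#' whatever `n_genes` is.
#'
#' @param tree Species tree (`phylo`), e.g. [species_tree()].
#' @param config A [sim_config()].
#' @return List of `n_genes` rooted `phylo` objects; attribute
#'   `perturbed` is the logical vector of which trees received moves.
#' @export
simulate_gene_trees <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  perturbed <- logical(config$n_genes)
  trees <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    set.seed(substream_seed(config$seed, g))
    gt <- tree
    if (stats::runif(1) < config$discord_rate) {
      perturbed[g] <- TRUE
      for (i in seq_len(config$nni_moves)) gt <- nni_once(gt)
    }
    trees[[g]] <- gt
  }
  attr(trees, "perturbed") <- perturbed
  trees
}
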