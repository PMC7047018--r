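## Character matrix (rows = taxa) of the masked columns of a codon
## alignment, with rows renamed to species labels.
masked_matrix <- function(aln) {
  stopifnot(!is.null(aln$mask))
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(mat) <- names(aln$rows)
  mat[, aln$mask + 1L, drop = FALSE]
}

#' Build a gene tree from a filtered codon alignment
#'
#' Default builder is neighbor joining on Jukes-Cantor distances computed
#' from the retained alignment columns. Saturated distances (proportion of
#' differing sites at or beyond 0.75, where the Jukes-Cantor correction
#' diverges) are clamped to `max_distance`. Deterministic for a fixed
#' input. An external maximum-likelihood adapter can be supplied as a
#' function `(character matrix) -> phylo`.
#'
#' @param aln A `codon_alignment` with a mask ([filter_blocks()]), or a
#'   character matrix of aligned sites (rows = taxa).
#' @param method `"nj"` (default) or a function for an external builder.
#' @param max_distance Clamp value for saturated distances (default 5).
#' @return Unrooted `phylo` with branch lengths.
#' @export
build_tree <- function(aln, method = "nj", max_distance = 5) {
  mat <- if (inherits(aln, "codon_alignment")) masked_matrix(aln) else aln
  if (nrow(mat) < 4L) stop("tree building requires at least 4 taxa")
  if (ncol(mat) < 3L) stop("alignment retains fewer than one codon")
  if (is.function(method)) return(method(mat))
  stopifnot(identical(method, "nj"))
  d <- ape::dist.dna(ape::as.DNAbin(tolower(mat)), model = "JC69",
                     pairwise.deletion = TRUE)
  d[!is.finite(d) | d > max_distance] <- max_distance
  ape::nj(d)
}

#' Neighbor joining from a distance matrix
#'
#' Thin wrapper used by the quartet-recovery checks.
#'
#' @param d A `dist` or symmetric matrix.
#' @return Unrooted `phylo`.
#' @export
nj_tree <- function(d) ape::nj(stats::as.dist(d))

#' Outgroup check and rooting
#'
#' A gene tree is acceptable only when the outgroup pair forms its own
#' bipartition (the two outgroup taxa sister to everything else); such
#' trees are rooted on that edge, all others are rejected — rejection
#' feeds the `outgroup_not_monophyletic` ledger reason.
#'
#' @param tree Unrooted `phylo` containing both outgroup taxa.
#' @param outgroup Character vector of the two outgroup taxa.
#' @return Rooted `phylo`, or `NULL` on rejection.
#' @export
check_outgroup_and_root <- function(tree, outgroup = outgroup_species()) {
  if (!all(outgroup %in% tree$tip.label)) {
    stop("outgroup taxa missing from tree: ",
         paste(setdiff(outgroup, tree$tip.label), collapse = ", "))
  }
  other <- setdiff(tree$tip.label, outgroup)[1]
  probe <- ape::root(ape::unroot(tree), outgroup = other,
                     resolve.root = TRUE)
  if (!ape::is.monophyletic(probe, outgroup)) return(NULL)
  ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
}

#' Canonical serialization of a rooted topology
#'
#' Branch lengths are stripped and children are recursively sorted by
#' their own canonical strings, so any rotation of the same rooted
#' topology — and any input leaf ordering — maps to one identical string.
#' Used as the hash key of the topology census.
#'
#' @param tree Rooted `phylo` with unique leaf labels.
#' @return Canonical nested-set string, e.g. `"((A,B),C)"`.
#' @export
canonical_topology <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    subs <- sort(vapply(kids[[as.character(node)]], rec, character(1)))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  rec(ntip + 1L)
}

#' Census of rooted gene-tree topologies
#'
#' Tallies canonical topologies over the accepted (outgroup-rooted) gene
#' trees; the census is sorted by count (descending), ties broken by
#' canonical string. Percentages are truncated to one decimal.
#'
#' @param trees List of rooted `phylo` objects (optionally named by
#'   "group#combo" sample ids).
#' @return data.frame of class `topology_census`: `rank`, `topology`
#'   (canonical string), `count`, `percent`; attribute `members` lists the
#'   contributing sample names per topology.
#' @export
topology_census <- function(trees) {
  if (length(trees) == 0L) {
    out <- data.frame(rank = integer(0), topology = character(0),
                      count = integer(0), percent = numeric(0))
    class(out) <- c("topology_census", "data.frame")
    return(out)
  }
  keys <- vapply(trees, canonical_topology, character(1))
  tab <- table(keys)
  ord <- order(-as.integer(tab), names(tab))
  out <- data.frame(
    rank = seq_along(ord),
    topology = names(tab)[ord],
    count = as.integer(tab)[ord],
    percent = pct_trunc(as.integer(tab)[ord], length(trees)),
    stringsAsFactors = FALSE)
  attr(out, "members") <- lapply(out$topology, function(tp) {
    nm <- names(keys)[keys == tp]
    if (is.null(nm)) which(keys == tp) else nm
  })
  class(out) <- c("topology_census", "data.frame")
  out
}

#' Write a topology census as TSV
#'
#' Columns: rank, topology (canonical newick), count, percent. Output is
#' byte-stable for identical input, so two equally seeded pipeline runs
#' produce identical files.
#'
#' @param census A `topology_census`.
#' @param path Output file.
#' @export
write_census <- function(census, path) {
  out <- data.frame(rank = census$rank,
                    topology = paste0(census$topology, ";"),
                    count = census$count,
                    percent = sprintf("%.1f", census$percent),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.topology_census <- function(x, max_rows = 10L, ...) {
  total <- sum(x$count)
  cat(sprintf("Topology census over %d accepted gene trees\n", total))
  n <- min(nrow(x), max_rows)
  for (i in seq_len(n)) {
    cat(sprintf("  rank %d: %d trees (%.1f%%)  %s\n",
                x$rank[i], x$count[i], x$percent[i],
                substr(x$topology[i], 1, 70)))
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more topologies\n", nrow(x) - n))
  invisible(x)
}
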