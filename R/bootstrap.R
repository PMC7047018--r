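## Per-branch bootstrap proportions of `best` given replicate trees,
## returned as a named vector keyed by clade composition.
branch_support <- function(best, replicates, reps) {
  pp <- ape::prop.part(best)
  counts <- ape::prop.clades(best, replicates, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ntip <- length(best$tip.label)
  keys <- vapply(seq_along(pp), function(k) {
    paste(sort(best$tip.label[pp[[k]]]), collapse = ",")
  }, character(1))
  keep <- lengths(pp) < ntip # drop the root/full clade
  stats::setNames(100 * counts[keep] / reps, keys[keep])
}

#' Bootstrap branch support averaged per topology class
#'
#' For each sampled alignment: the retained codon columns are resampled
#' with replacement (in whole codons) `reps` times, a tree is rebuilt from
#' each replicate, and per-branch support of that alignment's best tree is
#' the fraction of replicates containing the branch's bipartition.
#' Alignments are then binned by the canonical topology of their best
#' (outgroup-rooted) tree and branch supports are averaged across the
#' members of each topology, keyed by clade composition.
#'
#' @param alignments Named list of filtered `codon_alignment`s.
#' @param n_sample Number of alignments drawn without replacement.
#' @param reps Bootstrap replicates per alignment (>= 1).
#' @param seed Integer seed.
#' @param outgroup Outgroup pair used to root best trees.
#' @return Named list per canonical topology: `count` (member alignments)
#'   and `support` (named numeric, mean percentage per clade).
#' @export
bootstrap_support <- function(alignments, n_sample = length(alignments),
                              reps = 100L, seed = 1L,
                              outgroup = outgroup_species()) {
  stopifnot(reps >= 1L)
  if (n_sample > length(alignments)) {
    stop("n_sample exceeds the number of available alignments")
  }
  set.seed(seed)
  picked <- sample(names(alignments), n_sample)
  bins <- list()
  for (nm in picked) {
    aln <- alignments[[nm]]
    mat <- masked_matrix(aln)
    best_un <- build_tree(mat)
    best <- check_outgroup_and_root(best_un, outgroup)
    if (is.null(best)) next
    n_codons <- ncol(mat) / 3L
    reps_trees <- vector("list", reps)
    for (r in seq_len(reps)) {
      cod <- sample.int(n_codons, n_codons, replace = TRUE)
      cols <- as.vector(rbind(3L * cod - 2L, 3L * cod - 1L, 3L * cod))
      reps_trees[[r]] <- build_tree(mat[, cols, drop = FALSE])
    }
    sup <- branch_support(best, reps_trees, reps)
    key <- canonical_topology(best)
    if (is.null(bins[[key]])) bins[[key]] <- list()
    bins[[key]][[length(bins[[key]]) + 1L]] <- sup
  }
  lapply(bins, function(sups) {
    keys <- unique(unlist(lapply(sups, names)))
    avg <- vapply(keys, function(k) {
      mean(vapply(sups, function(s) unname(s[k]), numeric(1)), na.rm = TRUE)
    }, numeric(1))
    list(count = length(sups), support = avg)
  })
}
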