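## Attach CDS-less transcripts (no stop codon in any forward frame) to the
## anchor gene sharing the most exact 12-mers, for quality-screen
## accounting. min_shared keeps random matches out.
attach_unassignable <- function(seqs, anchor_cds, min_shared = 2L) {
  if (length(seqs) == 0L) return(stats::setNames(character(0), character(0)))
  cand <- seed_candidates(seqs, anchor_cds, min_shared = min_shared)
  out <- character(0)
  for (i in seq_along(seqs)) {
    if (length(cand[[i]]$j) == 0L) next
    out[names(seqs)[i]] <-
      names(anchor_cds)[cand[[i]]$j[which.max(cand[[i]]$count)]]
  }
  out
}

#' Run the transcript-to-phylogeny pipeline
#'
#' End-to-end chain: per-transcript CDS calling (longest stop-terminated
#' ORF), reciprocal-best-hit pairing of target-species CDSs against the
#' anchor reference CDSs, representative-transcript selection per anchor
#' gene, transitive ortholog-group construction over the syntenic table,
#' WGD copy-combination sampling, protein-guided codon alignment with
#' conserved-block filtering, the discard ledger, neighbor-joining gene
#' trees with outgroup-constrained rooting, and the rooted-topology
#' census (all alignments, plus the long-alignment subset).
#'
#' @param transcripts Named list: target species -> named character vector
#'   of transcript sequences.
#' @param reference_cds Named list: reference species -> named character
#'   vector of CDS sequences.
#' @param synteny Syntenic-ortholog data.frame ([read_synteny()]).
#' @param anchor Anchor reference species.
#' @param outgroup Outgroup pair for rooting.
#' @param min_identity,min_coverage Similarity-search thresholds.
#' @param min_alignment_nt High-quality alignment length threshold.
#' @param protein_aligner Passed to [codon_align()].
#' @param tree_method Passed to [build_tree()].
#' @return Object of class `panphylo_result` with components `cds`
#'   (per-species CDS records), `rbh` (per-species RBH tables),
#'   `representatives`, `groups`, `category_tally`, `alignments`
#'   (surviving filtered alignments), `ledger`, `trees` (accepted rooted
#'   trees), `counts` (built/accepted/rejected), `census` (all genes) and
#'   `census_long` (>= `min_alignment_nt`).
#' @export
run_pipeline <- function(transcripts, reference_cds, synteny,
                         anchor = anchor_species(),
                         outgroup = outgroup_species(),
                         min_identity = 0.70, min_coverage = 0.50,
                         min_alignment_nt = 900L,
                         protein_aligner = "centerstar",
                         tree_method = "nj") {
  anchor_cds <- reference_cds[[anchor]]
  stopifnot(!is.null(anchor_cds))
  flat_ref <- do.call(c, unname(reference_cds))

  ## 1. CDS calling
  cds <- lapply(transcripts, find_cds_set)

  ## 2. RBH vs anchor + representative per anchor gene
  rbh <- list()
  reps <- list()
  for (sp in names(transcripts)) {
    sp_cds <- vapply(cds[[sp]], function(r) r$cds_seq, character(1))
    hits <- similarity_search_both(sp_cds, anchor_cds,
                                   min_identity, min_coverage)
    rbh[[sp]] <- reciprocal_best_hits(hits$ab, hits$ba)
    reps[[sp]] <- select_representative(rbh[[sp]], nchar(sp_cds))
  }

  ## 3. ortholog groups
  groups <- build_groups(synteny, reps, anchor = anchor)
  tally <- tally_categories(groups)

  ## 4. group-attached transcripts for the quality screen: representatives
  ##    plus CDS-less transcripts attached by seed matches
  gid_of_anchor <- stats::setNames(
    rep(vapply(groups, `[[`, character(1), "group_id"),
        vapply(groups, function(g) length(g$members[[anchor]]), integer(1))),
    unlist(lapply(groups, function(g) g$members[[anchor]])))
  target_tx <- list()
  add_tx <- function(gid, id, seq) {
    target_tx[[gid]] <<- c(target_tx[[gid]], stats::setNames(seq, id))
  }
  for (sp in names(transcripts)) {
    no_cds <- setdiff(names(transcripts[[sp]]), names(cds[[sp]]))
    att <- attach_unassignable(transcripts[[sp]][no_cds], anchor_cds)
    for (id in names(att)) {
      gid <- gid_of_anchor[att[id]]
      if (!is.na(gid)) add_tx(gid, id, transcripts[[sp]][[id]])
    }
    for (g in names(reps[[sp]])) {
      gid <- gid_of_anchor[g]
      tid <- reps[[sp]][[g]]
      if (!is.na(gid)) add_tx(gid, tid, transcripts[[sp]][[tid]])
    }
  }

  ## 5. align category-3 groups (per WGD copy combination)
  cds_seq_of <- function(sp, tid) cds[[sp]][[tid]]$cds_seq
  tx_species <- stats::setNames(
    rep(names(transcripts), vapply(transcripts, length, integer(1))),
    unlist(lapply(transcripts, names)))
  cat3 <- groups[vapply(groups, function(g) g$category == 3L, logical(1))]
  class(cat3) <- "ortho_groups"
  alignments <- list()
  for (g in cat3) {
    if (!all(unlist(g$members[intersect(names(g$members),
                                        names(reference_cds))]) %in%
             names(flat_ref))) next # missing annotation, ledgered below
    for (smp in enumerate_combinations(g)) {
      sel <- smp$leaf_selection
      seqs <- vapply(names(sel), function(sp) {
        if (sp %in% names(reference_cds)) flat_ref[[sel[[sp]]]]
        else cds_seq_of(sp, sel[[sp]])
      }, character(1))
      names(seqs) <- names(sel)
      aln <- codon_align(seqs, protein_aligner = protein_aligner)
      aln$group_id <- g$group_id
      aln$combo_index <- smp$combo_index
      alignments[[paste0(g$group_id, "#", smp$combo_index)]] <-
        filter_blocks(aln)
    }
  }

  ## 6. discard ledger
  ledger <- apply_ledger(cat3, alignments, flat_ref, target_tx,
                         min_alignment_nt = min_alignment_nt)

  ## 7. trees + outgroup constraint (alignments retaining no codon after
  ##    filtering carry no signal and are not built)
  accepted <- list()
  rejected <- character(0)
  n_built <- 0L
  for (nm in names(ledger$alignments)) {
    aln <- ledger$alignments[[nm]]
    if (masked_length(aln) < 3L) next
    n_built <- n_built + 1L
    tr <- build_tree(aln, method = tree_method)
    rt <- check_outgroup_and_root(tr, outgroup)
    if (is.null(rt)) {
      rejected <- c(rejected, nm)
      ledger$entries <- rbind(ledger$entries, data.frame(
        group_id = aln$group_id, reason = "outgroup_not_monophyletic",
        detail = nm, stringsAsFactors = FALSE))
    } else {
      accepted[[nm]] <- rt
    }
  }

  ## 8. census: all genes, and the long-alignment subset
  census_all <- topology_census(accepted)
  long <- intersect(names(accepted), ledger$long_alignments)
  census_long <- topology_census(accepted[long])

  structure(list(
    cds = cds, rbh = rbh, representatives = reps, groups = groups,
    category_tally = tally, alignments = ledger$alignments,
    ledger = ledger$entries, long_alignments = ledger$long_alignments,
    trees = accepted,
    counts = c(built = n_built,
               accepted = length(accepted), rejected = length(rejected)),
    census = census_all, census_long = census_long
  ), class = "panphylo_result")
}

#' @export
print.panphylo_result <- function(x, ...) {
  cat("<panphylo_result>\n")
  cat(sprintf("  groups: %d (category 0/1/2/3 = %s)\n", length(x$groups),
              paste(x$category_tally, collapse = "/")))
  cat(sprintf("  trees: %d built, %d accepted, %d rejected on outgroup\n",
              x$counts["built"], x$counts["accepted"],
              x$counts["rejected"]))
  if (nrow(x$census)) {
    cat(sprintf("  rank-1 topology: %d/%d trees (%.1f%%)\n",
                x$census$count[1], sum(x$census$count),
                x$census$percent[1]))
  }
  invisible(x)
}

#' @export
summary.panphylo_result <- function(object, ...) {
  cat("Transcript-to-phylogeny pipeline result\n")
  cat("=======================================\n")
  print(object)
  reasons <- table(object$ledger$reason)
  if (length(reasons)) {
    cat("  ledger entries:\n")
    for (r in names(reasons)) cat(sprintf("    %-26s %d\n", r, reasons[[r]]))
  }
  cat(sprintf("  long (>= threshold) alignments: %d\n",
              length(object$long_alignments)))
  if (nrow(object$census)) {
    cat("  census (all genes):\n")
    print(object$census)
  }
  invisible(object)
}
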