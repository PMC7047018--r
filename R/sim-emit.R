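DNA_BASES <- c("A", "C", "G", "T")

## Random CDS of n codons: ATG + non-stop codons + TAA-family stop.
random_root_cds <- function(n_codons) {
  body <- character(n_codons - 2L)
  for (i in seq_along(body)) {
    repeat {
      cd <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!cd %in% STOP_CODONS) break
    }
    body[i] <- cd
  }
  paste0("ATG", paste(body, collapse = ""),
         sample(STOP_CODONS, 1L))
}

## Jukes-Cantor evolution of a CDS along one branch. Per-site substitution
## probability p = 3/4 (1 - exp(-4 b / 3)). A mutation that creates an
## in-frame stop is resampled among the remaining bases (unless
## allow_stops); the terminal stop codon is held fixed so every descendant
## CDS stays stop-terminated.
evolve_cds <- function(cds, branch_length, allow_stops = FALSE) {
  p <- 0.75 * (1 - exp(-4 * branch_length / 3))
  bases <- strsplit(cds, "", fixed = TRUE)[[1]]
  n <- length(bases)
  mutable <- seq_len(n - 3L) # protect terminal stop
  hit <- mutable[stats::runif(length(mutable)) < p]
  for (i in hit) {
    alt <- setdiff(DNA_BASES, bases[i])
    bases[i] <- alt[sample.int(3L, 1L)]
  }
  if (!allow_stops) {
    repeat {
      codon_start <- seq.int(1L, n - 5L, by = 3L) # internal codons only
      codons <- paste0(bases[codon_start], bases[codon_start + 1L],
                       bases[codon_start + 2L])
      bad <- which(codons %in% STOP_CODONS)
      if (length(bad) == 0L) break
      for (b in bad) {
        ## re-draw one position of the offending codon
        pos <- codon_start[b] + sample.int(3L, 1L) - 1L
        bases[pos] <- sample(DNA_BASES, 1L)
      }
    }
  }
  paste(bases, collapse = "")
}

## Evolve the root CDS down a rooted gene tree; returns per-tip sequences.
## WGD lineage tips draw a second, independently evolved copy along their
## terminal branch when the duplicate pair is retained.
evolve_along_tree <- function(tree, root_cds, retained) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_cds
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  tips <- list()
  walk <- function(node) {
    for (e in kids[[as.character(node)]]) {
      chd <- tree$edge[e, 2]
      child_seq <- evolve_cds(seqs[[node]], tree$edge.length[e])
      if (chd <= ntip) {
        sp <- tree$tip.label[chd]
        copies <- child_seq
        if (isTRUE(retained[sp])) {
          copies <- c(copies, evolve_cds(seqs[[node]], tree$edge.length[e]))
        }
        tips[[sp]] <<- copies
      } else {
        seqs[[chd]] <<- child_seq
        walk(chd)
      }
    }
  }
  walk(root)
  tips
}

## Random UTR with a stop cassette covering all three frames placed at the
## CDS-proximal end, so the planted CDS is the longest ORF by construction.
STOP_CASSETTE <- "TAAATAAATAA"

random_utr <- function(len, cassette_at_end) {
  core <- paste(sample(DNA_BASES, len - nchar(STOP_CASSETTE), replace = TRUE),
                collapse = "")
  if (cassette_at_end) paste0(core, STOP_CASSETTE)
  else paste0(STOP_CASSETTE, core)
}

## Strip every stop codon, on both strands and in all frames, from a
## sequence by point substitutions: forward stops TAA/TAG/TGA lose their
## leading T; reverse-strand stops (seen forward as TTA/CTA/TCA) lose their
## trailing A. Iterates until the six-frame check finds nothing.
remove_all_stops <- function(seq) {
  fwd <- c("TAA", "TAG", "TGA")
  rev <- c("TTA", "CTA", "TCA")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  repeat {
    n <- length(bases)
    tri <- paste0(bases[1:(n - 2)], bases[2:(n - 1)], bases[3:n])
    hits_f <- which(tri %in% fwd)
    hits_r <- which(tri %in% rev)
    if (length(hits_f) == 0L && length(hits_r) == 0L) break
    if (length(hits_f)) bases[hits_f] <- "C"
    if (length(hits_r)) bases[hits_r + 2L] <- "G"
  }
  paste(bases, collapse = "")
}

#' Evolve sequences along gene trees and emit a synthetic dataset
#'
#' For each gene: a random root CDS (ATG ... stop, no internal stop) is
#' evolved along the gene tree under per-site Jukes-Cantor substitution;
#' the two WGD lineages retain an independently evolved duplicate copy with
#' their lineage retention probability; each target-species locus, unless
#' dropped out, emits Poisson(isoform_mean)+1 redundant transcript copies,
#' UTR-padded (100 nt 5', 150 nt 3', stop cassettes seeded in all frames)
#' and each 5'-truncated by a uniform fraction of at most 50% with
#' probability `truncation_prob`. Planted defects: an internal in-frame
#' stop in one non-anchor reference CDS; removal of every stop codon (all
#' six frames) from one target-species isoform; deletion of one reference
#' annotation from the CDS FASTA while its id stays in the synteny table.
#'
#' @param gene_trees List of rooted `phylo` trees from
#'   [simulate_gene_trees()].
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes per-species
#'   transcript FASTA (`<species>.transcripts.fa`), per-species reference
#'   CDS FASTA (`<species>.cds.fa`), `synteny.tsv` and `truth.json`.
#' @return Invisibly (visibly when `out_dir` is `NULL`) a list of class
#'   `sim_dataset`: `transcripts` (per target species, named character
#'   vectors), `reference_cds` (per reference species), `synteny`
#'   (data.frame), `truth` (gene trees, ortholog map, WGD status, planted
#'   defects), `config`.
#' @export
evolve_and_emit <- function(gene_trees, config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(gene_trees)
  refs <- reference_species()
  targets <- target_species()
  lineages <- wgd_lineages()

  transcripts <- stats::setNames(
    replicate(length(targets), character(0), simplify = FALSE), targets)
  reference_cds <- stats::setNames(
    replicate(length(refs), character(0), simplify = FALSE), refs)
  synteny_cells <- matrix(".", nrow = n, ncol = length(refs),
                          dimnames = list(NULL, refs))
  group_ids <- sprintf("grp%04d", seq_len(n))
  ortholog_map <- list()
  wgd_status <- list()
  defects <- list()

  for (g in seq_len(n)) {
    set.seed(substream_seed(config$seed, 100000L + g))
    gid <- group_ids[g]
    root_cds <- random_root_cds(config$root_cds_codons)
    retained <- stats::setNames(
      stats::runif(length(lineages)) < config$retention_prob[lineages],
      lineages)
    wgd_status[[gid]] <- stats::setNames(
      ifelse(retained, "retained", "fractionated"), lineages)

    tips <- evolve_along_tree(gene_trees[[g]], root_cds, retained)

    ## choose planted defects for this group; a no-stop defect is only
    ## recorded in the truth if some target species expresses the locus
    planted <- names(config$defect_rates)[
      stats::runif(length(config$defect_rates)) < config$defect_rates]

    ## reference species: CDS records + synteny row
    for (sp in refs) {
      ids <- if (length(tips[[sp]]) == 2L) {
        paste0(sp, "_", gid, c("a", "b"))
      } else paste0(sp, "_", gid)
      seqs <- tips[[sp]]
      if ("internal_stop_reference" %in% planted && sp == "Oropetium") {
        ## overwrite an internal codon of the first copy with a stop
        bases <- strsplit(seqs[1], "", fixed = TRUE)[[1]]
        at <- 3L * (sample.int(config$root_cds_codons - 2L, 1L)) + 1L
        bases[at:(at + 2L)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
        seqs[1] <- paste(bases, collapse = "")
      }
      keep <- rep(TRUE, length(ids))
      if ("missing_annotation" %in% planted && sp == "Brachypodium") {
        keep[1] <- FALSE # id stays in the synteny table, sequence withheld
      }
      reference_cds[[sp]] <- c(reference_cds[[sp]],
                               stats::setNames(seqs[keep], ids[keep]))
      synteny_cells[g, sp] <- paste(ids, collapse = ",")
    }

    ## target species: redundant, UTR-padded, truncated isoforms
    no_stop_used <- FALSE
    for (sp in targets) {
      if (stats::runif(1) < config$expression_dropout) next
      n_iso <- stats::rpois(1, config$isoform_mean) + 1L
      cds <- tips[[sp]][1]
      for (k in seq_len(n_iso)) {
        tid <- sprintf("%s_%s_iso%02d", sp, gid, k)
        full <- paste0(random_utr(100L, cassette_at_end = TRUE), cds,
                       random_utr(150L, cassette_at_end = FALSE))
        if (config$isoform_error > 0) {
          bases <- strsplit(full, "", fixed = TRUE)[[1]]
          hit <- which(stats::runif(length(bases)) < config$isoform_error)
          for (i in hit) {
            bases[i] <- sample(setdiff(DNA_BASES, bases[i]), 1L)
          }
          full <- paste(bases, collapse = "")
        }
        if ("no_stop_six_frames" %in% planted && !no_stop_used && k == 1L) {
          full <- remove_all_stops(full)
          no_stop_used <- TRUE
        } else if (stats::runif(1) < config$truncation_prob) {
          cut <- floor(stats::runif(1, 0, 0.5) * nchar(full))
          if (cut > 0) full <- substr(full, cut + 1L, nchar(full))
        }
        transcripts[[sp]] <- c(transcripts[[sp]],
                               stats::setNames(full, tid))
        ortholog_map[[tid]] <- list(group_id = gid, species = sp)
      }
    }

    materialized <- setdiff(planted, "no_stop_six_frames")
    if (no_stop_used) materialized <- c(materialized, "no_stop_six_frames")
    for (reason in materialized) defects[[length(defects) + 1L]] <-
      list(group_id = gid, reason = reason)
  }

  synteny <- data.frame(group_id = group_ids, synteny_cells,
                        stringsAsFactors = FALSE, check.names = FALSE)
  truth <- list(gene_trees = gene_trees, ortholog_map = ortholog_map,
                wgd_status = wgd_status, planted_defects = defects)
  out <- structure(list(transcripts = transcripts,
                        reference_cds = reference_cds,
                        synteny = synteny, truth = truth, config = config),
                   class = "sim_dataset")
  if (!is.null(out_dir)) {
    write_sim_dataset(out, out_dir)
    return(invisible(out))
  }
  out
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: species tree, gene trees, then sequence emission.
#'
#' @inheritParams evolve_and_emit
#' @param config A [sim_config()].
#' @return A `sim_dataset`; see [evolve_and_emit()].
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  tr <- species_tree(config$branch_length)
  gts <- simulate_gene_trees(tr, config)
  evolve_and_emit(gts, config, out_dir = out_dir)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d groups; %s transcripts per target species; seed %d\n",
    nrow(x$synteny),
    paste(vapply(x$transcripts, length, integer(1)), collapse = "/"),
    x$config$seed))
  invisible(x)
}
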