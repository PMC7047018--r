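#' Enumerate WGD copy-combination samples for a group
#'
#' Gene trees must keep one leaf per species, but a lineage that retained
#' its whole-genome-duplication pair contributes two co-orthologous
#' copies. Every combination of one copy per retained lineage is sampled:
#' both lineages fractionated gives a single sample, exactly one retained
#' gives two, both retained gives four.
#'
#' @param group An `ortho_group` (category must be 3; groups lacking a
#'   representative in some target species are not aligned).
#' @param lineages WGD lineage labels.
#' @return List of samples, each with `group_id`, `combo_index` and
#'   `leaf_selection` (named character: species -> single id).
#' @export
enumerate_combinations <- function(group, lineages = wgd_lineages()) {
  if (group$category != 3L) {
    stop("combination sampling requires a category-3 group, got category ",
         group$category)
  }
  fixed <- group$members[setdiff(names(group$members), lineages)]
  stopifnot(all(lengths(fixed) <= 1L))
  fixed <- unlist(lapply(fixed, function(x) x[1]))
  choices <- lapply(group$members[lineages], function(ids) ids)
  grid <- expand.grid(rev(choices), stringsAsFactors = FALSE)[
    , rev(seq_along(lineages)), drop = FALSE]
  names(grid) <- lineages
  lapply(seq_len(nrow(grid)), function(i) {
    sel <- c(fixed, unlist(grid[i, , drop = FALSE]))
    list(group_id = group$group_id, combo_index = i,
         leaf_selection = sel[!is.na(sel)])
  })
}

## ---- protein multiple alignment -------------------------------------------

## Center-star progressive alignment: every sequence is globally aligned to
## the longest sequence (the center) with BLOSUM62 scoring; gaps are merged
## into a common coordinate system. Adequate for closely related
## orthologous proteins, which is the operating regime here.
align_proteins_centerstar <- function(prots) {
  n <- length(prots)
  if (n == 1L) return(stats::setNames(prots, names(prots)))
  clean <- chartr("*", "X", prots)
  center <- which.max(nchar(clean))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  pas <- lapply(seq_len(n)[-center], function(i) {
    Biostrings::pairwiseAlignment(
      clean[[i]], clean[[center]], type = "global",
      substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5)
  })
  m <- nchar(clean[[center]])
  ## insertions relative to the center: ins[k] = columns inserted after
  ## center position k (k = 0 .. m)
  ins_per <- lapply(pas, function(pa) {
    caln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ins <- integer(m + 1L)
    pos <- 0L
    for (ch in caln) {
      if (ch == "-") ins[pos + 1L] <- ins[pos + 1L] + 1L else pos <- pos + 1L
    }
    ins
  })
  ins <- Reduce(pmax, ins_per, integer(m + 1L))
  ## rebuild the center row
  cch <- strsplit(clean[[center]], "")[[1]]
  center_row <- paste0(
    strrep("-", ins[1]),
    paste0(vapply(seq_len(m), function(k) {
      paste0(cch[k], strrep("-", ins[k + 1L]))
    }, character(1)), collapse = ""))
  rows <- stats::setNames(vector("character", n), names(prots))
  rows[center] <- center_row
  others <- seq_len(n)[-center]
  for (oi in seq_along(others)) {
    pa <- pas[[oi]]
    oaln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    caln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    out <- character(0)
    pos <- 0L            # center position emitted so far
    run <- character(0)  # other-sequence chars in current insertion run
    for (j in seq_along(caln)) {
      if (caln[j] == "-") {
        run <- c(run, oaln[j])
      } else {
        out <- c(out, run, rep("-", ins[pos + 1L] - length(run)))
        run <- character(0)
        pos <- pos + 1L
        out <- c(out, oaln[j])
      }
    }
    out <- c(out, run, rep("-", ins[m + 1L] - length(run)))
    ## splice trailing-run handling: insertion runs precede the next center
    ## residue, so re-walk emitted columns are already in order
    rows[others[oi]] <- paste(out, collapse = "")
  }
  ## restore the original residues (X substitutions were for scoring only)
  for (i in seq_len(n)) {
    orig <- strsplit(prots[[i]], "")[[1]]
    ach <- strsplit(rows[i], "")[[1]]
    ach[ach != "-"] <- orig
    rows[i] <- paste(ach, collapse = "")
  }
  rows
}

## External aligner adapter (mafft); produces the same contract as the
## internal aligner.
align_proteins_mafft <- function(prots) {
  tmp_in <- tempfile(fileext = ".fa")
  tmp_out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  write_fasta(prots, tmp_in)
  system2("mafft", c("--quiet", "--auto", tmp_in), stdout = tmp_out)
  aln <- read_fasta(tmp_out)
  toupper(aln[names(prots)])
}

#' Protein-guided codon alignment
#'
#' Translates each CDS (terminal stop set aside), aligns the proteins, and
#' expands every aligned residue back to its source codon — each protein
#' gap becomes a 3-nt gap, so gaps only ever appear in whole-codon units
#' and removing the gaps from any row reproduces its input CDS exactly.
#' The terminal stop codons are re-appended as the final, never-masked
#' codon column.
#'
#' @param cds Named character vector of in-frame, stop-terminated CDS
#'   sequences (one per species).
#' @param protein_aligner `"centerstar"` (internal, default), `"mafft"`
#'   (external adapter), or a function `(named proteins) -> named aligned
#'   proteins`.
#' @return Object of class `codon_alignment`: `rows` (named aligned DNA),
#'   `protein_rows`, `ncol`, `mask` (`NULL` until [filter_blocks()]).
#' @export
codon_align <- function(cds, protein_aligner = "centerstar") {
  stopifnot(!is.null(names(cds)), all(nchar(cds) %% 3 == 0))
  aligner <- if (is.function(protein_aligner)) {
    protein_aligner
  } else {
    switch(match.arg(protein_aligner, c("centerstar", "mafft")),
           centerstar = align_proteins_centerstar,
           mafft = align_proteins_mafft)
  }
  prots <- vapply(cds, translate_cds, character(1))
  aln <- aligner(prots)
  stopifnot(length(unique(nchar(aln))) == 1L)
  rows <- vapply(names(cds), function(sp) {
    codons <- codon_split(cds[[sp]])
    stop_codon <- codons[length(codons)]
    codons <- codons[-length(codons)]
    ach <- strsplit(aln[[sp]], "")[[1]]
    out <- character(length(ach))
    k <- 0L
    for (j in seq_along(ach)) {
      if (ach[j] == "-") {
        out[j] <- "---"
      } else {
        k <- k + 1L
        out[j] <- codons[k]
      }
    }
    stopifnot(k == length(codons))
    paste0(paste(out, collapse = ""), stop_codon)
  }, character(1))
  structure(list(rows = rows, protein_rows = aln,
                 ncol = unname(nchar(rows[1])), mask = NULL),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d rows x %d nt%s\n", length(x$rows),
              x$ncol,
              if (is.null(x$mask)) "" else
                sprintf(", %d nt retained after filtering", length(x$mask))))
  invisible(x)
}
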