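#' Conserved-block filtering of a codon alignment
#'
#' Reimplementation of the default-parameter conserved-block filter used
#' for alignment quality control, evaluated on the protein projection of
#' the codon alignment. A column is *conserved* when its majority residue
#' occurs in at least floor(n/2)+1 sequences and *highly conserved* at
#' ceiling(0.85 n); a tie for the majority residue counts as nonconserved.
#' Columns containing any gap are non-retainable. Runs of more than
#' `max_nonconserved_run` contiguous nonconserved columns break the
#' alignment into blocks; block flanks are trimmed until highly conserved;
#' blocks shorter than `min_block` protein columns are dropped. The mask
#' is the codon expansion of the surviving protein columns (gap columns
#' excluded); the terminal stop-codon column is never part of the mask.
#'
#' @param aln A `codon_alignment` from [codon_align()].
#' @param min_block Minimum block length in protein columns (default 10).
#' @param max_nonconserved_run Longest nonconserved run tolerated inside a
#'   block (default 8).
#' @return The alignment with `mask` set: sorted 0-based nucleotide column
#'   indices retained by the filter.
#' @export
filter_blocks <- function(aln, min_block = 10L, max_nonconserved_run = 8L) {
  stopifnot(inherits(aln, "codon_alignment"))
  mat <- do.call(rbind, strsplit(unname(aln$protein_rows), ""))
  n <- nrow(mat)
  ncols <- ncol(mat)
  conserved_min <- floor(n / 2) + 1L
  highly_min <- ceiling(0.85 * n)
  has_gap <- apply(mat == "-", 2, any)
  cls <- character(ncols) # "NC", "C", "HC"
  for (j in seq_len(ncols)) {
    if (has_gap[j]) { cls[j] <- "NC"; next }
    tab <- table(mat[, j])
    top <- max(tab)
    if (sum(tab == top) > 1L || top < conserved_min) cls[j] <- "NC"
    else if (top >= highly_min) cls[j] <- "HC"
    else cls[j] <- "C"
  }
  ## break at nonconserved runs longer than the tolerance
  r <- rle(cls == "NC")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cut <- logical(ncols)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > max_nonconserved_run) {
      cut[starts[k]:ends[k]] <- TRUE
    }
  }
  keep_prot <- integer(0)
  seg_r <- rle(!cut)
  seg_ends <- cumsum(seg_r$lengths)
  seg_starts <- seg_ends - seg_r$lengths + 1L
  for (k in seq_along(seg_r$lengths)) {
    if (!seg_r$values[k]) next
    a <- seg_starts[k]; b <- seg_ends[k]
    while (a <= b && cls[a] != "HC") a <- a + 1L
    while (b >= a && cls[b] != "HC") b <- b - 1L
    if (b - a + 1L >= min_block) {
      cols <- a:b
      keep_prot <- c(keep_prot, cols[!has_gap[cols]])
    }
  }
  nt <- sort(unlist(lapply(keep_prot, function(j) (3L * (j - 1L)):(3L * j - 1L))))
  aln$mask <- as.integer(nt)
  aln
}

masked_length <- function(aln) length(aln$mask %||% integer(0))

#' Apply the discard ledger to ortholog groups and their alignments
#'
#' Screens every group for the defect classes that exclude it from
#' phylogenetic analysis, and flags alignments below the minimum
#' high-quality length:
#' \describe{
#'   \item{internal_stop_reference}{a reference CDS in the group translates
#'     with an internal stop;}
#'   \item{no_stop_six_frames}{a target-species transcript attached to the
#'     group has no stop codon in any of the six frames;}
#'   \item{missing_annotation}{a synteny cell id has no sequence in the
#'     reference CDS data;}
#'   \item{short_alignment}{a filtered alignment retains fewer than
#'     `min_alignment_nt` nucleotides. This does not discard the group: it
#'     defines the long-alignment subset, with the all-genes analysis
#'     keeping every surviving alignment.}
#' }
#'
#' @param groups `ortho_groups` to screen.
#' @param alignments Named list of filtered `codon_alignment`s; names are
#'   `"<group_id>#<combo_index>"`.
#' @param reference_cds Named character vector of all reference CDS
#'   sequences (ids as in the synteny table).
#' @param target_transcripts Named list: group id -> named character vector
#'   of target-species transcript sequences attached to that group.
#' @param min_alignment_nt High-quality length threshold in retained
#'   nucleotides (default 900, i.e. 300 codons).
#' @return List: `entries` (data.frame `group_id`, `reason`, `detail`),
#'   `discarded` (group ids removed by the first three reasons),
#'   `alignments` (surviving alignments, each with a logical `long`
#'   element), `long_alignments` (names of those at or above the
#'   threshold).
#' @export
apply_ledger <- function(groups, alignments, reference_cds,
                         target_transcripts = list(),
                         min_alignment_nt = 900L) {
  entries <- list()
  add <- function(gid, reason, detail = "") {
    entries[[length(entries) + 1L]] <<- data.frame(
      group_id = gid, reason = reason, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (g in groups) {
    for (sp in intersect(names(g$members), reference_species())) {
      for (id in g$members[[sp]]) {
        seq <- reference_cds[id]
        if (is.na(seq)) {
          add(g$group_id, "missing_annotation", id)
        } else if (grepl("*", translate_cds(seq), fixed = TRUE)) {
          add(g$group_id, "internal_stop_reference", id)
        }
      }
    }
    for (tid in names(target_transcripts[[g$group_id]] %||% character(0))) {
      if (!six_frame_stop_check(target_transcripts[[g$group_id]][[tid]])) {
        add(g$group_id, "no_stop_six_frames", tid)
      }
    }
  }
  entry_df <- if (length(entries)) do.call(rbind, entries) else
    data.frame(group_id = character(0), reason = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  discarded <- unique(entry_df$group_id[entry_df$reason %in%
    c("internal_stop_reference", "no_stop_six_frames", "missing_annotation")])
  surviving <- alignments[
    !vapply(alignments, function(a) a$group_id %in% discarded, logical(1))]
  for (nm in names(surviving)) {
    len <- masked_length(surviving[[nm]])
    surviving[[nm]]$long <- len >= min_alignment_nt
    if (len < min_alignment_nt) {
      entry_df <- rbind(entry_df, data.frame(
        group_id = surviving[[nm]]$group_id, reason = "short_alignment",
        detail = sprintf("%s retains %d nt", nm, len),
        stringsAsFactors = FALSE))
    }
  }
  list(entries = entry_df, discarded = discarded, alignments = surviving,
       long_alignments = names(surviving)[
         vapply(surviving, function(a) isTRUE(a$long), logical(1))])
}
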