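#' Call the single longest ORF of a transcript as its CDS
#'
#' Scans the three forward frames of a consensus transcript. Within each
#' frame the codon stream is partitioned into segments bounded by stop
#' codons (and the sequence start); every segment that terminates in a stop
#' codon is a candidate CDS. The longest candidate, including its terminal
#' stop, is returned. An in-frame ATG is *not* required: oligo-dT captured
#' transcripts may have lost their 5' end, so the reported CDS starts at the
#' segment start and may carry non-translated codons upstream of the first
#' ATG. `has_start` records whether an in-frame ATG exists within the
#' segment, in which case the protein is read conventionally from the
#' segment start anyway.
#'
#' Ties on length are broken towards the 5'-most candidate (smallest start
#' coordinate on the transcript), then the lowest frame index. Codons
#' containing IUPAC ambiguity codes are legal and translate to 'X'.
#'
#' @param seq A single DNA string (character scalar).
#' @param id Transcript identifier carried into the record.
#' @return A list of class `cds_record` with elements `transcript_id`,
#'   `frame_offset` (0/1/2, 0-based offset of the first CDS base),
#'   `cds_start` (0-based), `cds_seq`, `protein_seq` (terminal stop
#'   removed), `has_start`, `has_stop` (always `TRUE`), `complete`
#'   (filled by [classify_completeness()]); or `NULL` when no forward frame
#'   contains a stop codon.
#' @seealso [classify_completeness()], [six_frame_stop_check()]
#' @examples
#' find_cds("CCATGAAATGACC")$cds_seq # "ATGAAATGA", frame 2
#' @export
find_cds <- function(seq, id = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  best <- NULL
  for (f in 0:2) {
    codons <- codon_split(seq, f)
    if (length(codons) == 0L) next
    is_stop <- codons %in% STOP_CODONS
    if (!any(is_stop)) next
    stop_idx <- which(is_stop)
    seg_start <- c(1L, head(stop_idx, -1L) + 1L) # codon index of segment start
    seg_len <- stop_idx - seg_start + 1L         # codons incl. terminal stop
    for (k in seq_along(stop_idx)) {
      start0 <- f + (seg_start[k] - 1L) * 3L     # 0-based nt start
      len_nt <- seg_len[k] * 3L
      if (is.null(best) ||
          len_nt > best$len ||
          (len_nt == best$len && start0 < best$start0)) {
        best <- list(len = len_nt, start0 = start0, frame = f)
      }
    }
  }
  if (is.null(best)) return(NULL)
  cds <- substr(seq, best$start0 + 1L, best$start0 + best$len)
  codons <- codon_split(cds)
  rec <- structure(list(
    transcript_id = id,
    frame_offset  = best$frame,
    cds_start     = best$start0,
    cds_seq       = cds,
    protein_seq   = translate_cds(cds, drop_terminal_stop = TRUE),
    has_start     = any(codons == "ATG"),
    has_stop      = TRUE,
    complete      = NA
  ), class = "cds_record")
  rec$complete <- classify_completeness(rec, seq)
  rec
}

#' Classify a called CDS as complete or partial
#'
#' A CDS is complete when it has both an in-frame ATG and a terminal stop
#' codon and occupies at least 60% of the total transcript length.
#'
#' @param cds A `cds_record` from [find_cds()].
#' @param transcript_seq The transcript the CDS was called from.
#' @return Logical scalar.
#' @export
classify_completeness <- function(cds, transcript_seq) {
  stopifnot(inherits(cds, "cds_record"))
  isTRUE(cds$has_start) && isTRUE(cds$has_stop) &&
    nchar(cds$cds_seq) >= 0.6 * nchar(transcript_seq)
}

#' Check for a stop codon in any of the six reading frames
#'
#' Quality screen used by the discard ledger: a transcript with no stop
#' codon in any of the three forward or three reverse-complement frames
#' indicates a sequencing artefact or incomplete 3' coverage.
#'
#' @param seq A single DNA string.
#' @return `TRUE` iff at least one of the 6 frames contains a stop codon.
#' @export
six_frame_stop_check <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  for (s in c(seq, reverse_complement(seq))) {
    for (f in 0:2) {
      if (any(codon_split(s, f) %in% STOP_CODONS)) return(TRUE)
    }
  }
  FALSE
}

#' Translate a CDS under the standard genetic code
#'
#' Codons containing any non-ACGT character become 'X'. Internal stop codons
#' translate to '*' and are preserved — the discard ledger relies on them to
#' flag defective reference CDS annotations. The terminal stop, when
#' present, is dropped by default.
#'
#' @param cds DNA string whose length is a multiple of 3 (hard error
#'   otherwise).
#' @param drop_terminal_stop Drop a trailing stop codon from the protein
#'   (default `TRUE`).
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGTAAAAATGA") # "M*K"
#' @export
translate_cds <- function(cds, drop_terminal_stop = TRUE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length is not divisible by 3: ", nchar(cds))
  }
  codons <- codon_split(toupper(cds))
  if (drop_terminal_stop && length(codons) &&
      codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  if (length(codons) == 0L) return("")
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Call CDSs for a set of transcripts
#'
#' Vectorised wrapper around [find_cds()].
#'
#' @param seqs Named character vector of transcript sequences (names are
#'   transcript ids).
#' @return A list of `cds_record` objects, one per transcript that yielded a
#'   CDS, named by transcript id; transcripts with no stop codon in any
#'   forward frame are omitted.
#' @export
find_cds_set <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  out <- lapply(names(seqs), function(id) find_cds(seqs[[id]], id = id))
  names(out) <- names(seqs)
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf(
    "<cds_record> %s: %d nt CDS at offset %d (frame %d), start %s, %s\n",
    x$transcript_id, nchar(x$cds_seq), x$cds_start, x$frame_offset,
    if (isTRUE(x$has_start)) "present" else "absent",
    if (isTRUE(x$complete)) "complete" else "partial"
  ))
  invisible(x)
}
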