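#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)),
                  sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a syntenic-ortholog table
#'
#' TSV with a `group_id` column and one column per reference species; cells
#' hold one or two comma-separated gene ids, or "." for a missing gene.
#'
#' @param path TSV file.
#' @return data.frame with character columns.
#' @export
read_synteny <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

#' Write a syntenic-ortholog table
#'
#' @param synteny data.frame as produced by [read_synteny()].
#' @param path Output TSV.
#' @export
write_synteny <- function(synteny, path) {
  utils::write.table(synteny, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Serialize a sim_dataset to disk: per-species FASTAs, synteny TSV and a
## truth JSON (gene trees as newick strings).
write_sim_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  for (sp in names(dataset$transcripts)) {
    write_fasta(dataset$transcripts[[sp]],
                file.path(out_dir, paste0(sp, ".transcripts.fa")))
  }
  for (sp in names(dataset$reference_cds)) {
    write_fasta(dataset$reference_cds[[sp]],
                file.path(out_dir, paste0(sp, ".cds.fa")))
  }
  write_synteny(dataset$synteny, file.path(out_dir, "synteny.tsv"))
  truth <- dataset$truth
  truth$gene_trees <- vapply(truth$gene_trees, ape::write.tree, character(1))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
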