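#' Simulation configuration
#'
#' Bundles the knobs of the synthetic transcriptome generator. Defaults
#' emulate the study conditions: ~30% duplicate retention in the maize-like
#' WGD lineage and ~91% in the teff-like lineage; a mean of ~10 redundant
#' consensus transcripts per expressed locus (the observed range is
#' 9.3-12.1 per anchor gene); frequent 5'-truncated isoforms from oligo-dT
#' capture of fragmented mRNA; and low rates of planted sequence defects
#' matching the relative frequencies of the discard-ledger reasons.
#'
#' @param n_genes Number of ortholog groups (loci) to simulate.
#' @param discord_rate Probability a gene tree is perturbed away from the
#'   species topology.
#' @param nni_moves Nearest-neighbour-interchange moves applied to each
#'   perturbed gene tree.
#' @param retention_prob Named numeric: per WGD lineage, probability the
#'   duplicate pair is retained (not fractionated).
#' @param expression_dropout Probability a target-species locus emits no
#'   transcript. Default 0.39, the marginal per-species absence rate of
#'   syntenic anchor genes in the transcript data (coverage 54.2-65.7%).
#' @param isoform_mean Mean redundant transcripts per expressed locus;
#'   emitted count is Poisson(isoform_mean) + 1.
#' @param truncation_prob Probability an isoform loses a uniform fraction
#'   (at most 50%) of its 5' end.
#' @param isoform_error Per-base substitution probability applied
#'   independently to every emitted isoform, emulating residual consensus
#'   error and divergent haplotypes (and ensuring redundant isoforms are
#'   not byte-identical copies).
#' @param defect_rates Named numeric: per-group probabilities of planting
#'   `internal_stop_reference`, `no_stop_six_frames`, `missing_annotation`.
#'   Defaults are the study's per-group discard frequencies
#'   (113/5139, 61/5139, 57/5139).
#' @param root_cds_codons Codons in each root CDS including start and stop
#'   (>= 34 so the CDS spans at least 102 nt).
#' @param branch_length Species-tree branch length (substitutions/site).
#' @param seed Master integer seed; per-gene substreams are derived from
#'   (seed, gene index).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       discord_rate = 0,
                       nni_moves = 1L,
                       retention_prob = c(Zea = 0.30, Eragrostis = 0.91),
                       expression_dropout = 0.39,
                       isoform_mean = 10,
                       truncation_prob = 0.3,
                       isoform_error = 0.005,
                       defect_rates = c(internal_stop_reference = 113 / 5139,
                                        no_stop_six_frames = 61 / 5139,
                                        missing_annotation = 57 / 5139),
                       root_cds_codons = 500L,
                       branch_length = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    discord_rate = discord_rate,
    nni_moves = as.integer(nni_moves),
    retention_prob = retention_prob,
    expression_dropout = expression_dropout,
    isoform_mean = isoform_mean,
    truncation_prob = truncation_prob,
    isoform_error = isoform_error,
    defect_rates = defect_rates,
    root_cds_codons = as.integer(root_cds_codons),
    branch_length = branch_length,
    seed = as.integer(seed)
  )
  probs <- c(cfg$discord_rate, cfg$retention_prob, cfg$expression_dropout,
             cfg$truncation_prob, cfg$isoform_error, cfg$defect_rates)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$root_cds_codons < 34L) stop("root_cds_codons must be >= 34")
  if (!all(wgd_lineages() %in% names(cfg$retention_prob))) {
    stop("retention_prob must name every WGD lineage: ",
         paste(wgd_lineages(), collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d (%d-codon root CDS), discordance %.2f (%d NNI)\n",
              x$n_genes, x$root_cds_codons, x$discord_rate, x$nni_moves))
  cat(sprintf("  WGD retention: %s\n",
              paste(sprintf("%s=%.2f", names(x$retention_prob),
                            x$retention_prob), collapse = ", ")))
  cat(sprintf("  dropout %.2f, isoform mean %.1f, truncation %.2f, seed %d\n",
              x$expression_dropout, x$isoform_mean, x$truncation_prob,
              x$seed))
  invisible(x)
}
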