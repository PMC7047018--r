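Package: panphylo
Title: Transcript-to-Phylogeny Inference for Reference-Free Grass Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for inferring gene-tree topologies from long-read
    consensus transcriptomes of species without reference genomes. Calls a
    single coding sequence per transcript with a stop-required,
    start-optional longest-ORF rule, assigns putative orthology by
    thresholded reciprocal best hits against an anchor reference species,
    joins hits with a syntenic-ortholog table into transitive ortholog
    groups, samples whole-genome-duplication copy combinations, builds
    protein-guided codon alignments filtered to conserved blocks, and
    censuses rooted gene-tree topologies under an outgroup constraint.
    Includes a synthetic transcriptome generator with known gene trees,
    isoform redundancy, 5'-truncation and planted sequence defects so every
    stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
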