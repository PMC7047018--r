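---
title: "From consensus transcripts to a gene-tree topology census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From consensus transcripts to a gene-tree topology census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panphylo)
```

## The problem

Wild grasses rarely have reference genomes, but long-read cDNA sequencing
yields full-length consensus transcripts that can stand in for gene
models. `panphylo` implements the analysis chain that turns such
transcript sets — here for three C3 panicoid grasses (*Chasmanthium*,
*Dichanthelium*, *Hymenachne*) — into phylogenetic evidence, anchored on
eight grass species with published genomes (rice and brachypodium as the
BOP-clade outgroup; oropetium and teff for the Chloridoideae; pearl
millet, foxtail millet, sorghum and maize for the Panicoideae). The
chain is:

1. **CDS calling** — one coding sequence per consensus transcript.
2. **Orthology** — reciprocal best hits (RBH) against the sorghum anchor,
   joined transitively with a syntenic-ortholog table.
3. **Alignment QC** — protein-guided codon alignments, conserved-block
   filtering, a discard ledger for defective groups.
4. **Topology census** — one neighbor-joining tree per alignment, rooted
   on the outgroup pair, canonicalized and tallied.

A synthetic-data generator with full ground truth (gene trees, ortholog
map, WGD retention, planted defects) backs every stage's tests.

## CDS calling

Oligo-dT capture recovers 3' ends of fragmented mRNAs, so a transcript
may lack its true start codon. The caller therefore requires an in-frame
stop but not an ATG: each forward frame is partitioned into
stop-bounded segments, every stop-terminated segment is a candidate, and
the longest candidate (ties: 5'-most, then lowest frame) becomes the
CDS, possibly with non-translated codons appended 5' of the first ATG.
A CDS is *complete* when it has an in-frame ATG, a stop, and covers at
least 60% of the transcript. A separate six-frame stop scan feeds the
discard ledger: a transcript with no stop codon in any of the six frames
indicates a sequencing artefact or missing 3' coverage.

Decisions the rule leaves open, fixed here: nested ORFs are not
considered (segments start after the previous stop); codons containing
ambiguity codes are legal and translate to `X`; coordinates are 0-based,
half-open.

## Orthology

The similarity search is an exact affine-gap local alignment
(match +1, mismatch −1, gap open −2, gap extend −1, ambiguity codes
neutral) implemented in C. Hits must reach 70% identity
(matches / aligned columns) and 50% query coverage (aligned query bases /
query length) — the operating point of the original search. Candidate
pairs are seeded by shared exact 12-mers (3 or more), mirroring a
`match12` seed; inside the pipeline the dynamic program is additionally
restricted to a ±150 diagonal band centred on the median seed diagonal,
which is exact whenever the optimal alignment stays near one diagonal —
the case for orthologous coding sequences — and roughly ten times
faster. `similarity_search()` exposes the unbanded search.

A transcript and an anchor gene are orthologous when each is the other's
top-scoring hit. Because a locus emits many redundant isoforms,
exact score ties between isoforms are generic; ties are broken
deterministically (identity, then coverage, then smallest id) rather
than discarding the query — the reciprocity requirement is what guards
against arbitrary cross-locus orthology. Per anchor gene, one
representative transcript is kept: highest score, then longest CDS, then
smallest id.

Orthology is transitive: a transcript paired with an anchor gene joins
every syntenic ortholog in that gene's row of the synteny table. Groups
are categorized 0-3 by how many of the three target species contributed
a representative; only category-3 groups are aligned.

## WGD sampling and alignment QC

Maize-lineage and teff-lineage whole-genome duplications leave some
groups with two co-orthologous copies in those species. To keep every
gene tree at one leaf per species, each combination of one copy per
retained lineage becomes its own alignment: 1, 2 or 4 samples per group.

Alignments are protein-guided: proteins are aligned (internal
center-star aligner with BLOSUM62 scoring by default; a `mafft` adapter
is provided), then each residue is expanded back to its source codon, so
gaps occur only in whole-codon units and degapping any row reproduces
its input CDS. Conserved-block filtering then reimplements the classic
default-parameter block filter on the protein projection: a column is
conserved when its majority residue occurs in more than half the
sequences (ties count as nonconserved), highly conserved at 85%; gap
columns are never retained; runs of more than 8 nonconserved columns
break blocks; flanks must be highly conserved; blocks under 10 columns
are dropped. Alignments whose retained length reaches 900 nt
(300 codons) form the "long" subset; shorter ones stay in the all-genes
analysis. The threshold is applied to the *retained* (post-filter)
length.

The discard ledger removes a group when a reference CDS translates with
an internal stop, when a transcript attached to the group has no stop in
any of six frames, or when a synteny-table id has no sequence (the
generalization of annotation version drift). Transcripts with no
callable CDS are attached to their group by shared 12-mer vote so the
six-frame screen can see them.

## Trees and the census

The default tree builder is neighbor joining on Jukes-Cantor distances
over the retained columns; saturated distances (p ≥ 0.75) are clamped
to 5 substitutions/site. An external maximum-likelihood builder can be
plugged in as a function. A tree is accepted only if the outgroup pair
(rice, brachypodium) forms its own bipartition, in which case the tree
is rooted on that edge; rejections are ledgered. Accepted rooted trees
are canonicalized — branch lengths stripped, children recursively sorted
— and tallied; percentages are *truncated* to one decimal, the
convention the study's printed percentages follow (e.g. 291/684 → 42.5).
Bootstrap support resamples retained codon columns, rebuilds trees, and
averages per-branch support across the groups sharing a topology.

## The synthetic-data generator

`simulate_dataset()` emulates the study conditions with known truth:

* the fixed 11-taxon species topology, branch lengths defaulting to
  0.05 substitutions/site per edge (the study gives no divergence
  depths; this yields ~75-85% pairwise CDS identity between target and
  anchor species, comfortably inside the 70% search threshold);
* gene trees equal to the species tree, or perturbed by
  nearest-neighbour interchanges with probability `discord_rate`
  (the moves never break the outgroup pair, so rooting stays defined —
  NNI rather than coalescent simulation because it controls topological
  distance directly, with no population-size parameter);
* Jukes-Cantor substitution with p = 3/4·(1 − exp(−4b/3)) per site,
  resampling mutations that create internal stops (simpler than the
  GTR+Γ model used for inference on the real data, but sufficient to
  exercise topology recovery); the terminal stop codon is held fixed;
* WGD duplicate retention with probability 0.30 (maize-like) and 0.91
  (teff-like) per lineage, the study's syntenic retention rates;
* per-locus isoform redundancy Poisson(10)+1 (observed: 9.3-12.1
  consensus transcripts per anchor gene), 100 nt 5' and 150 nt 3' UTR
  padding with stop cassettes seeded in all frames so the planted CDS is
  the longest ORF by construction, 5'-truncation of up to 50% with
  probability 0.3 (emulating oligo-dT capture of fragmented mRNA), and
  a 0.5% per-base isoform substitution error emulating residual
  consensus error and divergent haplotypes;
* expression dropout 0.39 per target species and locus, the marginal
  absence rate of syntenic anchor genes in the transcript data
  (54-66% coverage);
* planted defects at the study's per-group discard frequencies
  (113/5139 internal reference stop, 61/5139 stop-free transcript,
  57/5139 missing annotation).

What the generator does *not* emulate: indels and splice isoform
structure (isoforms differ by substitutions, truncation and UTRs only),
codon-usage bias, correlated expression dropout across species (real
unexpressed genes are missing from all three species far more often
than independence predicts), paralogous gene families beyond the two
WGD events, and PacBio error profiles. Passing tests therefore
demonstrate correctness of the chain's logic under controlled
conditions, not robustness to every artefact of real long-read data.

Determinism: every gene uses a substream seed derived from
(master seed, gene index), so outputs are byte-identical across runs
and the first k genes do not change when `n_genes` grows.

## Numerical and design choices

* Score ties in best-hit ranking: broken by identity, coverage, then id
  (see Orthology above). Majority-residue ties in block filtering:
  nonconserved (conservative).
* Distances: computed with pairwise deletion; after filtering there are
  no gap columns, so this only matters for degenerate inputs.
* Fewer than 4 taxa, or an alignment retaining less than one codon, is a
  hard error in tree building; the pipeline skips zero-retention
  alignments (they carry no signal and are already flagged as short),
  and an empty census is a valid result.
* Problem sizes used by the test-suite and the acceptance script —
  ORF oracle on 1,000 random sequences, 100 random additive quartets,
  a 200-gene dataset for RBH precision/recall, 50-gene datasets
  (500-codon CDSs) for end-to-end topology recovery — were chosen as the
  smallest scales at which the corresponding properties are
  statistically meaningful.
* Within-alignment bootstrap signal is unaffected by between-gene
  discordance in this design (each simulated gene tree is internally
  coherent), so support values are expected to be flat, not decreasing,
  as `discord_rate` rises; the support checks therefore assert bounds
  and determinism, not a trend.

## Worked example

```{r example, eval = FALSE}
library(panphylo)

cfg <- sim_config(n_genes = 50, root_cds_codons = 500,
                  discord_rate = 0.3, truncation_prob = 0.2, seed = 1)
ds <- simulate_dataset(cfg)
res <- run_pipeline(ds$transcripts, ds$reference_cds, ds$synteny)
summary(res)
res$census$topology[1] == canonical_topology(species_tree())
```

On this configuration 11 of the 50 groups reach category 3; one is
ledgered for a planted missing annotation, the rest yield 23 alignments
after WGD combination sampling. All 23 trees pass the outgroup
constraint and the species topology ranks first (15 of 23 trees at
`discord_rate = 0.3`; 23 of 23 at 0).

## Known limitations

Groups are anchored strictly on the sorghum-like species; a transcript
whose best anchor sits in two merged synteny rows would be attached to
the first (rows are assumed disjoint on anchor ids). The center-star
protein aligner is adequate for closely related orthologs but is not a
general MSA method — use the `mafft` adapter for divergent groups. The
internal NJ builder replaces maximum likelihood for speed and
determinism; an external builder preserves the original method where
exactness matters.
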