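mk_group <- function(zea, erag) {
  members <- list(
    Oryza = "o1", Brachypodium = "b1", Oropetium = "p1",
    Eragrostis = erag, Pennisetum = "pn1", Setaria = "s1",
    Sorghum = "sb1", Zea = zea,
    Chasmanthium = "tc", Dichanthelium = "td", Hymenachne = "th")
  retention <- c(
    Zea = if (length(zea) == 2) "retained" else "fractionated",
    Eragrostis = if (length(erag) == 2) "retained" else "fractionated")
  list(group_id = "g1", members = members, category = 3L,
       retention = retention)
}

test_that("combination sampling follows the 1/2/4 law", {
  expect_length(enumerate_combinations(mk_group("z1", "e1")), 1L)
  expect_length(enumerate_combinations(mk_group(c("z1", "z2"), "e1")), 2L)
  expect_length(enumerate_combinations(mk_group("z1", c("e1", "e2"))), 2L)
  combos <- enumerate_combinations(mk_group(c("z1", "z2"), c("e1", "e2")))
  expect_length(combos, 4L)
  ## every copy pairing appears exactly once, one leaf per species in each
  pairs <- vapply(combos, function(s) {
    paste(s$leaf_selection[["Zea"]], s$leaf_selection[["Eragrostis"]])
  }, character(1))
  expect_setequal(pairs, c("z1 e1", "z1 e2", "z2 e1", "z2 e2"))
  for (s in combos) {
    expect_setequal(names(s$leaf_selection),
                    c(reference_species(), target_species()))
  }
  g <- mk_group("z1", "e1")
  g$category <- 2L
  expect_error(enumerate_combinations(g), "category")
})

test_that("codon alignment round-trips every input CDS", {
  cds <- c(a = "ATGAAACCCGGGTGA", b = "ATGAAACCCGGGTAA")
  aln <- codon_align(cds)
  expect_equal(aln$ncol, 15L)
  expect_equal(unname(gsub("-", "", aln$rows)), unname(cds))

  ## clean one-codon insertion gets a single 3-nt gap in the shorter row
  cds2 <- c(x = "ATGAAATTTCCCGGGTGA", y = "ATGAAACCCGGGTGA")
  aln2 <- codon_align(cds2)
  expect_equal(aln2$ncol, 18L)
  expect_equal(unname(gsub("-", "", aln2$rows)), unname(cds2))
  gaps <- gregexpr("-+", aln2$rows[["y"]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 3L)
})

test_that("codon alignment round-trips on random synthetic groups", {
  set.seed(13)
  cfg <- clean_config(n_genes = 4L, seed = 61L)
  ds <- simulate_dataset(cfg)
  for (r in 1:4) {
    cds <- vapply(reference_species(), function(sp) {
      ds$reference_cds[[sp]][[strsplit(ds$synteny[[sp]][r], ",")[[1]][1]]]
    }, character(1))
    aln <- codon_align(cds)
    expect_equal(unname(nchar(aln$rows)), rep(aln$ncol, length(cds)))
    expect_equal(aln$ncol %% 3, 0)
    expect_equal(gsub("-", "", aln$rows[names(cds)]), cds)
    ## gaps only in whole-codon units
    for (row in aln$rows) {
      g <- gregexpr("-+", row)[[1]]
      if (g[1] != -1) {
        expect_true(all(attr(g, "match.length") %% 3 == 0))
        expect_true(all((g - 1) %% 3 == 0))
      }
    }
  }
})

test_that("mafft adapter matches the internal aligner contract", {
  cds <- c(a = "ATGAAACCCGGGACTTGA", b = "ATGAAATTTCCCGGGACTTAA",
           c = "ATGAAACCCGGAACTTGA")
  aln <- codon_align(cds, protein_aligner = "mafft")
  expect_equal(gsub("-", "", aln$rows[names(cds)]), cds)
  expect_equal(length(unique(nchar(aln$rows))), 1L)
})

test_that("block filtering keeps conserved blocks and drops gapped columns", {
  ## identical gapless alignment: everything retained except terminal stop
  cds <- c(a = paste0("ATG", strrep("GCT", 20), "TGA"),
           b = paste0("ATG", strrep("GCT", 20), "TGA"))
  aln <- filter_blocks(codon_align(cds))
  expect_equal(length(aln$mask), 21L * 3L)
  expect_equal(aln$mask, 0:62)

  ## a gap column is never retained
  cds2 <- c(x = paste0("ATG", strrep("GCT", 20), "TGA"),
            y = paste0("ATG", strrep("GCT", 19), "TGA"))
  aln2 <- filter_blocks(codon_align(cds2))
  rowx <- aln2$rows[["x"]]
  gap_cols <- which(strsplit(aln2$rows[["y"]], "")[[1]] == "-") - 1L
  expect_false(any(gap_cols %in% aln2$mask))
})

test_that("long nonconserved runs break blocks per the stated rules", {
  ## protein design over 4 sequences: 12 identical cols, 9 diverse cols,
  ## 12 identical cols. Oracle: direct evaluation of the stated rules.
  set.seed(3)
  n_seq <- 4
  aas <- c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L")
  block <- function(k) strrep("K", k)
  mids <- replicate(n_seq, paste(sample(aas, 9, TRUE), collapse = ""))
  ## ensure every middle column is nonconserved (all residues distinct)
  mid_mat <- matrix(c("A", "R", "N", "D"), nrow = n_seq, ncol = 9)
  mids <- apply(mid_mat, 1, paste, collapse = "")
  prots <- paste0(block(12), mids, block(12))
  ## reverse-translate to a gapless codon alignment
  codon_of <- c(K = "AAA", A = "GCT", R = "CGT", N = "AAT", D = "GAT")
  cds <- vapply(prots, function(p) {
    paste0(paste(codon_of[strsplit(p, "")[[1]]], collapse = ""), "TGA")
  }, character(1))
  names(cds) <- paste0("s", seq_len(n_seq))
  aln <- codon_align(cds)
  aln <- filter_blocks(aln)
  ## two 12-column blocks survive; the 9-column run is excluded
  expect_equal(length(aln$mask), 2L * 12L * 3L)
  prot_cols <- unique(aln$mask %/% 3) + 1L
  expect_setequal(prot_cols, c(1:12, 22:33))

  ## mask monotonicity: a larger minimum block length never grows the mask
  m10 <- filter_blocks(aln, min_block = 10L)$mask
  m13 <- filter_blocks(aln, min_block = 13L)$mask
  expect_true(all(m13 %in% m10))
})

test_that("ties for the majority residue count as nonconserved", {
  ## 4 sequences, column split 2/2: tie -> nonconserved
  cds <- c(a = paste0(strrep("AAA", 12), "GCT", strrep("AAA", 12), "TGA"),
           b = paste0(strrep("AAA", 12), "GCT", strrep("AAA", 12), "TGA"),
           c = paste0(strrep("AAA", 12), "CGT", strrep("AAA", 12), "TGA"),
           d = paste0(strrep("AAA", 12), "CGT", strrep("AAA", 12), "TGA"))
  aln <- filter_blocks(codon_align(cds))
  ## the tied column (protein col 13) is nonconserved but inside a block,
  ## so it is retained; flanks trim to highly conserved columns
  expect_true(all(c(36, 37, 38) %in% aln$mask))
})
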