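test_that("neighbor joining recovers the quartet of additive distances", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_equal(quartet_split(tr), "AB|CD")
  expect_equal(quartet_oracle(d), "AB|CD")
})

test_that("neighbor joining matches the least-squares quartet oracle on
           random additive matrices", {
  set.seed(101)
  hits <- 0L
  for (i in 1:100) {
    ## random additive quartet: internal branch + 4 terminal branches
    tb <- stats::runif(4, 0.5, 3)
    ib <- stats::runif(1, 0.3, 2)
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    pair <- function(i, j, v) d[i, j] <<- d[j, i] <<- v
    pair(1, 2, tb[1] + tb[2])
    pair(3, 4, tb[3] + tb[4])
    pair(1, 3, tb[1] + ib + tb[3])
    pair(1, 4, tb[1] + ib + tb[4])
    pair(2, 3, tb[2] + ib + tb[3])
    pair(2, 4, tb[2] + ib + tb[4])
    ## shuffle labels so the generating split varies
    perm <- sample(4)
    d <- d[perm, perm]
    hits <- hits + (quartet_split(nj_tree(d)) == quartet_oracle(d))
  }
  expect_equal(hits, 100L)
})

test_that("identical sequences give a star-like zero-length tree", {
  cds <- stats::setNames(rep(paste0("ATG", strrep("GCTAAGGTT", 12), "TGA"),
                             5), paste0("t", 1:5))
  aln <- filter_blocks(codon_align(cds))
  tr <- build_tree(aln)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length < 1e-8))
  expect_error(build_tree(filter_blocks(codon_align(cds[1:3]))), "4 taxa")
})

test_that("trees built from alignments evolved on a known tree recover it", {
  set.seed(19)
  cfg <- clean_config(n_genes = 30L, root_cds_codons = 500L, seed = 83L,
                      branch_length = 0.05)
  sp <- species_tree(0.05)
  gts <- simulate_gene_trees(sp, cfg)
  ds <- evolve_and_emit(gts, cfg)
  ok <- 0L
  for (r in seq_len(30)) {
    cds <- vapply(reference_species(), function(s) {
      ds$reference_cds[[s]][[strsplit(ds$synteny[[s]][r], ",")[[1]][1]]]
    }, character(1))
    aln <- filter_blocks(codon_align(cds))
    tr <- build_tree(aln)
    ref <- ape::keep.tip(sp, reference_species())
    ok <- ok + (ape::dist.topo(ape::unroot(tr), ape::unroot(ref)) == 0)
  }
  expect_gte(ok, ceiling(0.95 * 30))
})

test_that("outgroup check roots on the outgroup edge or rejects", {
  good <- ape::read.tree(text = "((Oryza,Brachypodium),(X,(Y,Z)));")
  rt <- check_outgroup_and_root(good)
  expect_false(is.null(rt))
  expect_true(ape::is.monophyletic(rt, c("Oryza", "Brachypodium")))

  bad <- ape::read.tree(text = "((Oryza,X),(Brachypodium,(Y,Z)));")
  expect_null(check_outgroup_and_root(bad))

  four <- ape::read.tree(text = "((Oryza,Brachypodium),(X,Y));")
  rt4 <- check_outgroup_and_root(four)
  expect_false(is.null(rt4))
  kids <- rt4$edge[rt4$edge[, 1] == length(rt4$tip.label) + 1L, 2]
  expect_length(kids, 2L)

  expect_error(check_outgroup_and_root(
    ape::read.tree(text = "((A,B),(C,D));")), "missing")
})

test_that("canonical topology is invariant to rotation and leaf order", {
  t1 <- ape::read.tree(text = "((B,A),(D,C));")
  t2 <- ape::read.tree(text = "((C,D),(A,B));")
  expect_identical(canonical_topology(t1), canonical_topology(t2))
  t3 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_false(identical(canonical_topology(t1), canonical_topology(t3)))

  ## 100 random rotations of one 11-taxon tree collapse to one string
  set.seed(29)
  base <- species_tree()
  canon <- canonical_topology(base)
  for (i in 1:100) {
    rot <- base
    for (nd in sample(12:21, 3)) rot <- ape::rotate(rot, nd)
    nwk <- ape::write.tree(rot)
    expect_identical(canonical_topology(ape::read.tree(text = nwk)), canon)
  }
  dup <- ape::read.tree(text = "((A,A),(B,C));")
  expect_error(canonical_topology(dup), "duplicate")
})

test_that("canonicalization is idempotent through newick round-trips", {
  set.seed(31)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    c1 <- canonical_topology(tr)
    tr2 <- ape::read.tree(text = paste0(c1, ";"))
    expect_identical(canonical_topology(tr2), c1)
  }
})

test_that("census tallies, sorts and truncates percentages", {
  t_a <- ape::read.tree(text = "((A,B),(C,D));")
  t_b <- ape::read.tree(text = "((A,C),(B,D));")
  cen <- topology_census(list(t_a, t_a, t_a, t_b, t_b))
  expect_equal(cen$count, c(3L, 2L))
  expect_equal(cen$rank, 1:2)
  expect_equal(cen$percent, c(60, 40))
  expect_equal(sum(cen$count), 5L)
  expect_equal(nrow(topology_census(list())), 0L)
})

test_that("census percentages follow the truncation convention", {
  ## 684 trees, 291 + 43 + 28 across three topologies, remainder spread
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  t3 <- ape::read.tree(text = "((A,D),(B,C));")
  t4 <- ape::read.tree(text = "(A,(B,(C,D)));")
  t5 <- ape::read.tree(text = "(B,(A,(C,D)));")
  trees <- c(rep(list(t1), 291), rep(list(t2), 43), rep(list(t3), 28),
             rep(list(t4), 200), rep(list(t5), 684 - 291 - 43 - 28 - 200))
  cen <- topology_census(trees)
  expect_equal(sum(cen$count), 684L)
  expect_equal(cen[cen$count == 291, ]$percent, 42.5)
  expect_equal(cen[cen$count == 43, ]$percent, 6.2)
  expect_equal(cen[cen$count == 28, ]$percent, 4.0)
})

test_that("bootstrap support is deterministic, bounded and saturates on
           clean signal", {
  cds <- list()
  set.seed(37)
  ds <- simulate_dataset(clean_config(n_genes = 2L, root_cds_codons = 400L,
                                      seed = 89L))
  alns <- list()
  for (r in 1:2) {
    cdsr <- vapply(reference_species(), function(s) {
      ds$reference_cds[[s]][[strsplit(ds$synteny[[s]][r], ",")[[1]][1]]]
    }, character(1))
    alns[[paste0("g", r)]] <- filter_blocks(codon_align(cdsr))
  }
  b1 <- bootstrap_support(alns, n_sample = 2L, reps = 25L, seed = 11L)
  b2 <- bootstrap_support(alns, n_sample = 2L, reps = 25L, seed = 11L)
  expect_identical(b1, b2)
  sup <- unlist(lapply(b1, `[[`, "support"))
  expect_true(all(sup >= 0 & sup <= 100))
  ## 1200 nt of clean signal at moderate divergence: near-full support
  expect_gt(mean(sup), 85)
  ## single replicate gives supports in {0, 100} only
  b3 <- bootstrap_support(alns, n_sample = 1L, reps = 1L, seed = 13L)
  expect_true(all(unlist(lapply(b3, `[[`, "support")) %in% c(0, 100)))
  expect_error(bootstrap_support(alns, n_sample = 5L, reps = 2L), "exceeds")
})
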