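test_that("species tree has the fixed 11-taxon study topology", {
  tr <- species_tree()
  expect_equal(length(tr$tip.label), 11L)
  expect_true(ape::is.monophyletic(tr, c("Oryza", "Brachypodium")))
  expect_true(ape::is.monophyletic(tr, c("Hymenachne", "Sorghum", "Zea")))
  expect_true(ape::is.monophyletic(tr, c("Oropetium", "Eragrostis")))
  expect_equal(sort(tr$tip.label),
               sort(c(target_species(), reference_species())))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(discord_rate = 1.2), "probabilities")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(root_cds_codons = 10), "root_cds_codons")
})

test_that("gene trees match the species tree when discordance is off", {
  cfg <- clean_config(n_genes = 20L, discord_rate = 0)
  gts <- simulate_gene_trees(species_tree(), cfg)
  expect_length(gts, 20L)
  canon <- canonical_topology(species_tree())
  for (gt in gts) expect_equal(canonical_topology(gt), canon)
})

test_that("one NNI move yields Robinson-Foulds distance exactly 2", {
  cfg <- clean_config(n_genes = 25L, discord_rate = 1, nni_moves = 1L,
                      seed = 17L)
  sp <- species_tree()
  gts <- simulate_gene_trees(sp, cfg)
  for (gt in gts) {
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(sp),
                                           ape::unroot(gt))), 2)
    ## outgroup pair survives every move
    expect_true(ape::is.monophyletic(gt, c("Oryza", "Brachypodium")))
  }
})

test_that("perturbed trees keep the outgroup pair under many moves", {
  cfg <- clean_config(n_genes = 15L, discord_rate = 1, nni_moves = 5L,
                      seed = 23L)
  gts <- simulate_gene_trees(species_tree(), cfg)
  for (gt in gts) {
    expect_true(ape::is.monophyletic(gt, c("Oryza", "Brachypodium")))
  }
})

test_that("emitted transcripts carry the planted CDS when not truncated", {
  cfg <- sim_config(n_genes = 6L, root_cds_codons = 80L,
                    expression_dropout = 0, truncation_prob = 0,
                    isoform_mean = 2, isoform_error = 0,
                    defect_rates = c(internal_stop_reference = 0,
                                     no_stop_six_frames = 0,
                                     missing_annotation = 0),
                    seed = 31L)
  ds <- simulate_dataset(cfg)
  truthmap <- vapply(ds$truth$ortholog_map, function(m) m$group_id,
                     character(1))
  for (sp in target_species()) {
    for (tid in names(ds$transcripts[[sp]])) {
      gid <- truthmap[[tid]]
      ## the species' evolved CDS must sit inside the emitted transcript,
      ## and the longest-ORF caller must recover it exactly
      r <- find_cds(ds$transcripts[[sp]][[tid]], tid)
      expect_equal(nchar(r$cds_seq), 80L * 3L)
      expect_true(grepl(r$cds_seq, ds$transcripts[[sp]][[tid]], fixed = TRUE))
    }
  }
})

test_that("WGD retention probabilities control duplicate copies", {
  cfg <- clean_config(n_genes = 8L,
                      retention_prob = c(Zea = 1, Eragrostis = 1))
  ds <- simulate_dataset(cfg)
  for (r in seq_len(nrow(ds$synteny))) {
    expect_length(strsplit(ds$synteny$Zea[r], ",")[[1]], 2L)
    expect_length(strsplit(ds$synteny$Eragrostis[r], ",")[[1]], 2L)
  }
  cfg0 <- clean_config(n_genes = 8L,
                       retention_prob = c(Zea = 0, Eragrostis = 0))
  ds0 <- simulate_dataset(cfg0)
  expect_false(any(grepl(",", ds0$synteny$Zea)))
  expect_false(any(grepl(",", ds0$synteny$Eragrostis)))
})

test_that("isoform counts average near Poisson(mean)+1", {
  cfg <- sim_config(n_genes = 200L, root_cds_codons = 40L,
                    expression_dropout = 0, isoform_mean = 10,
                    truncation_prob = 0,
                    defect_rates = c(internal_stop_reference = 0,
                                     no_stop_six_frames = 0,
                                     missing_annotation = 0),
                    seed = 41L)
  tr <- species_tree(cfg$branch_length)
  gts <- simulate_gene_trees(tr, cfg)
  ds <- evolve_and_emit(gts, cfg)
  ## direct tally of emitted records per locus for one species
  loci <- sub("_iso[0-9]+$", "", names(ds$transcripts$Chasmanthium))
  mean_iso <- mean(table(loci))
  expect_lt(abs(mean_iso - 11) / 11, 0.10)
})

test_that("reference CDSs are stop-free internally when defects are off", {
  ds <- simulate_dataset(clean_config(n_genes = 10L, seed = 47L))
  for (sp in reference_species()) {
    for (s in ds$reference_cds[[sp]]) {
      expect_false(grepl("*", translate_cds(s), fixed = TRUE))
    }
  }
})

test_that("every emitted transcript id maps to the truth and back", {
  ds <- simulate_dataset(fast_defect_config())
  emitted <- unlist(lapply(ds$transcripts, names), use.names = FALSE)
  expect_setequal(emitted, names(ds$truth$ortholog_map))
  ## wgd status defined for every group x lineage
  expect_setequal(names(ds$truth$wgd_status), ds$synteny$group_id)
  for (st in ds$truth$wgd_status) {
    expect_setequal(names(st), wgd_lineages())
    expect_true(all(st %in% c("retained", "fractionated")))
  }
})

test_that("identical config and seed reproduce byte-identical outputs", {
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  simulate_dataset(fast_defect_config(seed = 8L), out_dir = d1)
  simulate_dataset(fast_defect_config(seed = 8L), out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})
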