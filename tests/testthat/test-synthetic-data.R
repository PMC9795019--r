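test_that("invalid configurations are refused with clear messages", {
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(mean_count = -1), "mean_count")
  expect_error(sim_config(degradome_peak_fraction = 0), "peak_fraction")
  expect_error(sim_config(degradome_peak_fraction = 1.2), "peak_fraction")
  expect_error(sim_config(design = bloom_design(replicates = 1)))
})

test_that("identical configs give byte-identical emitted files", {
  cfg <- small_config(seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bloom_sim(simulate_bloom_dataset(cfg), d1)
  write_bloom_sim(simulate_bloom_dataset(cfg), d2)
  f1 <- sort(list.files(d1))
  f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("gp3 matures are absent from the genome and gp4 absent from the references", {
  sim <- simulate_bloom_dataset(small_config(seed = 8))
  tr <- sim$truth$mirnas
  for (s in tr$sequence[tr$group == "gp3"]) {
    expect_equal(nrow(map_tag(s, sim$genome, 0, "both")), 0)
  }
  for (s in tr$sequence[tr$group == "gp4"]) {
    expect_equal(nrow(map_tag(s, sim$reference$mature, 0, "plus")), 0)
    expect_equal(nrow(map_tag(s, sim$reference$precursor, 0, "plus")), 0)
  }
})

test_that("the reference has the planted record count and gp1 precursors map uniquely", {
  cfg <- small_config(seed = 8)
  sim <- simulate_bloom_dataset(cfg)
  n_known <- sum(cfg$n_mir[c("gp1", "gp2a", "gp2b", "gp3")])
  expect_length(sim$reference$mature, n_known)
  expect_length(sim$reference$precursor, n_known)
  tr <- sim$truth$mirnas
  for (id in tr$id[tr$group == "gp1"]) {
    hits <- map_tag(sim$reference$precursor[[paste0(id, "_pre")]],
                    sim$genome, 0, "both")
    expect_equal(nrow(hits[hits$strand == "+", ]), 1, info = id)
  }
  # gp2a/gp2b/gp3 precursors are genome-absent
  for (id in tr$id[tr$group %in% c("gp2a", "gp2b", "gp3")]) {
    expect_equal(nrow(map_tag(sim$reference$precursor[[paste0(id, "_pre")]],
                              sim$genome, 0, "both")), 0, info = id)
  }
})

test_that("planted effects shift negative-binomial means by the configured fold change", {
  # a dedicated truth with many affected transcripts, to estimate the
  # empirical mean ratio at Monte-Carlo precision
  cfg <- sim_config(seed = 31, n_transcripts = 600L,
                    n_planted_modules = 0L, n_extra_de_mirna = 0L,
                    n_extra_de_mrna = 0L)
  gen <- simulate_genome(cfg)
  truth <- gen$truth
  ids <- truth$transcripts_plan$transcript_id[1:500]
  truth$cell_effects <- tibble::tibble(
    feature_id = ids, feature_type = "mrna",
    genotype = "FD", stage = "DE", log2fc = 2
  )
  cnt <- simulate_counts(cfg, truth)
  de_libs <- paste0("FD_DE_", 1:3)
  bs_libs <- paste0("FD_BS_", 1:3)
  aff <- cnt$mrna_counts[match(ids, cnt$mrna_counts$transcript_id), ]
  ratio <- mean(as.matrix(aff[de_libs])) / mean(as.matrix(aff[bs_libs]))
  # NB with mu=100, phi=0.05: SE of the ratio over 1500 draws ~ 1.5%
  expect_equal(ratio, 4, tolerance = 0.05)
  # null features stay flat
  rest <- cnt$mrna_counts[!cnt$mrna_counts$transcript_id %in% ids, ]
  ratio0 <- mean(as.matrix(rest[de_libs])) / mean(as.matrix(rest[bs_libs]))
  expect_equal(ratio0, 1, tolerance = 0.1)
})

test_that("a zero-effect configuration plants no differential truth", {
  cfg <- small_config(seed = 14, effect_log2fc = 0)
  sim <- simulate_bloom_dataset(cfg)
  expect_true(all(sim$truth$cell_effects$log2fc == 0))
  expect_true(all(sim$truth$de_contrasts$log2fc == 0))
})

test_that("the decoy out-of-range fraction is respected and removed by the filter", {
  cfg <- small_config(seed = 15, n_decoy_tags = 1000L,
                      decoy_out_fraction = 0.2)
  sim <- simulate_bloom_dataset(cfg)
  decoys <- setdiff(sim$srna_tags$sequence, sim$truth$mirnas$sequence)
  out <- sum(!nchar(decoys) %in% 18:26)
  # the generator draws round(n * fraction) out-of-range lengths; the only
  # slack is duplicate-sequence removal
  expect_equal(out, 200, tolerance = 0.02)
  kept <- filter_and_collapse(sim$srna_tags, quiet = TRUE)
  expect_true(all(nchar(kept$sequence) %in% 18:26))
})

test_that("degradome truth positions respect transcript bounds and fail loudly otherwise", {
  sim <- simulate_bloom_dataset(small_config(seed = 4))
  bad_truth <- sim$truth
  bad_truth$cleavages$position[1] <- 10 * max(sim$exon_lengths$length)
  expect_error(simulate_degradome(sim$config, bad_truth, sim$exon_lengths),
               "bounds")
})

test_that("transcripts without planted sites show no dominant degradome position", {
  cfg <- small_config(seed = 22, degradome_background_rate = 8)
  sim <- simulate_bloom_dataset(cfg)
  quiet_tx <- setdiff(sim$exon_lengths$transcript_id,
                      sim$truth$cleavages$transcript_id)
  dg <- sim$degradome[sim$degradome$transcript_id %in% quiet_tx &
                        sim$degradome$genotype == "FD", ]
  shares <- vapply(split(dg$count, dg$transcript_id),
                   function(x) max(x) / sum(x), numeric(1))
  # uniform single-count background: no position should dominate the way a
  # planted peak (>= 90% share) does
  expect_true(all(shares <= 0.5))
})

test_that("the cross-file truth audit passes on generated data and catches corruption", {
  sim <- simulate_bloom_dataset(small_config(seed = 3))
  expect_length(audit_sim(sim), 0)
  broken <- sim
  broken$degradome <- broken$degradome[0, ]
  expect_gt(length(audit_sim(broken)), 0)
})
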