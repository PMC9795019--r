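make_hairpin_genome <- function(mature, loop_len = 8, pad = 150) {
  cassette <- paste0(mature, random_seq(loop_len), oracle_revcomp(mature))
  g <- c(chr = paste0(random_seq(pad), cassette, random_seq(pad)))
  list(genome = g, start = pad + 1, end = pad + nchar(mature))
}

test_that("a perfect inverted repeat is accepted with a fully paired stem", {
  set.seed(21)
  mature <- random_seq(21)
  hp_g <- make_hairpin_genome(mature, loop_len = 8)
  hp <- fold_back(hp_g$genome, "chr", hp_g$start, hp_g$end, "+")
  expect_true(hp$accepted)
  expect_equal(hp$n_paired, 21)
  expect_equal(hp$largest_bulge, 0)
  expect_equal(hp$loop_size, 8)
  expect_equal(hp$arm, "5p")
  expect_equal(nchar(hp$precursor), nchar(hp$structure))
  # balanced dot-bracket
  db <- strsplit(hp$structure, "")[[1]]
  expect_equal(sum(db == "("), sum(db == ")"))
})

test_that("a mature inside homopolymer flanks is rejected for lack of pairing", {
  mature <- "ACGTACGTACGTACGTACGTA"
  g <- c(chr = paste0(strrep("A", 150), mature, strrep("A", 150)))
  hp <- fold_back(g, "chr", 151, 151 + nchar(mature) - 1, "+")
  expect_false(hp$accepted)
  expect_equal(hp$reason, "too_few_paired")
})

test_that("fold_back is symmetric under reverse-complementing the locus", {
  set.seed(33)
  for (i in 1:5) {
    mature <- random_seq(sample(20:24, 1))
    hp_g <- make_hairpin_genome(mature, loop_len = sample(4:15, 1))
    fwd <- fold_back(hp_g$genome, "chr", hp_g$start, hp_g$end, "+")
    # same locus on the reverse-complemented contig, minus strand
    glen <- nchar(hp_g$genome[["chr"]])
    rc_genome <- c(chr = oracle_revcomp(hp_g$genome[["chr"]]))
    rc_start <- glen - hp_g$end + 1
    rc_end <- glen - hp_g$start + 1
    rev <- fold_back(rc_genome, "chr", rc_start, rc_end, "-")
    expect_equal(rev$accepted, fwd$accepted)
    expect_equal(rev$n_paired, fwd$n_paired)
    expect_equal(rev$loop_size, fwd$loop_size)
  }
})

test_that("loci outside the contig raise an error", {
  g <- c(chr = random_seq(100))
  expect_error(fold_back(g, "chr", 90, 120, "+"), "outside")
  expect_error(fold_back(g, "nope", 1, 21, "+"), "contig")
})

test_that("planted gp2b loci are rejected and gp1/gp2a/gp4 loci accepted by the hairpin oracle", {
  sim <- simulate_bloom_dataset(small_config(seed = 2))
  tr <- sim$truth$mirnas
  for (i in which(tr$group %in% c("gp1", "gp2a", "gp4"))) {
    hp <- fold_back(sim$genome, tr$contig[i], tr$start[i], tr$end[i],
                    tr$strand[i], params = sim$config$hairpin)
    expect_true(hp$accepted, info = tr$id[i])
  }
  for (i in which(tr$group == "gp2b")) {
    hp <- fold_back(sim$genome, tr$contig[i], tr$start[i], tr$end[i],
                    tr$strand[i], params = sim$config$hairpin)
    expect_false(hp$accepted, info = tr$id[i])
  }
})

test_that("classification recovers planted groups exactly and partitions every tag", {
  sim <- simulate_bloom_dataset(small_config(seed = 9))
  catalog <- filter_and_collapse(sim$srna_tags, quiet = TRUE)
  ev <- collect_evidence(catalog, sim$reference$mature,
                         sim$reference$precursor, sim$genome)
  rec <- classify_tags(ev, sim$genome)
  # exactly one label each
  expect_equal(nrow(rec), nrow(ev))
  expect_true(all(rec$group %in% c("gp1", "gp2a", "gp2b", "gp3", "gp4",
                                   "UNCLASSIFIED")))
  # planted tags get their intended group
  truth_grp <- setNames(sim$truth$mirnas$group, sim$truth$mirnas$sequence)
  planted <- rec[rec$sequence %in% names(truth_grp), ]
  expect_equal(unname(truth_grp[planted$sequence]), planted$group)
  # agrees with the literal predicate oracle on every tag
  oracle <- vapply(seq_len(nrow(ev)), function(i) {
    oracle_classify_one(ev[i, ], sim$genome)
  }, character(1))
  expect_equal(rec$group, oracle)
  # known flag is group != gp4 for classified records
  cls <- rec[rec$group != "UNCLASSIFIED", ]
  expect_equal(cls$known, cls$group != "gp4")
})

test_that("removing the mature reference only ever demotes known groups to gp4/UNCLASSIFIED", {
  sim <- simulate_bloom_dataset(small_config(seed = 13))
  catalog <- filter_and_collapse(sim$srna_tags, quiet = TRUE)
  ev <- collect_evidence(catalog, sim$reference$mature,
                         sim$reference$precursor, sim$genome)
  rec <- classify_tags(ev, sim$genome)
  empty_ref <- c(x = strrep("A", 60))  # no tag can hit within 2 mismatches
  ev2 <- collect_evidence(catalog, empty_ref, sim$reference$precursor,
                          sim$genome)
  rec2 <- classify_tags(ev2, sim$genome)
  known_before <- rec$group %in% c("gp1", "gp2a", "gp2b", "gp3")
  expect_true(all(rec2$group[known_before] %in% c("gp4", "UNCLASSIFIED")))
  # and nothing moved the other way
  expect_true(all(rec2$group[!known_before] == rec$group[!known_before]))
})

test_that("group summary totals are additive and zero records give a zero table", {
  z <- summarize_groups(tibble::tibble(
    id = character(), sequence = character(), group = character(),
    known = logical(), mature_hit = character(),
    hairpin_locus = character(), precursor = character(),
    structure = character()
  ))
  expect_true(all(z$n_mirna == 0))

  sim <- simulate_bloom_dataset(small_config(seed = 9))
  catalog <- filter_and_collapse(sim$srna_tags, quiet = TRUE)
  ev <- collect_evidence(catalog, sim$reference$mature,
                         sim$reference$precursor, sim$genome)
  rec <- classify_tags(ev, sim$genome)
  smry <- summarize_groups(rec)
  known_rows <- smry[smry$category == "known miRNA" & smry$group != "total", ]
  known_total <- smry[smry$category == "known miRNA" & smry$group == "total", ]
  expect_equal(sum(known_rows$n_mirna), known_total$n_mirna)
  grand <- smry[smry$category == "Total", ]
  expect_equal(grand$n_mirna,
               sum(smry$n_mirna[smry$group != "total" &
                                  smry$category != "Total"]))
  # per-group unique miRNA counts equal the planted design
  cfg_n <- small_config(seed = 9)$n_mir
  for (g in names(cfg_n)) {
    expect_equal(smry$n_mirna[smry$group == g], unname(cfg_n[[g]]),
                 info = g)
  }
})
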