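test_that("a perfect complementary site scores zero penalty at the right coordinates", {
  set.seed(3)
  m <- random_seq(21)
  left <- random_seq(100)
  tx <- c(T1 = paste0(left, oracle_revcomp(m), random_seq(80)))
  hits <- predict_targets(c(mir1 = m), tx)
  perfect <- hits[hits$penalty == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$start, 101)
  expect_equal(perfect$end, 121)
  expect_equal(perfect$alignment, strrep("|", 21))
  # cleavage opposite miRNA position 10
  expect_equal(perfect$cleavage_pos, 101 + 21 - 10)
  # max_penalty = 0 keeps only perfect sites
  p0 <- predict_targets(c(mir1 = m), tx, target_params(max_penalty = 0))
  expect_true(all(p0$penalty == 0))
})

test_that("position weighting doubles costs in the miRNA 5' region", {
  set.seed(4)
  m <- random_seq(21)
  site <- oracle_revcomp(m)
  flip <- function(x, i) {
    b <- substr(x, i, i)
    # replace with a base that pairs with nothing (avoid G:U)
    repl <- setdiff(c("A", "C", "G", "T"), c(b, switch(b,
      A = c("T"), T = c("A", "G"), G = c("C", "T"), C = "G")))[1]
    substr(x, i, i) <- repl
    x
  }
  L <- 21
  # mismatch at miRNA position 5 (inside 2-13): transcript offset L - 5 + 1
  site5 <- flip(site, L - 5 + 1)
  tx <- c(T1 = paste0(strrep("A", 50), site5, strrep("A", 50)))
  h5 <- predict_targets(c(m1 = m), tx)
  expect_equal(h5$penalty[h5$start == 51], 2.0)
  # mismatch at miRNA position 20 (outside): weight 1
  site20 <- flip(site, L - 20 + 1)
  tx2 <- c(T1 = paste0(strrep("A", 50), site20, strrep("A", 50)))
  h20 <- predict_targets(c(m1 = m), tx2)
  expect_equal(h20$penalty[h20$start == 51], 1.0)
})

test_that("miRNAs longer than the transcript yield no sites rather than an error", {
  hits <- predict_targets(c(m = random_seq(24)), c(T1 = random_seq(10)))
  expect_equal(nrow(hits), 0)
})

test_that("the window scan agrees with the brute-force penalty oracle", {
  set.seed(8)
  params <- target_params(max_penalty = 6)  # permissive, to compare many sites
  for (rep in 1:4) {
    m <- random_seq(sample(20:23, 1))
    tx_seq <- random_seq(sample(300:600, 1))
    # plant a degenerate site so hits exist
    site <- oracle_revcomp(m)
    substr(site, 3, 3) <- "A"
    substr(tx_seq, 100, 99 + nchar(site)) <- site
    got <- predict_targets(c(m = m), c(T1 = tx_seq), params)
    want <- oracle_scan(m, tx_seq, params)
    expect_equal(got$start, want$start)
    expect_equal(got$penalty, want$penalty, tolerance = 1e-9)
  }
})

test_that("profiles accumulate counts and skip out-of-bounds records with a warning", {
  lens <- tibble::tibble(transcript_id = c("T1", "T2"), length = c(200L, 150L))
  dg <- tibble::tibble(
    genotype = "FD",
    transcript_id = c("T1", "T1", "T1", "T2"),
    position = c(100L, 100L, 5L, 400L),
    count = c(3L, 4L, 1L, 9L)
  )
  expect_warning(pr <- build_profiles(dg, lens), "outside")
  v <- profile_vector(pr, "T1", "FD")
  expect_equal(v[100], 7L)
  expect_equal(v[5], 1L)
  expect_equal(sum(v), 8L)
  expect_equal(sum(profile_vector(pr, "T2", "FD")), 0L)
  empty <- build_profiles(dg[0, ], lens)
  expect_equal(nrow(empty), 0)
})

make_profile <- function(dens, genotype = "FD", id = "T1") {
  pos <- which(dens > 0)
  pr <- build_profiles(
    tibble::tibble(genotype = genotype, transcript_id = id,
                   position = pos, count = dens[pos]),
    tibble::tibble(transcript_id = id, length = length(dens))
  )
  pr
}

site_at <- function(expected, id = "T1") {
  tibble::tibble(mirna_id = "m1", transcript_id = id, start = 1L,
                 end = 21L, penalty = 0, alignment = strrep("|", 21),
                 cleavage_pos = as.integer(expected))
}

test_that("cleavage categories follow the t-plot rule set", {
  dens <- integer(200)
  dens[50] <- 20; dens[90] <- 5; dens[120] <- 3; dens[150] <- 1
  pr <- make_profile(dens)
  # unique maximum -> 0
  v0 <- validate_cleavage(site_at(50), pr)
  expect_equal(v0$category, 0L)
  expect_equal(v0$peak_pos, 50L)
  # tied maximum -> 1
  dens1 <- dens; dens1[30] <- 20
  v1 <- validate_cleavage(site_at(50), make_profile(dens1))
  expect_equal(v1$category, 1L)
  # above mean, below max -> 2 (signal mean = (20+5+3+1)/4 = 7.25 -> no;
  # use a peak of 8)
  dens2 <- dens; dens2[90] <- 8  # mean over signal = 8: equal, not above
  dens2[90] <- 10                # mean = 8.5, 10 > 8.5 -> category 2
  v2 <- validate_cleavage(site_at(90), make_profile(dens2))
  expect_equal(v2$category, 2L)
  # more than one read but at most the mean -> 3
  v3 <- validate_cleavage(site_at(120), pr)
  expect_equal(v3$category, 3L)
  # a single raw read -> 4, even on an otherwise empty transcript
  lone <- integer(200); lone[77] <- 1
  v4 <- validate_cleavage(site_at(77), make_profile(lone))
  expect_equal(v4$category, 4L)
  # all-zero profile -> no record
  none <- validate_cleavage(site_at(50, id = "T9"), {
    pr2 <- make_profile(dens)
    attr(pr2, "lengths") <- c(attr(pr2, "lengths"), T9 = 200L)
    pr2
  })
  expect_equal(nrow(none), 0)
})

test_that("raising the peak count never increases the category", {
  base <- integer(300)
  base[10] <- 12; base[50] <- 6; base[200] <- 2; base[250] <- 2
  cats <- vapply(c(1L, 2L, 3L, 5L, 9L, 12L, 15L), function(c0) {
    dens <- base
    dens[100] <- c0
    validate_cleavage(site_at(100), make_profile(dens))$category
  }, integer(1))
  expect_true(all(diff(cats) <= 0))
})

test_that("the observed peak stays within the search window of the expected site", {
  dens <- integer(200)
  dens[99] <- 4; dens[101] <- 9; dens[140] <- 50
  v <- validate_cleavage(site_at(100), make_profile(dens), window = 1)
  expect_equal(v$peak_pos, 101L)
  expect_lte(abs(v$peak_pos - v$expected_pos), 1)
  # the distant higher peak is not chosen, and drives the category instead
  expect_equal(v$category, 3L)  # 9 > 1, <= mean(4,9,50)=21
})

test_that("synthetic degradome peaks recover the planted positions", {
  sim <- simulate_bloom_dataset(small_config(seed = 4))
  pr <- build_profiles(sim$degradome, sim$exon_lengths)
  for (i in seq_len(nrow(sim$truth$cleavages))) {
    cl <- sim$truth$cleavages[i, ]
    v <- profile_vector(pr, cl$transcript_id, "FD")
    expect_equal(which.max(v), cl$position)
  }
  # degenerate peak_fraction = 1: every tag of a cleaved transcript at one spot
  sim1 <- simulate_bloom_dataset(small_config(
    seed = 4, degradome_peak_fraction = 1, degradome_background_rate = 0
  ))
  dg <- sim1$degradome
  for (i in seq_len(nrow(sim1$truth$cleavages))) {
    cl <- sim1$truth$cleavages[i, ]
    sub <- dg[dg$transcript_id == cl$transcript_id & dg$genotype == "FD", ]
    expect_equal(nrow(sub), 1)
    expect_equal(sub$position, cl$position)
  }
})
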