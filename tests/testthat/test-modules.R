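mk_de <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(feature_id = r[[1]], contrast = r[[2]], family = r[[3]],
                   direction = r[[4]],
                   significant = r[[4]] != "none")
  }))
}

mk_validated <- function(pairs) {
  tibble::tibble(
    mirna_id = vapply(pairs, `[[`, "", 1),
    transcript_id = vapply(pairs, `[[`, "", 2),
    best_category = 0L, n_genotypes = 3L
  )
}

test_that("union sets follow the definitions and empty inputs give empty unions", {
  deg <- mk_de(
    list("g1", "FD:DEvsBS", "developmental", "up"),
    list("g2", "BS:LHvsFD", "varietal", "down"),
    list("g3", "FD:DEvsBS", "developmental", "none")
  )
  u <- build_union_sets(deg)
  expect_equal(u$developmental, "g1")
  expect_equal(u$varietal, "g2")
  empty <- build_union_sets(deg[0, ])
  expect_length(empty$developmental, 0)
  expect_length(empty$varietal, 0)
})

test_that("modules require validation, membership and opposite directions jointly", {
  dem <- mk_de(
    list("m1", "MU:DEvsBS", "developmental", "up"),
    list("m2", "MU:DEvsBS", "developmental", "up"),
    list("m3", "FD:DEvsBS", "developmental", "down")
  )
  deg <- mk_de(
    list("t1", "MU:DEvsBS", "developmental", "down"),
    list("t2", "MU:DEvsBS", "developmental", "up"),
    list("t3", "FD:DEvsBS", "developmental", "up")
  )
  validated <- mk_validated(list(c("m1", "t1"), c("m2", "t2")))
  mods <- find_antagonistic(dem, deg, validated)
  # m1/t1: validated + antagonistic -> module; m2/t2 same direction -> none
  expect_equal(nrow(mods), 1)
  expect_equal(mods$mirna_id, "m1")
  expect_equal(mods$evidence_class, "developmental")
  expect_equal(mods$mirna_direction, "up")
  expect_equal(mods$mrna_direction, "down")
  # m3/t3 perfectly antagonistic but unvalidated -> never a module
  mods2 <- find_antagonistic(dem, deg, mk_validated(list(c("m3", "t3"))))
  expect_equal(mods2$mirna_id, "m3")
  mods3 <- find_antagonistic(dem, deg, mk_validated(list()))
  expect_equal(nrow(mods3), 0)
  # the opposite-direction invariant holds over all emitted detail rows
  for (d in mods$detail) {
    expect_true(all(d$mirna_direction != d$mrna_direction))
  }
})

test_that("evidence classes partition into developmental, varietal and dual", {
  dem <- mk_de(
    list("m1", "MU:DEvsBS", "developmental", "up"),
    list("m1", "DE:LHvsMU", "varietal", "up"),
    list("m2", "DE:LHvsMU", "varietal", "down")
  )
  deg <- mk_de(
    list("t1", "MU:DEvsBS", "developmental", "down"),
    list("t1", "DE:LHvsMU", "varietal", "down"),
    list("t2", "DE:LHvsMU", "varietal", "up")
  )
  mods <- find_antagonistic(dem, deg,
                            mk_validated(list(c("m1", "t1"), c("m2", "t2"))))
  expect_equal(sort(mods$evidence_class), c("dual", "varietal"))
  dual <- mods[mods$evidence_class == "dual", ]
  expect_equal(dual$n_contrasts, 2L)
})

test_that("module finding equals a brute-force triple loop on a synthetic run", {
  run <- run_bloom(small_config(seed = 17), qpcr = FALSE, quiet = TRUE)
  dem <- run$dem_pairwise
  deg <- run$deg
  validated <- run$validated_pairs
  unions <- run$unions
  want <- character(0)
  for (k in seq_len(nrow(validated))) {
    m <- validated$mirna_id[k]
    t <- validated$transcript_id[k]
    dsub <- dem[dem$feature_id == m & dem$direction != "none", ]
    gsub <- deg[deg$feature_id == t & deg$direction != "none", ]
    hit <- FALSE
    for (i in seq_len(nrow(dsub))) for (j in seq_len(nrow(gsub))) {
      if (dsub$contrast[i] == gsub$contrast[j] &&
          dsub$direction[i] != gsub$direction[j] &&
          t %in% unions[[gsub$family[j]]]) {
        hit <- TRUE
      }
    }
    if (hit) want <- c(want, paste(m, t))
  }
  got <- paste(run$modules$mirna_id, run$modules$transcript_id)
  expect_setequal(got, want)
})

test_that("tightening the DEG threshold never grows the module set", {
  run <- run_bloom(small_config(seed = 17), qpcr = FALSE, quiet = TRUE)
  sim <- run$sim
  design <- sim$config$design
  deg_strict <- deg_call(sim$mrna_counts, design, alpha = 0.001)
  mods_strict <- find_antagonistic(run$dem_pairwise, deg_strict,
                                   run$validated_pairs)
  loose <- paste(run$modules$mirna_id, run$modules$transcript_id)
  strict <- paste(mods_strict$mirna_id, mods_strict$transcript_id)
  expect_true(all(strict %in% loose))
})

test_that("TF annotation adds family nodes and per-family counts", {
  mods <- find_antagonistic(
    mk_de(list("m1", "MU:DEvsBS", "developmental", "up"),
          list("m2", "MU:DEvsBS", "developmental", "up"),
          list("m3", "MU:DEvsBS", "developmental", "down")),
    mk_de(list("t1", "MU:DEvsBS", "developmental", "down"),
          list("t2", "MU:DEvsBS", "developmental", "down"),
          list("t3", "MU:DEvsBS", "developmental", "up")),
    mk_validated(list(c("m1", "t1"), c("m2", "t2"), c("m3", "t3")))
  )
  tf <- tibble::tibble(transcript_id = c("t1", "t2"),
                       tf_family = c("NAC", "NAC"))
  ann <- annotate_tf_modules(mods, tf)
  expect_equal(sum(!is.na(ann$tf_family)), 2)
  net <- tf_module_edges(ann)
  expect_equal(sum(net$edges$edge_type == "silences"), 3)
  tf_edges <- net$edges[net$edges$edge_type == "encodes_tf", ]
  expect_setequal(tf_edges$source, c("t1", "t2"))
  expect_true(all(tf_edges$target == "NAC"))
  expect_equal(net$family_counts$n[net$family_counts$tf_family == "NAC"], 2L)
  # no TF targets: empty TF edge list, silencing edges unchanged
  ann0 <- annotate_tf_modules(mods, tf[0, ])
  net0 <- tf_module_edges(ann0)
  expect_equal(sum(net0$edges$edge_type == "encodes_tf"), 0)
  expect_equal(sum(net0$edges$edge_type == "silences"), 3)
})
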