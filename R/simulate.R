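#' Configuration for the synthetic flowering dataset
#'
#' Defines the study conditions emulated by the generator: a small genome
#' with planted miRNA loci of the five evidence groups, a miRBase-like
#' reference, negative-binomial sRNA/mRNA counts for a 3-genotype x 4-stage
#' x 3-replicate design, per-genotype pooled degradome libraries with
#' planted cleavage peaks, and antagonistic miRNA-mRNA(-TF) modules with
#' full ground truth.
#'
#' @param seed Integer seed; fully determines every emitted object. Each
#'   component draws from its own derived sub-stream so regenerating one
#'   file never perturbs another.
#' @param n_contigs,contig_length Genome shape (contigs of `contig_length`
#'   nt).
#' @param n_mir Named integer vector of planted miRNA counts per group
#'   (`gp1`, `gp2a`, `gp2b`, `gp3`, `gp4`).
#' @param mature_len_range Inclusive range of mature miRNA lengths (nt).
#' @param n_transcripts Number of mRNA transcripts.
#' @param transcript_len_range Inclusive range of transcript lengths (nt).
#' @param design Library design tibble from [bloom_design()]; the same
#'   design is used for sRNA and mRNA libraries, while degradome libraries
#'   are one per genotype (petals of all stages pooled).
#' @param effect_log2fc Planted |log2 fold change| for differential
#'   features.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param mean_count Baseline NB mean per feature and library; must be > 0.
#' @param n_planted_modules Number of planted antagonistic miRNA-mRNA
#'   modules (each gets a cleavage site and opposite-signed expression
#'   effects in a shared genotype x stage cell).
#' @param n_extra_de_mirna,n_extra_de_mrna Additional differential features
#'   outside modules, to exercise the set algebra.
#' @param tf_fraction Fraction of transcripts annotated with a TF family.
#' @param degradome_peak_fraction Fraction of a cleaved transcript's
#'   degradome tags placed exactly at the planted position, in (0, 1].
#' @param degradome_tags_per_site Total degradome tags per cleaved
#'   transcript per genotype library.
#' @param degradome_background_rate Expected number of background positions
#'   (one tag each) on transcripts without a planted site.
#' @param n_decoy_tags Number of non-miRNA decoy tags in the sRNA table.
#' @param decoy_out_fraction Fraction of decoys drawn outside the 18-26 nt
#'   window (they must be removed by the catalog filter).
#' @param hairpin [hairpin_params()] used to verify planted loci during
#'   generation (the same oracle the discovery stage applies).
#' @param max_attempts Bound on rejection sampling per locus.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 3L,
                       contig_length = 20000L,
                       n_mir = c(gp1 = 6L, gp2a = 5L, gp2b = 5L,
                                 gp3 = 4L, gp4 = 8L),
                       mature_len_range = c(20L, 24L),
                       n_transcripts = 80L,
                       transcript_len_range = c(600L, 1500L),
                       design = bloom_design(),
                       effect_log2fc = 2.0,
                       dispersion = 0.05,
                       mean_count = 100,
                       n_planted_modules = 8L,
                       n_extra_de_mirna = 4L,
                       n_extra_de_mrna = 6L,
                       tf_fraction = 0.3,
                       degradome_peak_fraction = 0.9,
                       degradome_tags_per_site = 40L,
                       degradome_background_rate = 1.5,
                       n_decoy_tags = 50L,
                       decoy_out_fraction = 0.2,
                       hairpin = hairpin_params(),
                       max_attempts = 1000L) {
  groups <- c("gp1", "gp2a", "gp2b", "gp3", "gp4")
  full <- setNames(rep(0L, 5), groups)
  full[names(n_mir)] <- as.integer(n_mir)
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (mean_count <= 0) abort("`mean_count` must be > 0.")
  if (degradome_peak_fraction <= 0 || degradome_peak_fraction > 1) {
    abort("`degradome_peak_fraction` must lie in (0, 1].")
  }
  reps <- design |> count(.data$genotype, .data$stage)
  if (any(reps$n < 2)) abort("Design needs >= 2 replicates per cell.")
  n_genome_mir <- sum(full[c("gp1", "gp2a", "gp2b", "gp4")])
  if (n_planted_modules > sum(full)) {
    abort("More planted modules than planted miRNAs.")
  }
  if (n_planted_modules + 0 > n_transcripts) {
    abort("More planted modules than transcripts.")
  }
  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_mir = full,
    mature_len_range = as.integer(mature_len_range),
    n_transcripts = as.integer(n_transcripts),
    transcript_len_range = as.integer(transcript_len_range),
    design = design, effect_log2fc = effect_log2fc,
    dispersion = dispersion, mean_count = mean_count,
    n_planted_modules = as.integer(n_planted_modules),
    n_extra_de_mirna = as.integer(n_extra_de_mirna),
    n_extra_de_mrna = as.integer(n_extra_de_mrna),
    tf_fraction = tf_fraction,
    degradome_peak_fraction = degradome_peak_fraction,
    degradome_tags_per_site = as.integer(degradome_tags_per_site),
    degradome_background_rate = degradome_background_rate,
    n_decoy_tags = as.integer(n_decoy_tags),
    decoy_out_fraction = decoy_out_fraction,
    hairpin = hairpin, max_attempts = as.integer(max_attempts),
    n_genome_mir = n_genome_mir
  ), class = "sim_config")
}

TF_FAMILIES <- c("MYB-related", "bHLH", "Trihelix", "NAC", "GRAS", "HD-ZIP")

# Expand a planted cell effect (feature up/down in one genotype x stage
# cell) into the signed pairwise contrasts it touches.
expand_cell_effects <- function(cell_effects, design) {
  contrasts <- bloom_contrasts(design)
  rows <- purrr::pmap(cell_effects, function(feature_id, feature_type,
                                             genotype, stage, log2fc) {
    hit <- contrasts |>
      filter(
        (.data$family == "developmental" & .data$within == genotype &
           (.data$group_b == stage | .data$group_a == stage)) |
        (.data$family == "varietal" & .data$within == stage &
           (.data$group_b == genotype | .data$group_a == genotype))
      ) |>
      mutate(
        feature_id = feature_id, feature_type = feature_type,
        log2fc = ifelse(
          (.data$family == "developmental" & .data$group_b == stage) |
            (.data$family == "varietal" & .data$group_b == genotype),
          log2fc, -log2fc
        )
      )
    select(hit, "feature_id", "feature_type", "contrast", "family", "log2fc")
  })
  list_rbind(rows)
}

#' Simulate a genome with planted miRNA loci and the ground-truth plan
#'
#' Plants mature miRNA loci of every evidence group into random contigs:
#' gp1/gp2a/gp4 loci get an inverted-repeat cassette (mature + loop +
#' reverse complement) so the fold-back test accepts them (verified during
#' generation by calling [fold_back()] itself); gp2b matures are embedded
#' bare, with their flanks reshuffled by rejection sampling until the
#' fold-back test rejects; gp3 matures are kept out of the genome entirely
#' (verified by exact search on both strands). The function also plans the
#' downstream truth: transcripts, planted expression effects, cleavage
#' sites and antagonistic modules.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (named character vector), `mir_gff` (tibble of
#'   planted loci, 1-based inclusive), `truth` (class `bloom_truth`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, "genome"), {
    genome <- setNames(
      random_dna(config$n_contigs, config$contig_length),
      sprintf("contig_%02d", seq_len(config$n_contigs))
    )

    # non-overlapping slots, each wide enough for cassette + flanks
    slot_width <- 2L * config$hairpin$flank + 200L
    slots <- list_rbind(purrr::imap(genome, function(s, nm) {
      starts <- seq(1L, nchar(s) - slot_width, by = slot_width)
      tibble(contig = nm, slot_start = starts)
    }))
    need <- config$n_genome_mir
    if (nrow(slots) < need) {
      abort("Genome too small for the requested number of planted loci.")
    }
    slots <- slots[sample.int(nrow(slots), need), , drop = FALSE]

    groups <- rep(names(config$n_mir), times = config$n_mir)
    ids <- sprintf("pmir_%s_%02d", groups,
                   unlist(lapply(config$n_mir, seq_len)))
    lens <- sample(seq(config$mature_len_range[1], config$mature_len_range[2]),
                   length(ids), replace = TRUE)
    matures <- character(length(ids))
    # unique mature sequences
    seen <- character(0)
    for (i in seq_along(ids)) {
      repeat {
        m <- random_dna(1, lens[i])
        if (!m %in% seen) break
      }
      matures[i] <- m
      seen <- c(seen, m)
    }

    rec <- tibble(
      id = ids, sequence = matures, group = groups,
      contig = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, pre_start = NA_integer_, pre_end = NA_integer_
    )

    slot_i <- 0L
    for (i in seq_along(ids)) {
      g <- groups[i]
      if (g == "gp3") next
      slot_i <- slot_i + 1L
      ctg <- slots$contig[slot_i]
      base <- slots$slot_start[slot_i] + config$hairpin$flank
      L <- nchar(matures[i])
      if (g %in% c("gp1", "gp2a", "gp4")) {
        ok <- FALSE
        for (att in seq_len(config$max_attempts)) {
          loop_len <- sample(8:20, 1)
          cassette <- paste0(matures[i], random_dna(1, loop_len),
                             revcomp(matures[i]))
          s <- genome[[ctg]]
          substr(s, base, base + nchar(cassette) - 1L) <- cassette
          genome[[ctg]] <- s
          hp <- fold_back(genome, ctg, base, base + L - 1L, "+",
                          params = config$hairpin)
          if (hp$accepted) {
            rec$contig[i] <- ctg
            rec$start[i] <- base
            rec$end[i] <- base + L - 1L
            rec$strand[i] <- "+"
            rec$pre_start[i] <- base
            rec$pre_end[i] <- base + nchar(cassette) - 1L
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "Rejection sampling failed to build an accepting hairpin for %s at %s:%d after %d attempts.",
            ids[i], ctg, base, config$max_attempts))
        }
      } else { # gp2b: bare mature, flanks shuffled until the hairpin fails
        s <- genome[[ctg]]
        substr(s, base, base + L - 1L) <- matures[i]
        genome[[ctg]] <- s
        ok <- FALSE
        for (att in seq_len(config$max_attempts)) {
          hp <- fold_back(genome, ctg, base, base + L - 1L, "+",
                          params = config$hairpin)
          if (!hp$accepted) {
            ok <- TRUE
            break
          }
          fl <- config$hairpin$flank
          up <- substr(genome[[ctg]], base - fl, base - 1L)
          dn <- substr(genome[[ctg]], base + L, base + L + fl - 1L)
          shuf <- function(x) paste(sample(strsplit(x, "")[[1]]), collapse = "")
          s <- genome[[ctg]]
          substr(s, base - fl, base - 1L) <- shuf(up)
          substr(s, base + L, base + L + fl - 1L) <- shuf(dn)
          genome[[ctg]] <- s
        }
        if (!ok) {
          abort(sprintf(
            "Rejection sampling failed to break the hairpin for %s at %s:%d after %d attempts.",
            ids[i], ctg, base, config$max_attempts))
        }
        rec$contig[i] <- ctg
        rec$start[i] <- base
        rec$end[i] <- base + L - 1L
        rec$strand[i] <- "+"
      }
    }

    # gp3 matures must be genome-absent; resample on collision
    for (i in which(groups == "gp3")) {
      att <- 0L
      while (nrow(map_tag(rec$sequence[i], genome, 0L, "both")) > 0) {
        att <- att + 1L
        if (att > config$max_attempts) {
          abort(sprintf("Could not draw a genome-absent gp3 mature for %s.",
                        ids[i]))
        }
        rec$sequence[i] <- random_dna(1, lens[i])
      }
    }

    mir_gff <- rec |>
      filter(!is.na(.data$contig)) |>
      mutate(source = "mirbloom", type = "miRNA", score = ".", phase = ".") |>
      select("contig", "source", "type", "start", "end", "score", "strand",
             "phase", "id", "group")

    truth <- plan_truth(config, rec)
    list(genome = genome, mir_gff = mir_gff, truth = truth)
  })
}

# Plan transcripts, planted expression effects, cleavage sites and modules.
# Called inside simulate_genome's seeded block (sub-stream "plan").
plan_truth <- function(config, mirnas) {
  withr::with_seed(sub_seed(config$seed, "plan"), {
    tx <- tibble(
      transcript_id = sprintf("T%04d", seq_len(config$n_transcripts)),
      length = sample(seq(config$transcript_len_range[1],
                          config$transcript_len_range[2]),
                      config$n_transcripts, replace = TRUE),
      tf_family = NA_character_
    )
    n_tf <- round(config$tf_fraction * config$n_transcripts)
    tf_rows <- sample.int(config$n_transcripts, n_tf)
    tx$tf_family[tf_rows] <- sample(TF_FAMILIES, n_tf, replace = TRUE)

    genotypes <- levels(config$design$genotype)
    stages <- levels(config$design$stage)
    later_stages <- stages[-1]

    # a null simulation (zero effect) cannot plant antagonistic modules:
    # their defining opposite-signed effects would not exist
    nm <- if (config$effect_log2fc == 0) 0L else config$n_planted_modules
    mod_mirnas <- mirnas$id[seq_len(min(nm, nrow(mirnas)))]
    mod_tx <- tx$transcript_id[seq_len(nm)]
    cells <- tibble(
      genotype = genotypes[(seq_len(nm) - 1L) %% length(genotypes) + 1L],
      stage = later_stages[(seq_len(nm) - 1L) %% length(later_stages) + 1L]
    )
    mir_sign <- ifelse(runif(nm) < 0.5, 1, -1)

    modules <- tibble(
      mirna_id = mod_mirnas, transcript_id = mod_tx,
      tf_family = tx$tf_family[match(mod_tx, tx$transcript_id)],
      genotype = cells$genotype, stage = cells$stage,
      mirna_log2fc = mir_sign * config$effect_log2fc,
      mrna_log2fc = -mir_sign * config$effect_log2fc
    )

    # planted cleavage sites: embed site away from transcript ends
    mlen <- nchar(mirnas$sequence[match(mod_mirnas, mirnas$id)])
    site_start <- vapply(seq_len(nm), function(i) {
      tl <- tx$length[match(mod_tx[i], tx$transcript_id)]
      sample(seq(50L, tl - mlen[i] - 50L), 1)
    }, integer(1))
    cleavages <- tibble(
      mirna_id = mod_mirnas, transcript_id = mod_tx,
      site_start = site_start,
      position = site_start + mlen - 10L  # opposite miRNA position 10
    )

    cell_effects <- bind_rows(
      tibble(feature_id = modules$mirna_id, feature_type = "mirna",
             genotype = modules$genotype, stage = modules$stage,
             log2fc = modules$mirna_log2fc),
      tibble(feature_id = modules$transcript_id, feature_type = "mrna",
             genotype = modules$genotype, stage = modules$stage,
             log2fc = modules$mrna_log2fc)
    )

    # extra (non-module) differential features
    free_mir <- setdiff(mirnas$id, mod_mirnas)
    extra_mir <- head(free_mir, config$n_extra_de_mirna)
    free_tx <- setdiff(tx$transcript_id, mod_tx)
    extra_tx <- head(free_tx, config$n_extra_de_mrna)
    n_extra <- length(extra_mir) + length(extra_tx)
    if (n_extra > 0) {
      extra <- tibble(
        feature_id = c(extra_mir, extra_tx),
        feature_type = c(rep("mirna", length(extra_mir)),
                         rep("mrna", length(extra_tx))),
        genotype = sample(genotypes, n_extra, replace = TRUE),
        stage = sample(later_stages, n_extra, replace = TRUE),
        log2fc = sample(c(-1, 1), n_extra, replace = TRUE) * config$effect_log2fc
      )
      cell_effects <- bind_rows(cell_effects, extra)
    }

    structure(list(
      mirnas = mirnas,
      transcripts_plan = tx,
      cell_effects = cell_effects,
      de_contrasts = expand_cell_effects(cell_effects, config$design),
      cleavages = cleavages,
      modules = modules
    ), class = "bloom_truth")
  })
}

#' Simulate the miRBase-like mature and precursor reference
#'
#' Mature sequences of gp1/gp2a/gp2b/gp3 are placed in the mature
#' reference (gp4 tags are absent — that is what makes them "predicted").
#' The gp1 precursor is the exact genomic cassette, so it maps back to the
#' genome; gp2a/gp2b/gp3 precursors are synthetic stem-loops (mature +
#' random loop + reverse complement) verified to be genome-absent.
#' Precursor records are named `<mature id>_pre`.
#'
#' @param config A [sim_config()].
#' @param truth The `bloom_truth` from [simulate_genome()].
#' @param genome The genome from [simulate_genome()].
#' @return A list with named character vectors `mature` and `precursor`.
#' @export
simulate_mirbase <- function(config, truth, genome) {
  withr::with_seed(sub_seed(config$seed, "mirbase"), {
    known <- filter(truth$mirnas, .data$group != "gp4")
    mature <- setNames(known$sequence, known$id)
    precursor <- character(0)
    for (i in seq_len(nrow(known))) {
      id <- known$id[i]
      if (known$group[i] == "gp1") {
        pre <- substr(genome[[known$contig[i]]], known$pre_start[i],
                      known$pre_end[i])
      } else {
        for (att in seq_len(config$max_attempts)) {
          pre <- paste0(known$sequence[i], random_dna(1, 12L),
                        revcomp(known$sequence[i]))
          if (nrow(map_tag(pre, genome, 0L, "both")) == 0) break
          if (att == config$max_attempts) {
            abort(sprintf("Could not draw a genome-absent precursor for %s.", id))
          }
        }
      }
      precursor[paste0(id, "_pre")] <- pre
    }
    list(mature = mature, precursor = precursor)
  })
}

#' Simulate transcript sequences and sRNA/mRNA count tables
#'
#' Transcript sequences follow the planned lengths, with the reverse
#' complement of each module miRNA embedded at its planted target site.
#' Counts are negative-binomial: mean `mean_count * 2^log2fc` in libraries
#' of a feature's planted genotype x stage cell, `mean_count` elsewhere,
#' with the configured dispersion. The sRNA table also carries decoy tags
#' (a configurable fraction outside 18-26 nt) with null counts.
#'
#' @param config A [sim_config()].
#' @param truth The `bloom_truth` from [simulate_genome()].
#' @return A list: `transcripts` (named character vector), `srna_tags`
#'   (tibble `sequence` + one count column per library), `mrna_counts`
#'   (tibble `transcript_id` + count columns), `exon_lengths` (tibble
#'   `transcript_id`, `length`), `tf_annotation` (tibble `transcript_id`,
#'   `tf_family`).
#' @export
simulate_counts <- function(config, truth) {
  design <- config$design
  libs <- design$library

  nb_matrix <- function(feature_ids, feature_type) {
    eff <- truth$cell_effects |>
      filter(.data$feature_type == !!feature_type)
    mu <- matrix(config$mean_count, nrow = length(feature_ids),
                 ncol = length(libs), dimnames = list(feature_ids, libs))
    for (i in seq_len(nrow(eff))) {
      if (!eff$feature_id[i] %in% feature_ids) next
      cell_libs <- design_libraries(design, eff$genotype[i], eff$stage[i])
      mu[eff$feature_id[i], cell_libs] <-
        config$mean_count * 2^eff$log2fc[i]
    }
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )
    counts
  }

  withr::with_seed(sub_seed(config$seed, "transcripts"), {
    tx_plan <- truth$transcripts_plan
    transcripts <- setNames(
      vapply(tx_plan$length, function(l) random_dna(1, l), character(1)),
      tx_plan$transcript_id
    )
    for (i in seq_len(nrow(truth$cleavages))) {
      cl <- truth$cleavages[i, ]
      m <- truth$mirnas$sequence[truth$mirnas$id == cl$mirna_id]
      site <- revcomp(m)
      tseq <- transcripts[[cl$transcript_id]]
      if (cl$site_start + nchar(site) - 1L > nchar(tseq)) {
        abort(sprintf("Planted site for %s on %s exceeds transcript bounds.",
                      cl$mirna_id, cl$transcript_id))
      }
      substr(tseq, cl$site_start, cl$site_start + nchar(site) - 1L) <- site
      transcripts[[cl$transcript_id]] <- tseq
    }
  })

  withr::with_seed(sub_seed(config$seed, "srna_counts"), {
    n_out <- round(config$n_decoy_tags * config$decoy_out_fraction)
    n_in <- config$n_decoy_tags - n_out
    decoy_len <- c(
      sample(18:26, n_in, replace = TRUE),
      sample(c(14:17, 27:32), n_out, replace = TRUE)
    )
    decoys <- vapply(decoy_len, function(l) random_dna(1, l), character(1))
    decoys <- setdiff(unique(decoys), truth$mirnas$sequence)
    planted_ids <- truth$mirnas$id
    counts <- nb_matrix(planted_ids, "mirna")
    decoy_counts <- matrix(
      rnbinom(length(decoys) * length(libs), mu = config$mean_count,
              size = 1 / config$dispersion),
      nrow = length(decoys), dimnames = list(NULL, libs)
    )
    srna_tags <- bind_rows(
      bind_cols(tibble(sequence = truth$mirnas$sequence),
                as_tibble(counts)),
      bind_cols(tibble(sequence = decoys), as_tibble(decoy_counts))
    )
  })

  withr::with_seed(sub_seed(config$seed, "mrna_counts"), {
    counts <- nb_matrix(truth$transcripts_plan$transcript_id, "mrna")
    mrna_counts <- bind_cols(
      tibble(transcript_id = rownames(counts)), as_tibble(counts)
    )
  })

  list(
    transcripts = transcripts,
    srna_tags = srna_tags,
    mrna_counts = mrna_counts,
    exon_lengths = select(truth$transcripts_plan, "transcript_id", "length"),
    tf_annotation = truth$transcripts_plan |>
      filter(!is.na(.data$tf_family)) |>
      select("transcript_id", "tf_family")
  )
}

#' Simulate per-genotype degradome tag tables
#'
#' One degradome library per genotype (petals of all four stages pooled
#' before library construction). Each transcript carrying a planted
#' cleavage site receives `degradome_tags_per_site` tags of which
#' `degradome_peak_fraction` sit exactly at the planted position and the
#' rest are spread uniformly; transcripts without a planted site get a
#' sparse uniform background (single-count positions).
#'
#' @param config A [sim_config()].
#' @param truth The `bloom_truth` from [simulate_genome()].
#' @param exon_lengths Tibble `transcript_id`, `length` (bounds check).
#' @return A tibble with columns `genotype`, `transcript_id`, `position`
#'   (1-based 5' end), `count`.
#' @export
simulate_degradome <- function(config, truth, exon_lengths) {
  genotypes <- levels(config$design$genotype)
  lens <- setNames(exon_lengths$length, exon_lengths$transcript_id)
  bad <- truth$cleavages$position > lens[truth$cleavages$transcript_id] |
    truth$cleavages$position < 1
  if (any(bad)) {
    abort(sprintf("Planted cleavage position outside transcript bounds: %s",
                  paste(truth$cleavages$transcript_id[bad], collapse = ", ")))
  }
  withr::with_seed(sub_seed(config$seed, "degradome"), {
    rows <- purrr::map(genotypes, function(g) {
      planted <- purrr::pmap(truth$cleavages, function(mirna_id, transcript_id,
                                                       site_start, position) {
        total <- config$degradome_tags_per_site
        peak <- max(1L, round(config$degradome_peak_fraction * total))
        bg <- total - peak
        pos <- c(rep(position, peak),
                 if (bg > 0) sample.int(lens[[transcript_id]], bg,
                                        replace = TRUE))
        tab <- table(pos)
        tibble(genotype = g, transcript_id = transcript_id,
               position = as.integer(names(tab)),
               count = as.integer(tab))
      }) |> list_rbind()
      quiet_tx <- setdiff(names(lens), unique(truth$cleavages$transcript_id))
      n_bg <- stats::rpois(length(quiet_tx), config$degradome_background_rate)
      background <- purrr::map2(quiet_tx, n_bg, function(t, n) {
        if (n == 0) return(NULL)
        tibble(genotype = g, transcript_id = t,
               position = sample.int(lens[[t]], n, replace = FALSE),
               count = 1L)
      }) |> list_rbind()
      bind_rows(planted, background)
    }) |> list_rbind()
    rows |>
      group_by(.data$genotype, .data$transcript_id, .data$position) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      arrange(.data$genotype, .data$transcript_id, .data$position)
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs all generator stages under one seed and audits the result for
#' cross-file consistency (every planted module's components must exist in
#' every relevant table).
#'
#' @param config A [sim_config()].
#' @return A list of class `bloom_sim`: `genome`, `mir_gff`, `reference`
#'   (mature/precursor), `transcripts`, `srna_tags`, `mrna_counts`,
#'   `exon_lengths`, `tf_annotation`, `degradome`, `truth`, `config`.
#' @export
simulate_bloom_dataset <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  ref <- simulate_mirbase(config, gen$truth, gen$genome)
  cnt <- simulate_counts(config, gen$truth)
  dg <- simulate_degradome(config, gen$truth, cnt$exon_lengths)
  sim <- structure(list(
    genome = gen$genome, mir_gff = gen$mir_gff, reference = ref,
    transcripts = cnt$transcripts, srna_tags = cnt$srna_tags,
    mrna_counts = cnt$mrna_counts, exon_lengths = cnt$exon_lengths,
    tf_annotation = cnt$tf_annotation, degradome = dg,
    truth = gen$truth, config = config
  ), class = "bloom_sim")
  problems <- audit_sim(sim)
  if (length(problems) > 0) {
    abort(paste("Synthetic dataset failed its truth audit:",
                paste(problems, collapse = "; ")))
  }
  sim
}

#' Cross-file consistency audit of a synthetic dataset
#'
#' Verifies that every planted module's components are present in every
#' relevant emitted table: the miRNA tag in the sRNA table, the target in
#' the transcript/count tables, the cleavage peak in the degradome table,
#' and opposite-signed planted effects for miRNA and mRNA in at least one
#' shared contrast.
#'
#' @param sim A `bloom_sim` object.
#' @return A character vector of problems (empty when consistent).
#' @export
audit_sim <- function(sim) {
  problems <- character(0)
  tr <- sim$truth
  for (i in seq_len(nrow(tr$modules))) {
    m <- tr$modules[i, ]
    mseq <- tr$mirnas$sequence[tr$mirnas$id == m$mirna_id]
    if (!mseq %in% sim$srna_tags$sequence) {
      problems <- c(problems, sprintf("module miRNA %s missing from sRNA table",
                                      m$mirna_id))
    }
    if (!m$transcript_id %in% sim$mrna_counts$transcript_id) {
      problems <- c(problems, sprintf("module target %s missing from counts",
                                      m$transcript_id))
    }
    cl <- tr$cleavages[tr$cleavages$mirna_id == m$mirna_id &
                         tr$cleavages$transcript_id == m$transcript_id, ]
    if (nrow(cl) == 0) {
      problems <- c(problems, sprintf("module %s->%s has no planted cleavage",
                                      m$mirna_id, m$transcript_id))
    } else {
      hit <- sim$degradome |>
        filter(.data$transcript_id == m$transcript_id,
               .data$position == cl$position[[1]])
      if (nrow(hit) == 0) {
        problems <- c(problems,
                      sprintf("no degradome peak at planted position for %s",
                              m$transcript_id))
      }
    }
    shared <- inner_join(
      filter(tr$de_contrasts, .data$feature_id == m$mirna_id),
      filter(tr$de_contrasts, .data$feature_id == m$transcript_id),
      by = "contrast", suffix = c("_mir", "_tx")
    ) |>
      filter(sign(.data$log2fc_mir) != sign(.data$log2fc_tx))
    if (nrow(shared) == 0) {
      problems <- c(problems,
                    sprintf("module %s->%s lacks opposite-signed shared contrast",
                            m$mirna_id, m$transcript_id))
    }
  }
  problems
}

#' Write a synthetic dataset to disk in standard plain-text formats
#'
#' Emits genome and reference FASTA, MIR-locus GFF3 (1-based inclusive),
#' TSV count tables with library columns named `<genotype>_<stage>_<rep>`,
#' per-genotype degradome TSVs, a TF annotation TSV and the ground truth
#' as a JSON sidecar. Output is byte-deterministic for a given config.
#'
#' @param sim A `bloom_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_bloom_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fasta <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  }
  write_fasta(sim$genome, p("genome.fa"))
  write_fasta(sim$reference$mature, p("mature_ref.fa"))
  write_fasta(sim$reference$precursor, p("precursor_ref.fa"))
  write_fasta(sim$transcripts, p("transcripts.fa"))
  gff <- sim$mir_gff |>
    mutate(attributes = sprintf("ID=%s;group=%s", .data$id, .data$group)) |>
    select("contig", "source", "type", "start", "end", "score", "strand",
           "phase", "attributes")
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")),
             p("mir_loci.gff3"))
  readr::write_tsv(sim$srna_tags, p("srna_counts.tsv"))
  readr::write_tsv(sim$mrna_counts, p("mrna_counts.tsv"))
  readr::write_tsv(sim$exon_lengths, p("exon_lengths.tsv"))
  readr::write_tsv(sim$tf_annotation, p("tf_annotation.tsv"))
  for (g in unique(sim$degradome$genotype)) {
    readr::write_tsv(
      filter(sim$degradome, .data$genotype == g) |>
        select("transcript_id", "position", "count"),
      p(sprintf("degradome_%s.tsv", g))
    )
  }
  truth <- sim$truth
  truth_json <- list(
    mirnas = truth$mirnas, transcripts_plan = truth$transcripts_plan,
    cell_effects = truth$cell_effects, de_contrasts = truth$de_contrasts,
    cleavages = truth$cleavages, modules = truth$modules
  )
  jsonlite::write_json(truth_json, p("truth.json"), dataframe = "rows",
                       digits = NA, pretty = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}
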