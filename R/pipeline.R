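#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Run the integrated miRNA-transcriptome-degradome pipeline end-to-end
#'
#' Orchestrates every stage on a synthetic dataset with known ground
#' truth: simulate, catalogue (filter/collapse + mapping evidence),
#' discover (fold-back test + five-group classification), differential
#' expression (ANOVA DEMs, fold-change/P DEGs, union sets), degradome
#' (target scan, density profiles, cleavage validation), integration
#' (antagonistic miRNA-mRNA(-TF) modules) and, optionally, qPCR
#' validation by 2^-ddCt. All randomness derives from `config$seed`;
#' identical configs give identical results, which the run manifest
#' certifies by content digests.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, all inputs and outputs
#'   are written as plain-text files and their MD5 digests recorded in the
#'   manifest.
#' @param qpcr Also run the qPCR validation stage.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `bloom_run` with components `sim`, `catalog`,
#'   `evidence`, `mirnas`, `group_summary`, `mirna_counts`, `dem_anova`,
#'   `dem_pairwise`, `deg`, `unions`, `target_sites`, `profiles`,
#'   `validated`, `validated_pairs`, `modules`, `network`, `qpcr`
#'   (or `NULL`) and `manifest`.
#' @export
run_bloom <- function(config = sim_config(), outdir = NULL, qpcr = TRUE,
                      quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  stages <- character(0)
  design <- config$design

  say("stage simulate: generating synthetic dataset (seed %d)", config$seed)
  sim <- simulate_bloom_dataset(config)
  stages <- c(stages, "simulate")

  say("stage catalog: filtering and mapping %d raw tags", nrow(sim$srna_tags))
  catalog <- filter_and_collapse(sim$srna_tags, quiet = quiet)
  evidence <- collect_evidence(catalog, sim$reference$mature,
                               sim$reference$precursor, sim$genome)
  stages <- c(stages, "catalog")

  say("stage discover: classifying %d tags", nrow(evidence))
  mirnas <- classify_tags(evidence, sim$genome, params = config$hairpin)
  group_summary <- summarize_groups(mirnas)
  stages <- c(stages, "discover")

  say("stage de: differential expression across stages and genotypes")
  classified <- mirnas |> filter(.data$group != "UNCLASSIFIED")
  lib_cols <- design$library
  mirna_counts <- catalog |>
    inner_join(select(classified, "id", "sequence"), by = "sequence") |>
    select("id", dplyr::all_of(lib_cols))
  contrasts <- bloom_contrasts(design)
  dem_overall <- bind_rows(
    purrr::map(levels(design$genotype), function(g) {
      dem_anova(mirna_counts, design, factor = "stage", within = g)
    }),
    purrr::map(levels(design$stage), function(s) {
      dem_anova(mirna_counts, design, factor = "genotype", within = s)
    })
  )
  dem_pw <- dem_pairwise(mirna_counts, design, contrasts)
  deg <- deg_call(sim$mrna_counts, design, contrasts)
  unions <- build_union_sets(deg)
  stages <- c(stages, "de")

  say("stage degradome: target scan and cleavage validation")
  target_sites <- predict_targets(classified, sim$transcripts)
  profiles <- build_profiles(sim$degradome, sim$exon_lengths)
  validated <- validate_cleavage(target_sites, profiles)
  validated_pairs <- collapse_cleavage(validated)
  stages <- c(stages, "degradome")

  say("stage integrate: assembling antagonistic modules")
  modules <- find_antagonistic(dem_pw, deg, validated_pairs, unions)
  modules <- annotate_tf_modules(modules, sim$tf_annotation)
  network <- tf_module_edges(modules)
  stages <- c(stages, "integrate")

  qpcr_out <- NULL
  if (qpcr) {
    say("stage qpcr: 2^-ddCt validation of module pairs")
    qpcr_out <- run_qpcr_stage(sim, mirna_counts, mirnas)
    stages <- c(stages, "qpcr")
  }

  run <- structure(list(
    sim = sim, catalog = catalog, evidence = evidence, mirnas = mirnas,
    group_summary = group_summary, mirna_counts = mirna_counts,
    dem_anova = dem_overall, dem_pairwise = dem_pw, deg = deg,
    unions = unions, target_sites = target_sites, profiles = profiles,
    validated = validated, validated_pairs = validated_pairs,
    modules = modules, network = network, qpcr = qpcr_out,
    manifest = NULL
  ), class = "bloom_run")

  run$manifest <- build_manifest(run, config, stages, outdir)
  if (!is.null(outdir)) {
    write_bloom_run(run, outdir)
    run$manifest$file_digests <- as.list(
      tools::md5sum(sort(list.files(outdir, full.names = TRUE,
                                    pattern = "\\.(tsv|fa|gff3|json)$")))
    )
    jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  run
}

# qPCR stage: RQ per genotype (calibrator = that genotype's BS sample) and
# correlation against the sequencing CPM profile.
run_qpcr_stage <- function(sim, mirna_counts, mirnas) {
  design <- sim$config$design
  truth <- sim$truth
  ct <- simulate_qpcr(sim)
  genotypes <- levels(design$genotype)
  stages <- levels(design$stage)

  rq <- purrr::map(genotypes, function(g) {
    sub <- ct |> filter(.data$genotype == g)
    relative_quantity(select(sub, "sample", "gene", "role", "ct"),
                      calibrator = paste(g, "BS", sep = "_")) |>
      mutate(genotype = g)
  }) |> list_rbind()

  # sequencing-side profile: mean CPM per (genotype, stage)
  mir_cpm <- normalize_cpm(mirna_counts, id_col = "id")
  mrna_cpm <- normalize_cpm(sim$mrna_counts, id_col = "transcript_id")
  seq_profile <- function(feature) {
    src <- if (feature %in% mir_cpm$id) {
      list(tab = mir_cpm, key = "id")
    } else {
      list(tab = mrna_cpm, key = "transcript_id")
    }
    row <- src$tab[src$tab[[src$key]] == feature, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    purrr::map(genotypes, function(g) {
      tibble(
        genotype = g, stage = stages,
        expression = vapply(stages, function(s) {
          mean(as.numeric(row[design_libraries(design, g, s)]))
        }, numeric(1))
      )
    }) |> list_rbind()
  }

  feats <- unique(rq$gene)
  # truth miRNA ids map to catalog record ids through the mature sequence
  id_map <- setNames(mirnas$id, mirnas$sequence)
  correlations <- purrr::map(feats, function(f) {
    seq_id <- f
    if (f %in% truth$mirnas$id) {
      seq_id <- id_map[[truth$mirnas$sequence[truth$mirnas$id == f]]] %||% f
    }
    prof <- seq_profile(seq_id)
    if (is.null(prof)) return(NULL)
    purrr::map(genotypes, function(g) {
      rq_series <- rq |>
        filter(.data$gene == f, .data$genotype == g) |>
        mutate(stage = sub("^.*_", "", .data$sample)) |>
        arrange(match(.data$stage, stages))
      seq_series <- prof |>
        filter(.data$genotype == g) |>
        arrange(match(.data$stage, stages))
      if (nrow(rq_series) != length(stages)) return(NULL)
      tibble(
        feature_id = f, genotype = g,
        r = suppressMessages(
          profile_correlation(rq_series$rq, seq_series$expression + 1)
        )
      )
    }) |> list_rbind()
  }) |> list_rbind()

  list(ct = ct, rq = rq, correlations = correlations)
}

build_manifest <- function(run, config, stages, outdir) {
  list(
    package_version = as.character(utils::packageVersion("mirbloom")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    stages_complete = stages,
    result_digest = rlang::hash(list(
      run$mirnas, run$group_summary, run$dem_pairwise, run$deg,
      run$target_sites, run$validated, run$modules$mirna_id,
      run$modules$transcript_id
    )),
    outdir = outdir %||% NA_character_
  )
}

#' Write pipeline results to plain-text files
#'
#' @param run A `bloom_run` object.
#' @param outdir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_bloom_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_bloom_sim(run$sim, outdir)
  p <- function(...) file.path(outdir, ...)
  readr::write_tsv(run$mirnas, p("mirna_catalog.tsv"))
  readr::write_tsv(run$group_summary, p("group_summary.tsv"))
  readr::write_tsv(run$dem_anova, p("dem_anova.tsv"))
  readr::write_tsv(run$dem_pairwise, p("dem_pairwise.tsv"))
  readr::write_tsv(run$deg, p("deg.tsv"))
  readr::write_tsv(run$target_sites, p("target_sites.tsv"))
  readr::write_tsv(run$validated, p("validated_cleavages.tsv"))
  readr::write_tsv(select(run$modules, -dplyr::any_of("detail")),
                   p("modules.tsv"))
  readr::write_tsv(run$network$edges, p("network_edges.tsv"))
  readr::write_tsv(run$network$family_counts, p("tf_family_counts.tsv"))
  if (!is.null(run$qpcr)) {
    readr::write_tsv(run$qpcr$rq, p("qpcr_rq.tsv"))
    readr::write_tsv(run$qpcr$correlations, p("qpcr_correlations.tsv"))
  }
  invisible(list.files(outdir, full.names = TRUE))
}

#' @export
print.bloom_run <- function(x, ...) {
  g <- glance(x)
  cat("<bloom_run>\n")
  cat(sprintf("  seed %d | %d tags -> %d classified miRNAs (gp1 %d, gp2a %d, gp2b %d, gp3 %d, gp4 %d)\n",
              x$sim$config$seed, nrow(x$catalog), g$n_mirnas,
              g$n_gp1, g$n_gp2a, g$n_gp2b, g$n_gp3, g$n_gp4))
  cat(sprintf("  %d DEM calls, %d DEG calls, %d validated cleavage pairs, %d modules (%d TF)\n",
              g$n_dem_sig, g$n_deg_sig, g$n_validated_pairs, g$n_modules,
              g$n_tf_modules))
  invisible(x)
}

#' Tidy the module table of a pipeline run
#'
#' @param x A `bloom_run` object.
#' @param ... Unused.
#' @return The module tibble (one row per antagonistic, degradome-
#'   validated miRNA-mRNA pair) without the nested detail column.
#' @method tidy bloom_run
#' @export
tidy.bloom_run <- function(x, ...) {
  select(as_tibble(x$modules), -dplyr::any_of("detail"))
}

#' One-row summary of a pipeline run
#'
#' @param x A `bloom_run` object.
#' @param ... Unused.
#' @return A one-row tibble with tag, per-group miRNA, DEM/DEG,
#'   validation and module counts.
#' @method glance bloom_run
#' @export
glance.bloom_run <- function(x, ...) {
  grp <- function(g) sum(x$mirnas$group == g)
  tibble(
    n_tags = nrow(x$catalog),
    n_mirnas = sum(x$mirnas$group != "UNCLASSIFIED"),
    n_gp1 = grp("gp1"), n_gp2a = grp("gp2a"), n_gp2b = grp("gp2b"),
    n_gp3 = grp("gp3"), n_gp4 = grp("gp4"),
    n_unclassified = grp("UNCLASSIFIED"),
    n_dem_sig = length(unique(
      x$dem_pairwise$feature_id[x$dem_pairwise$significant])),
    n_deg_sig = length(unique(x$deg$feature_id[x$deg$significant])),
    n_validated_pairs = nrow(x$validated_pairs),
    n_modules = nrow(x$modules),
    n_tf_modules = sum(!is.na(x$modules$tf_family))
  )
}
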