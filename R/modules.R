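#' Assemble the developmental and varietal DEG union sets
#'
#' Genes called differentially expressed in any across-stage contrast
#' (within a genotype) form the developmental unified set; genes called in
#' any across-genotype contrast (within a stage) form the varietal unified
#' set. These unions are the gene-side input to module integration.
#'
#' @param deg A `bloom_de` tibble from [deg_call()] with a `family`
#'   column.
#' @return A list with character vectors `developmental` and `varietal`.
#' @export
build_union_sets <- function(deg) {
  stopifnot(all(c("feature_id", "family", "significant") %in% names(deg)))
  list(
    developmental = unique(deg$feature_id[deg$significant &
                                            deg$family == "developmental"]),
    varietal = unique(deg$feature_id[deg$significant &
                                       deg$family == "varietal"])
  )
}

#' Identify antagonistic, degradome-validated miRNA-mRNA modules
#'
#' A module is emitted for a (miRNA, target) pair exactly when (i) the
#' pair carries a degradome-validated cleavage site, (ii) the miRNA is
#' differentially expressed and the target belongs to the corresponding
#' DEG union, and (iii) in at least one shared contrast the two are
#' significant in opposite directions — the signature of miRNA-guided
#' gene silencing. The evidence class records whether the antagonism holds
#' in a developmental contrast, a varietal contrast, or both (`dual`).
#'
#' @param dem A `bloom_de` tibble of pairwise miRNA results
#'   ([dem_pairwise()]), with `direction` and `family` columns.
#' @param deg A `bloom_de` tibble of gene results ([deg_call()]).
#' @param validated Collapsed cleavage table from [collapse_cleavage()]
#'   (or a `bloom_cleavage` tibble, collapsed internally).
#' @param unions DEG union sets from [build_union_sets()]; recomputed from
#'   `deg` when omitted.
#' @return A tibble of class `bloom_modules`, one row per module:
#'   `mirna_id`, `transcript_id`, `contrast` (first supporting contrast),
#'   `mirna_direction`, `mrna_direction`, `degradome_category`,
#'   `evidence_class` (`developmental`/`varietal`/`dual`), `n_contrasts`,
#'   and `detail` (list column of all supporting per-contrast rows).
#' @export
find_antagonistic <- function(dem, deg, validated, unions = NULL) {
  if (inherits(validated, "bloom_cleavage")) {
    validated <- collapse_cleavage(validated)
  }
  if (is.null(unions)) unions <- build_union_sets(deg)
  if (nrow(validated) == 0) {
    return(empty_modules())
  }
  dem_sig <- dem |>
    filter(.data$direction != "none") |>
    select("feature_id", "contrast", "family",
           mirna_direction = "direction")
  deg_sig <- deg |>
    filter(.data$direction != "none") |>
    select("feature_id", "contrast", "family",
           mrna_direction = "direction")

  support <- validated |>
    select("mirna_id", "transcript_id", "best_category") |>
    inner_join(dem_sig, by = c(mirna_id = "feature_id"),
               relationship = "many-to-many") |>
    inner_join(deg_sig, by = c(transcript_id = "feature_id", "contrast",
                               "family"),
               relationship = "many-to-many") |>
    filter(.data$mirna_direction != .data$mrna_direction) |>
    filter(
      (.data$family == "developmental" &
         .data$transcript_id %in% unions$developmental) |
        (.data$family == "varietal" &
           .data$transcript_id %in% unions$varietal)
    )
  if (nrow(support) == 0) {
    return(empty_modules())
  }
  out <- support |>
    group_by(.data$mirna_id, .data$transcript_id) |>
    summarise(
      detail = list(data.frame(
        contrast = contrast, family = family,
        mirna_direction = mirna_direction,
        mrna_direction = mrna_direction
      ) |> as_tibble()),
      degradome_category = .data$best_category[[1]],
      evidence_class = evidence_class_of(.data$family),
      n_contrasts = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      contrast = map_chr(.data$detail, ~ .x$contrast[[1]]),
      mirna_direction = map_chr(.data$detail, ~ .x$mirna_direction[[1]]),
      mrna_direction = map_chr(.data$detail, ~ .x$mrna_direction[[1]])
    ) |>
    select("mirna_id", "transcript_id", "contrast", "mirna_direction",
           "mrna_direction", "degradome_category", "evidence_class",
           "n_contrasts", "detail")
  class(out) <- c("bloom_modules", class(out))
  out
}

evidence_class_of <- function(families) {
  dev <- "developmental" %in% families
  varietal <- "varietal" %in% families
  if (dev && varietal) "dual" else if (dev) "developmental" else "varietal"
}

empty_modules <- function() {
  out <- tibble(
    mirna_id = character(), transcript_id = character(),
    contrast = character(), mirna_direction = character(),
    mrna_direction = character(), degradome_category = integer(),
    evidence_class = character(), n_contrasts = integer(), detail = list()
  )
  class(out) <- c("bloom_modules", class(out))
  out
}

#' Annotate modules with transcription-factor families
#'
#' Propagates TF-family labels onto module targets; modules whose target
#' encodes a transcription factor gain a third node (the family label).
#'
#' @param modules A `bloom_modules` tibble.
#' @param tf_annotation Tibble `transcript_id`, `tf_family`.
#' @return The module tibble with a `tf_family` column (`NA` for
#'   non-TF targets).
#' @export
annotate_tf_modules <- function(modules, tf_annotation) {
  out <- modules |>
    left_join(select(tf_annotation, "transcript_id", "tf_family"),
              by = "transcript_id")
  class(out) <- unique(c("bloom_modules", class(out)))
  out
}

#' Export the miRNA-mRNA(-TF) network edge list and TF-family counts
#'
#' Builds an edge list importable by standard network tools: one
#' `silences` edge per module (miRNA to mRNA, attributed with the
#' evidence class and degradome category) and one `encodes_tf` edge from
#' each TF-annotated target to its family node.
#'
#' @param modules A TF-annotated `bloom_modules` tibble
#'   ([annotate_tf_modules()]).
#' @return A list: `edges` (tibble `source`, `target`, `edge_type`,
#'   `evidence_class`, `degradome_category`), `family_counts` (tibble
#'   `tf_family`, `n`).
#' @export
tf_module_edges <- function(modules) {
  if (!"tf_family" %in% names(modules)) {
    abort("Run annotate_tf_modules() first.")
  }
  silence <- tibble(
    source = modules$mirna_id, target = modules$transcript_id,
    edge_type = "silences", evidence_class = modules$evidence_class,
    degradome_category = modules$degradome_category
  )
  tf <- modules |> filter(!is.na(.data$tf_family))
  tf_edges <- tibble(
    source = tf$transcript_id, target = tf$tf_family,
    edge_type = "encodes_tf", evidence_class = tf$evidence_class,
    degradome_category = tf$degradome_category
  )
  family_counts <- tf |>
    count(.data$tf_family, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$tf_family)
  list(edges = bind_rows(silence, distinct(tf_edges)),
       family_counts = family_counts)
}
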