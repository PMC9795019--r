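#' Filter and collapse a raw small-RNA tag table
#'
#' Retains tags whose length lies in the miRNA-sized window (18-26 nt by
#' default), normalises the alphabet (uppercase, U to T), rejects records
#' containing non-ACGT/U characters, and merges duplicate sequences by
#' summing their per-library counts.
#'
#' @param raw A data frame with a `sequence` column and one non-negative
#'   integer count column per library.
#' @param min_len,max_len Inclusive length bounds for retained tags.
#' @param quiet Suppress the kept/dropped summary message.
#' @return A tibble with columns `sequence`, `length`, then the count
#'   columns, one row per unique retained sequence. Rejected records are
#'   attached as the `"rejected"` attribute (columns `sequence`, `reason`).
#' @examples
#' raw <- tibble::tibble(
#'   sequence = c("ACGTACGTACGTACGTAC", "acguacguacguacguac", "ACGT"),
#'   lib1 = c(3L, 5L, 2L)
#' )
#' filter_and_collapse(raw)
#' @export
filter_and_collapse <- function(raw, min_len = 18L, max_len = 26L,
                                quiet = FALSE) {
  stopifnot(is.data.frame(raw), "sequence" %in% names(raw))
  count_cols <- setdiff(names(raw), "sequence")
  if (length(count_cols) == 0) {
    abort("`raw` must carry at least one count column besides `sequence`.")
  }
  seqs <- normalize_seq(raw$sequence)
  bad <- !grepl("^[ACGT]+$", seqs)
  len <- nchar(seqs)
  out_of_range <- !bad & (len < min_len | len > max_len)

  rejected <- tibble(
    sequence = raw$sequence[bad | out_of_range],
    reason = c(
      rep("non_acgtu_character", sum(bad)),
      rep("length_out_of_range", sum(out_of_range))
    )[order(c(which(bad), which(out_of_range)))]
  )

  keep <- !bad & !out_of_range
  kept <- raw[keep, count_cols, drop = FALSE]
  kept$sequence <- seqs[keep]
  collapsed <- kept |>
    group_by(.data$sequence) |>
    summarise(across(dplyr::all_of(count_cols), sum), .groups = "drop") |>
    mutate(length = nchar(.data$sequence)) |>
    relocate("sequence", "length")

  if (!quiet) {
    inform(sprintf(
      "filter_and_collapse: kept %d/%d records (%d unique tags), dropped %d (%d bad alphabet, %d out of 18-26 nt range)",
      sum(keep), nrow(raw), nrow(collapsed), sum(!keep), sum(bad),
      sum(out_of_range)
    ))
  }
  attr(collapsed, "rejected") <- rejected
  collapsed
}

#' Map a short tag against a set of reference sequences
#'
#' Ungapped matching of a tag within each subject sequence, allowing up to
#' `max_mismatches` substitutions (no indels). For genome-style subjects the
#' minus strand is searched too; hits are always reported in subject-forward
#' coordinates, 1-based inclusive, with all tied occurrences listed.
#'
#' @param tag A single tag sequence (DNA or RNA alphabet).
#' @param subjects Named character vector (or `DNAStringSet`) of subject
#'   sequences: a genome, or a mature/precursor reference.
#' @param max_mismatches Maximum number of substitutions tolerated.
#' @param strand `"both"` to search the reverse complement as well (genome),
#'   `"plus"` for forward-only matching (mature reference).
#' @return A tibble with columns `subject`, `start`, `end`, `strand`,
#'   `mismatches`; zero rows when the tag does not map.
#' @export
map_tag <- function(tag, subjects, max_mismatches = 0L,
                    strand = c("both", "plus")) {
  strand <- match.arg(strand)
  if (length(subjects) == 0) abort("`subjects` is empty.")
  if (is.null(names(subjects)) && !inherits(subjects, "XStringSet")) {
    abort("`subjects` must be named.")
  }
  subj <- if (inherits(subjects, "XStringSet")) subjects else {
    Biostrings::DNAStringSet(normalize_seq(subjects))
  }
  pat <- normalize_seq(tag)
  pats <- list(`+` = pat)
  if (strand == "both") pats$`-` <- revcomp(pat)

  hits <- purrr::imap(pats, function(p, strd) {
    purrr::imap(as.list(subj), function(s, nm) {
      if (nchar(p) > length(s)) return(NULL)
      m <- Biostrings::matchPattern(p, s, max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      if (length(m) == 0) return(NULL)
      mm <- vapply(as.character(m), function(w) {
        sum(utf8ToInt(w) != utf8ToInt(p))
      }, integer(1), USE.NAMES = FALSE)
      tibble(subject = nm, start = BiocGenerics::start(m),
             end = BiocGenerics::end(m), strand = strd, mismatches = mm)
    }) |> list_rbind()
  }) |> list_rbind()

  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(subject = character(), start = integer(), end = integer(),
                  strand = character(), mismatches = integer()))
  }
  arrange(hits, .data$subject, .data$start, .data$strand)
}

#' Collect mapping evidence for every tag in a catalog
#'
#' For each collapsed tag, records the boolean evidence bits that drive the
#' five-group miRNA classification: does the tag hit the mature reference
#' (ungapped, forward strand, up to `ref_mismatches` substitutions), does the
#' precursor of its best mature hit map exactly to the genome, does the tag
#' itself map exactly to the genome (both strands, all loci kept)?
#'
#' Precursor records are looked up by the naming convention
#' `<mature id>_pre`; mature hits without a same-named precursor record are
#' treated as having no genome-mappable precursor.
#'
#' @param catalog Tibble from [filter_and_collapse()] (needs `sequence`).
#' @param mature_ref,precursor_ref Named character vectors of reference
#'   mature and precursor sequences.
#' @param genome Named character vector of genome contigs.
#' @param ref_mismatches Mismatch tolerance for mature-reference assignment.
#' @param genome_mismatches Mismatch tolerance for genome mapping of tags
#'   and precursors (0: exact, the conservative default).
#' @return A tibble, one row per tag: `sequence`, `hits_mature_ref`,
#'   `mature_hit`, `mature_mismatches`, `hits_precursor_ref`,
#'   `precursor_hit`, `precursor_maps_genome`, `tag_maps_genome`,
#'   `genome_loci` (list column of per-locus tibbles).
#' @export
collect_evidence <- function(catalog, mature_ref, precursor_ref, genome,
                             ref_mismatches = 2L, genome_mismatches = 0L) {
  stopifnot(is.data.frame(catalog), "sequence" %in% names(catalog))
  if (length(mature_ref) == 0 || length(genome) == 0) {
    abort("Mature reference and genome must be non-empty.")
  }
  precursor_maps <- vapply(names(precursor_ref), function(pid) {
    nrow(map_tag(precursor_ref[[pid]], genome,
                 max_mismatches = genome_mismatches, strand = "both")) > 0
  }, logical(1))

  rows <- purrr::map(catalog$sequence, function(s) {
    mh <- map_tag(s, mature_ref, max_mismatches = ref_mismatches,
                  strand = "plus")
    best_id <- NA_character_
    best_mm <- NA_integer_
    if (nrow(mh) > 0) {
      mh <- arrange(mh, .data$mismatches, .data$subject)
      best_id <- mh$subject[[1]]
      best_mm <- mh$mismatches[[1]]
    }
    ph <- if (length(precursor_ref)) {
      map_tag(s, precursor_ref, max_mismatches = ref_mismatches,
              strand = "plus")
    } else {
      NULL
    }
    pre_id <- if (!is.na(best_id)) paste0(best_id, "_pre") else NA_character_
    gl <- map_tag(s, genome, max_mismatches = genome_mismatches,
                  strand = "both")
    tibble(
      sequence = s,
      hits_mature_ref = nrow(mh) > 0,
      mature_hit = best_id,
      mature_mismatches = best_mm,
      hits_precursor_ref = !is.null(ph) && nrow(ph) > 0,
      precursor_hit = if (!is.null(ph) && nrow(ph) > 0) ph$subject[[1]] else NA_character_,
      precursor_maps_genome = !is.na(pre_id) && isTRUE(precursor_maps[[pre_id]]),
      tag_maps_genome = nrow(gl) > 0,
      genome_loci = list(gl)
    )
  })
  list_rbind(rows)
}
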