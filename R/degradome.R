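#' Scoring scheme for plant miRNA target prediction
#'
#' Position-weighted complementarity penalties in the style of plant
#' target-prediction tools: each duplex position costs 0 for a
#' Watson-Crick pair, `gu` for a G:U wobble and `mismatch` otherwise, and
#' costs are multiplied by `seed_mult` inside the functionally critical
#' 5' region of the miRNA (`seed_start`..`seed_end`). Sites with total
#' penalty at most `max_penalty` are reported.
#'
#' @param mismatch Cost of a mismatched position.
#' @param gu Cost of a G:U wobble pair.
#' @param seed_start,seed_end 1-based miRNA positions of the up-weighted
#'   5' region.
#' @param seed_mult Multiplier applied to costs inside that region.
#' @param max_penalty Maximum total penalty for a reported site.
#' @param cleavage_pos miRNA position whose paired transcript nucleotide is
#'   the expected slicer cleavage 5' end (cleavage falls between duplex
#'   positions 10 and 11).
#' @return A list of class `target_params`.
#' @export
target_params <- function(mismatch = 1.0, gu = 0.5, seed_start = 2L,
                          seed_end = 13L, seed_mult = 2.0,
                          max_penalty = 2.5, cleavage_pos = 10L) {
  structure(list(mismatch = mismatch, gu = gu,
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end), seed_mult = seed_mult,
                 max_penalty = max_penalty,
                 cleavage_pos = as.integer(cleavage_pos)),
            class = "target_params")
}

# Per-position cost of pairing miRNA base b (int code) against every
# transcript position (int codes), before seed weighting.
position_cost <- function(b, t_int, params) {
  cls <- PAIR_CLASS[b, t_int]
  cost <- numeric(length(t_int))
  cost[cls == 0L] <- params$mismatch
  cost[cls == 1L] <- params$gu
  cost
}

#' Predict miRNA binding sites on transcripts
#'
#' Scans every transcript window of miRNA length against the miRNA
#' (anti-parallel duplex: miRNA position `i` pairs transcript position
#' `start + L - i`), sums position-weighted penalties per
#' [target_params()], and reports every site with penalty at most
#' `params$max_penalty`, together with the expected cleavage coordinate
#' (the transcript nucleotide paired to miRNA position 10). Coordinates
#' are 1-based inclusive. miRNAs longer than a transcript yield no sites.
#'
#' @param mirnas Named character vector of mature miRNA sequences, or a
#'   data frame with `id` and `sequence` columns.
#' @param transcripts Named character vector of transcript sequences.
#' @param params A [target_params()] object.
#' @return A tibble: `mirna_id`, `transcript_id`, `start`, `end`,
#'   `penalty`, `alignment` (one symbol per miRNA position, 5' to 3':
#'   `|` Watson-Crick, `o` G:U, `.` mismatch), `cleavage_pos`.
#' @export
predict_targets <- function(mirnas, transcripts, params = target_params()) {
  if (is.data.frame(mirnas)) {
    mirnas <- setNames(mirnas$sequence, mirnas$id)
  }
  if (!is_valid_seq(paste0(paste(mirnas, collapse = ""), "A"))) {
    abort("miRNA sequences must be A/C/G/T/U only.")
  }
  mirnas <- vapply(mirnas, normalize_seq, character(1))
  transcripts <- vapply(transcripts, normalize_seq, character(1))
  t_ints <- lapply(transcripts, seq_to_int)

  rows <- purrr::imap(mirnas, function(mseq, mid) {
    m_int <- seq_to_int(mseq)
    L <- length(m_int)
    weights <- ifelse(seq_len(L) >= params$seed_start &
                        seq_len(L) <= params$seed_end, params$seed_mult, 1)
    purrr::imap(t_ints, function(t_int, tid) {
      n_win <- length(t_int) - L + 1L
      if (n_win < 1L) return(NULL)
      penalty <- numeric(n_win)
      for (i in seq_len(L)) {
        # transcript positions opposite miRNA position i across windows
        idx <- (L - i + 1L):(L - i + n_win)
        penalty <- penalty + weights[i] * position_cost(m_int[i], t_int[idx],
                                                        params)
      }
      hits <- which(penalty <= params$max_penalty + 1e-9)
      if (length(hits) == 0) return(NULL)
      aln <- vapply(hits, function(s) {
        opp <- t_int[s + L - seq_len(L)]
        cls <- PAIR_CLASS[cbind(m_int, opp)]
        paste(c(".", "o", "|")[cls + 1L], collapse = "")
      }, character(1))
      tibble(
        mirna_id = mid, transcript_id = tid,
        start = hits, end = hits + L - 1L,
        penalty = penalty[hits], alignment = aln,
        cleavage_pos = hits + L - params$cleavage_pos
      )
    }) |> list_rbind()
  }) |> list_rbind()

  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(mirna_id = character(), transcript_id = character(),
                  start = integer(), end = integer(), penalty = numeric(),
                  alignment = character(), cleavage_pos = integer()))
  }
  arrange(rows, .data$mirna_id, .data$transcript_id, .data$start)
}

#' Build degradome density profiles
#'
#' Accumulates degradome 5'-end counts per transcript position and
#' library. Records whose position falls outside the transcript bounds are
#' skipped with a warning.
#'
#' @param degradome A tibble with columns `transcript_id`, `position`,
#'   `count`, and optionally `genotype` (one pooled library per genotype);
#'   a missing `genotype` column is treated as a single library `"all"`.
#' @param exon_lengths Tibble `transcript_id`, `length`.
#' @return A tibble of class `bloom_profiles` (`genotype`,
#'   `transcript_id`, `position`, `count`), with transcript lengths kept
#'   in the `"lengths"` attribute.
#' @export
build_profiles <- function(degradome, exon_lengths) {
  stopifnot(all(c("transcript_id", "position", "count") %in% names(degradome)))
  if (!"genotype" %in% names(degradome)) {
    degradome$genotype <- "all"
  }
  lens <- setNames(exon_lengths$length, exon_lengths$transcript_id)
  known <- degradome$transcript_id %in% names(lens)
  inside <- known & degradome$position >= 1 &
    degradome$position <= (lens[degradome$transcript_id] %ifna% 0L)
  if (any(!inside)) {
    warn(sprintf("build_profiles: skipped %d degradome records outside transcript bounds.",
                 sum(!inside)))
  }
  out <- degradome[inside, ] |>
    group_by(.data$genotype, .data$transcript_id, .data$position) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$genotype, .data$transcript_id, .data$position)
  attr(out, "lengths") <- lens
  class(out) <- c("bloom_profiles", class(out))
  out
}

#' Dense degradome density for one transcript in one library
#'
#' @param profiles A `bloom_profiles` tibble from [build_profiles()].
#' @param transcript_id Transcript id (all-zero profile if absent).
#' @param genotype Library label.
#' @return Integer vector of per-position counts, length = transcript
#'   length.
#' @export
profile_vector <- function(profiles, transcript_id, genotype) {
  lens <- attr(profiles, "lengths")
  if (!transcript_id %in% names(lens)) {
    abort(sprintf("Unknown transcript '%s'.", transcript_id))
  }
  v <- integer(lens[[transcript_id]])
  sub <- profiles[profiles$transcript_id == transcript_id &
                    profiles$genotype == genotype, ]
  v[sub$position] <- sub$count
  v
}

# t-plot category of a peak count c within a transcript's density.
# Rule order: single raw read -> 4; equal to a unique transcript maximum
# -> 0; equal to a shared maximum -> 1; above the transcript mean (over
# positions with signal) -> 2; otherwise -> 3.
cleavage_category <- function(c, dens) {
  nz <- dens[dens > 0]
  tmax <- max(nz)
  tmean <- mean(nz)
  if (c == 1) return(4L)
  if (c == tmax) {
    if (sum(nz == tmax) == 1L) return(0L) else return(1L)
  }
  if (c > tmean) return(2L)
  3L
}

#' Validate predicted cleavage sites against degradome profiles
#'
#' Cross-references each predicted target site with the degradome: the
#' observed peak is the maximum-count position within `window` nt of the
#' expected cleavage coordinate (ties resolved towards the expected
#' position, then leftwards). Sites with zero signal in a library yield no
#' record for that library. Each validated site gets a t-plot category:
#' 0 = unique transcript maximum, 1 = tied maximum, 2 = above the
#' transcript mean (over positions with signal) but below the maximum,
#' 3 = more than one read but at most the mean, 4 = a single raw read.
#'
#' @param sites Target-site tibble from [predict_targets()].
#' @param profiles A `bloom_profiles` tibble.
#' @param window Search half-width (nt) around the expected cleavage
#'   position.
#' @return A tibble of class `bloom_cleavage`: `mirna_id`,
#'   `transcript_id`, `genotype`, `expected_pos`, `peak_pos`,
#'   `peak_count`, `transcript_max`, `transcript_mean`, `category`.
#'   One row per site per library with signal.
#' @export
validate_cleavage <- function(sites, profiles, window = 1L) {
  genotypes <- unique(profiles$genotype)
  lens <- attr(profiles, "lengths")
  rows <- purrr::pmap(
    list(sites$mirna_id, sites$transcript_id, sites$cleavage_pos),
    function(mid, tid, expected) {
      if (!tid %in% names(lens)) return(NULL)
      purrr::map(genotypes, function(g) {
        dens <- profile_vector(profiles, tid, g)
        lo <- max(1L, expected - window)
        hi <- min(length(dens), expected + window)
        if (lo > hi) return(NULL)
        win <- dens[lo:hi]
        if (all(win == 0)) return(NULL)
        cand <- lo:hi
        best <- cand[win == max(win)]
        peak <- best[order(abs(best - expected), best)][1]
        c0 <- dens[peak]
        nz <- dens[dens > 0]
        tibble(
          mirna_id = mid, transcript_id = tid, genotype = g,
          expected_pos = expected, peak_pos = peak, peak_count = c0,
          transcript_max = max(nz), transcript_mean = mean(nz),
          category = cleavage_category(c0, dens)
        )
      }) |> list_rbind()
    }
  ) |> list_rbind()
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- tibble(mirna_id = character(), transcript_id = character(),
                   genotype = character(), expected_pos = integer(),
                   peak_pos = integer(), peak_count = integer(),
                   transcript_max = integer(), transcript_mean = numeric(),
                   category = integer())
  }
  class(rows) <- c("bloom_cleavage", class(rows))
  rows
}

#' Collapse per-library cleavage validations to one row per pair
#'
#' A (miRNA, transcript) pair counts as degradome-validated when it is
#' supported in any genotype's pooled library; per-genotype support flags
#' are retained so differential degradation between genotypes can be
#' inspected.
#'
#' @param validated A `bloom_cleavage` tibble from [validate_cleavage()].
#' @return A tibble with one row per (miRNA, transcript): `best_category`
#'   (minimum over supporting libraries), `n_genotypes`, and one logical
#'   `in_<genotype>` column per library.
#' @export
collapse_cleavage <- function(validated) {
  if (nrow(validated) == 0) {
    return(tibble(mirna_id = character(), transcript_id = character(),
                  best_category = integer(), n_genotypes = integer()))
  }
  flags <- validated |>
    mutate(flag = TRUE) |>
    select("mirna_id", "transcript_id", "genotype", "flag") |>
    distinct() |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "flag",
                       names_prefix = "in_", values_fill = FALSE)
  validated |>
    group_by(.data$mirna_id, .data$transcript_id) |>
    summarise(best_category = min(.data$category),
              n_genotypes = dplyr::n_distinct(.data$genotype),
              .groups = "drop") |>
    left_join(flags, by = c("mirna_id", "transcript_id"))
}
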