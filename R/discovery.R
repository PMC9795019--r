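#' Thresholds for the fold-back hairpin criterion
#'
#' The stem-loop test accepts a genomic locus as a plausible miRNA precursor
#' when the candidate mature arm forms a fold-back duplex with its opposing
#' flank. Thresholds follow community miRNA-annotation practice: most of the
#' mature must be paired (Watson-Crick or G:U wobble), bulges in the mature
#' stem must be small, and a real terminal loop must separate the two arms.
#'
#' @param flank Nucleotides of genomic context examined on each side of the
#'   mature locus (truncated at contig ends).
#' @param min_paired Minimum number of paired mature positions for
#'   acceptance.
#' @param max_bulge Largest tolerated internal run of unpaired mature
#'   positions (nt).
#' @param min_loop Minimum loop size (nt) between the mature arm and the
#'   opposing arm.
#' @return A list of class `hairpin_params`.
#' @export
hairpin_params <- function(flank = 120L, min_paired = 16L, max_bulge = 3L,
                           min_loop = 3L) {
  stopifnot(flank > 0, min_paired > 0, max_bulge >= 0, min_loop >= 0)
  structure(
    list(flank = as.integer(flank), min_paired = as.integer(min_paired),
         max_bulge = as.integer(max_bulge), min_loop = as.integer(min_loop)),
    class = "hairpin_params"
  )
}

# Longest internal run of FALSE between the first and last TRUE.
largest_internal_gap <- function(paired) {
  idx <- which(paired)
  if (length(idx) < 2) return(0L)
  inner <- paired[idx[1]:idx[length(idx)]]
  r <- rle(inner)
  gaps <- r$lengths[!r$values]
  if (length(gaps) == 0) 0L else max(gaps)
}

# Score one candidate arm orientation: slide a window of mature length along
# the opposing flank (anti-parallel pairing: mature position i against window
# position L+1-i) and keep the best window by paired count, then smaller
# loop, then smaller bulge. `gap_of(k)` gives the loop size for window start
# k (1-based within the flank).
best_duplex_window <- function(m_int, flank_int, gap_of, min_loop) {
  L <- length(m_int)
  n_win <- length(flank_int) - L + 1
  if (n_win < 1) return(NULL)
  best <- NULL
  for (k in seq_len(n_win)) {
    loop <- gap_of(k)
    if (loop < min_loop) next
    w <- flank_int[k:(k + L - 1)]
    pairs <- PAIR_CLASS[cbind(m_int, rev(w))]
    paired <- pairs > 0
    np <- sum(paired)
    bulge <- largest_internal_gap(paired)
    cand <- list(k = k, loop = loop, n_paired = np, bulge = bulge,
                 paired = paired)
    if (is.null(best) ||
        np > best$n_paired ||
        (np == best$n_paired && loop < best$loop) ||
        (np == best$n_paired && loop == best$loop && bulge < best$bulge)) {
      best <- cand
    }
  }
  best
}

#' Test whether a genomic locus folds back into a miRNA-like hairpin
#'
#' Extends the candidate mature locus by `params$flank` nt on each side and
#' searches both flanks for the best anti-parallel duplex with the mature
#' sequence (Watson-Crick plus G:U wobble pairing, ungapped). The locus is
#' accepted as a stem-loop when at least `min_paired` mature positions are
#' paired, the largest internal bulge in the mature stem is at most
#' `max_bulge` nt, and the loop separating the arms is at least `min_loop`
#' nt. The mature arm never spans the loop by construction (only windows
#' fully beyond the loop are considered).
#'
#' @param genome Named character vector of contig sequences.
#' @param contig Contig name.
#' @param start,end 1-based inclusive mature coordinates on the contig.
#' @param strand `"+"` or `"-"` (mature read 5' to 3' on that strand).
#' @param params A [hairpin_params()] object.
#' @return A list of class `bloom_hairpin`: `accepted` (logical), `reason`
#'   (`"ok"`, `"no_window"`, `"too_few_paired"`, `"bulge_too_large"`),
#'   `arm` (`"5p"`/`"3p"`), `n_paired`, `largest_bulge`, `loop_size`,
#'   `precursor` (sequence), `structure` (dot-bracket), `mature_offset`
#'   (1-based within precursor), and the locus.
#' @examples
#' mat <- "AGCTAGGCTAGCTAAGCTTGA"
#' hp <- paste0(mat, "ATTACGTAC",
#'              as.character(Biostrings::reverseComplement(Biostrings::DNAString(mat))))
#' g <- c(chr = paste0(strrep("A", 30), hp, strrep("C", 30)))
#' fold_back(g, "chr", 31, 30 + nchar(mat), "+")$accepted
#' @export
fold_back <- function(genome, contig, start, end, strand = "+",
                      params = hairpin_params()) {
  if (!contig %in% names(genome)) abort(sprintf("Unknown contig '%s'", contig))
  cs <- normalize_seq(genome[[contig]])
  clen <- nchar(cs)
  if (start < 1 || end > clen || start > end) {
    abort(sprintf("Locus %s:%d-%d lies outside contig bounds (1-%d).",
                  contig, start, end, clen))
  }
  mature_fwd <- substr(cs, start, end)
  up_fwd <- substr(cs, max(1L, start - params$flank), start - 1L)
  down_fwd <- substr(cs, end + 1L, min(clen, end + params$flank))
  if (strand == "-") {
    mature <- revcomp(mature_fwd)
    upstream <- revcomp(down_fwd)    # 5' of mature in transcript orientation
    downstream <- revcomp(up_fwd)
  } else {
    mature <- mature_fwd
    upstream <- up_fwd
    downstream <- down_fwd
  }
  m_int <- seq_to_int(mature)
  L <- length(m_int)

  # mature as 5p arm: opposing arm downstream; loop = offset of window start
  best5 <- if (nchar(downstream) >= L) {
    best_duplex_window(m_int, seq_to_int(downstream),
                       gap_of = function(k) k - 1L,
                       min_loop = params$min_loop)
  }
  # mature as 3p arm: opposing arm upstream; loop = distance from window end
  # to the mature start
  ulen <- nchar(upstream)
  best3 <- if (ulen >= L) {
    best_duplex_window(m_int, seq_to_int(upstream),
                       gap_of = function(k) ulen - (k + L - 1L),
                       min_loop = params$min_loop)
  }

  arm <- NULL
  best <- NULL
  for (cand in list(list(w = best5, arm = "5p"), list(w = best3, arm = "3p"))) {
    if (is.null(cand$w)) next
    if (is.null(best) || cand$w$n_paired > best$n_paired) {
      best <- cand$w
      arm <- cand$arm
    }
  }

  locus <- list(contig = contig, start = start, end = end, strand = strand)
  fail <- function(reason) {
    structure(list(accepted = FALSE, reason = reason, arm = arm,
                   n_paired = if (is.null(best)) 0L else best$n_paired,
                   largest_bulge = if (is.null(best)) NA_integer_ else best$bulge,
                   loop_size = if (is.null(best)) NA_integer_ else best$loop,
                   precursor = NA_character_, structure = NA_character_,
                   mature_offset = NA_integer_, mature_length = L,
                   locus = locus),
              class = "bloom_hairpin")
  }
  if (is.null(best)) return(fail("no_window"))
  if (best$n_paired < params$min_paired) return(fail("too_few_paired"))
  if (best$bulge > params$max_bulge) return(fail("bulge_too_large"))

  # Assemble precursor sequence and dot-bracket in transcript orientation.
  if (arm == "5p") {
    win_start <- best$k
    loop_seq <- substr(downstream, 1L, win_start - 1L)
    win_seq <- substr(downstream, win_start, win_start + L - 1L)
    precursor <- paste0(mature, loop_seq, win_seq)
    mature_offset <- 1L
    db <- paste0(
      paste(ifelse(best$paired, "(", "."), collapse = ""),
      strrep(".", nchar(loop_seq)),
      paste(rev(ifelse(best$paired, ")", ".")), collapse = "")
    )
  } else {
    win_start <- best$k
    win_seq <- substr(upstream, win_start, win_start + L - 1L)
    loop_seq <- substr(upstream, win_start + L, ulen)
    precursor <- paste0(win_seq, loop_seq, mature)
    mature_offset <- nchar(win_seq) + nchar(loop_seq) + 1L
    db <- paste0(
      paste(rev(ifelse(best$paired, "(", ".")), collapse = ""),
      strrep(".", nchar(loop_seq)),
      paste(ifelse(best$paired, ")", "."), collapse = "")
    )
  }
  structure(
    list(accepted = TRUE, reason = "ok", arm = arm,
         n_paired = best$n_paired, largest_bulge = best$bulge,
         loop_size = best$loop, precursor = precursor, structure = db,
         mature_offset = mature_offset, mature_length = L, locus = locus),
    class = "bloom_hairpin"
  )
}

#' @export
print.bloom_hairpin <- function(x, ...) {
  cat(sprintf(
    "<bloom_hairpin> %s:%d-%d(%s) %s arm=%s paired=%d bulge=%s loop=%s\n",
    x$locus$contig, x$locus$start, x$locus$end, x$locus$strand,
    if (x$accepted) "ACCEPT" else paste0("REJECT[", x$reason, "]"),
    x$arm %||% "-", x$n_paired, x$largest_bulge, x$loop_size
  ))
  invisible(x)
}

#' Classify tags into the five miRNA evidence groups
#'
#' Applies the five-branch decision tree that separates known and predicted
#' miRNAs by three evidence bits — mature-reference hit, genome mappability
#' of the reference precursor, genome mappability of the tag itself — plus
#' the fold-back hairpin test at the tag's genomic loci:
#'
#' * `gp1`: hits the mature reference and the matching reference precursor
#'   maps to the genome;
#' * `gp2a`: hits the mature reference, precursor absent from the genome,
#'   but the tag maps and at least one of its loci folds into a hairpin;
#' * `gp2b`: as gp2a but no tag locus folds into a hairpin;
#' * `gp3`: hits the mature reference and the tag does not map to the
#'   genome at all;
#' * `gp4` (predicted/novel): no mature-reference hit, but the tag maps to
#'   the genome and some locus folds into a hairpin;
#' * anything else is `UNCLASSIFIED` and is not reported as a miRNA.
#'
#' Branches are evaluated in that fixed order; multi-locus tags use
#' existential ("any locus") semantics for hairpin acceptance.
#'
#' @param evidence Evidence tibble from [collect_evidence()].
#' @param genome Named character vector of contigs (for the hairpin test).
#' @param params [hairpin_params()] controlling the fold-back criterion.
#' @param ids Optional character vector of ids; defaults to `mir_0001`-style
#'   labels in input order.
#' @return A tibble of class `bloom_mirnas`: `id`, `sequence`, `group`
#'   (`gp1`, `gp2a`, `gp2b`, `gp3`, `gp4`, `UNCLASSIFIED`), `known`
#'   (TRUE for gp1-gp3, FALSE for gp4, NA for unclassified), `mature_hit`,
#'   `hairpin_locus` (contig:start-end:strand of the accepting locus, if
#'   any), `precursor`, `structure`.
#' @export
classify_tags <- function(evidence, genome, params = hairpin_params(),
                          ids = NULL) {
  needed <- c("sequence", "hits_mature_ref", "precursor_maps_genome",
              "tag_maps_genome", "genome_loci")
  if (!all(needed %in% names(evidence))) {
    abort("`evidence` must come from collect_evidence().")
  }
  if (is.null(ids)) {
    ids <- sprintf("mir_%04d", seq_len(nrow(evidence)))
  }
  rows <- purrr::pmap(
    list(seq_len(nrow(evidence)), evidence$sequence,
         evidence$hits_mature_ref, evidence$precursor_maps_genome,
         evidence$tag_maps_genome, evidence$genome_loci,
         evidence$mature_hit),
    function(i, s, mat, pre_g, tag_g, loci, mat_hit) {
      hp_accept <- NULL
      hp_of_locus <- function() {
        # first accepting locus, if any
        for (j in seq_len(nrow(loci))) {
          hp <- fold_back(genome, loci$subject[[j]], loci$start[[j]],
                          loci$end[[j]], loci$strand[[j]], params = params)
          if (hp$accepted) return(hp)
        }
        NULL
      }
      group <- "UNCLASSIFIED"
      if (mat && pre_g) {
        group <- "gp1"
        hp_accept <- if (tag_g && nrow(loci) > 0) hp_of_locus() else NULL
      } else if (mat && !pre_g && tag_g) {
        hp_accept <- hp_of_locus()
        group <- if (!is.null(hp_accept)) "gp2a" else "gp2b"
      } else if (mat && !tag_g) {
        group <- "gp3"
      } else if (!mat && tag_g) {
        hp_accept <- hp_of_locus()
        group <- if (!is.null(hp_accept)) "gp4" else "UNCLASSIFIED"
      }
      known <- if (group == "UNCLASSIFIED") NA else group != "gp4"
      tibble(
        id = ids[[i]],
        sequence = s,
        group = group,
        known = known,
        mature_hit = mat_hit,
        hairpin_locus = if (!is.null(hp_accept)) {
          sprintf("%s:%d-%d:%s", hp_accept$locus$contig,
                  hp_accept$locus$start, hp_accept$locus$end,
                  hp_accept$locus$strand)
        } else NA_character_,
        precursor = if (!is.null(hp_accept)) hp_accept$precursor else NA_character_,
        structure = if (!is.null(hp_accept)) hp_accept$structure else NA_character_
      )
    }
  )
  out <- list_rbind(rows)
  class(out) <- c("bloom_mirnas", class(out))
  out
}

#' Summarise classified tags into a per-group count table
#'
#' Tabulates classified miRNA records per evidence group, with known
#' (gp1-gp3) and predicted (gp4) subtotals and a grand total — the
#' standard summary shape for a known/predicted miRNA census. Both
#' precursor-level counts (records with a distinct hairpin locus or
#' reference precursor) and unique mature-sequence counts are reported.
#'
#' @param records A `bloom_mirnas` tibble from [classify_tags()].
#' @return A tibble of class `bloom_group_summary` with columns `category`
#'   (`known miRNA`, `predicted miRNA`, `Total`), `group`, `n_mirna`
#'   (unique mature sequences) and `n_premirna` (distinct precursor loci or
#'   reference hits backing them).
#' @export
summarize_groups <- function(records) {
  groups <- c("gp1", "gp2a", "gp2b", "gp3", "gp4")
  cls <- records[records$group %in% groups, , drop = FALSE]
  per_group <- purrr::map(groups, function(g) {
    sub <- cls[cls$group == g, , drop = FALSE]
    pre <- unique(stats::na.omit(c(
      sub$hairpin_locus[!is.na(sub$hairpin_locus)],
      sub$mature_hit[is.na(sub$hairpin_locus)]
    )))
    tibble(
      category = if (g == "gp4") "predicted miRNA" else "known miRNA",
      group = g,
      n_mirna = length(unique(sub$sequence)),
      n_premirna = if (nrow(sub) == 0) 0L else max(length(pre), 0L)
    )
  }) |> list_rbind()
  totals <- per_group |>
    group_by(.data$category) |>
    summarise(n_mirna = sum(.data$n_mirna), n_premirna = sum(.data$n_premirna),
              .groups = "drop") |>
    mutate(group = "total")
  grand <- tibble(
    category = "Total", group = "total",
    n_mirna = sum(per_group$n_mirna),
    n_premirna = sum(per_group$n_premirna)
  )
  out <- bind_rows(per_group, totals, grand) |>
    relocate("category", "group")
  class(out) <- c("bloom_group_summary", class(out))
  out
}
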