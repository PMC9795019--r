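# Independent oracles used to cross-check the implementation. These are
# deliberately naive (window-by-window loops) and share no code with the
# package internals beyond sequence containers.

DNAB <- c("A", "C", "G", "T")

oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# All-windows Hamming-distance scan; subject-forward coordinates.
oracle_map <- function(tag, subjects, max_mm = 0, strand = "both") {
  pats <- list(`+` = tag)
  if (strand == "both") pats$`-` <- oracle_revcomp(tag)
  out <- list()
  for (st in names(pats)) {
    p <- strsplit(pats[[st]], "")[[1]]
    L <- length(p)
    for (nm in names(subjects)) {
      s <- strsplit(subjects[[nm]], "")[[1]]
      if (L > length(s)) next
      for (i in seq_len(length(s) - L + 1)) {
        mm <- sum(p != s[i:(i + L - 1)])
        if (mm <= max_mm) {
          out[[length(out) + 1]] <- data.frame(
            subject = nm, start = i, end = i + L - 1, strand = st,
            mismatches = mm
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(subject = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$subject, df$start, df$strand), , drop = FALSE]
}

# Literal evaluation of the five classification predicates for one
# evidence row; hairpin decisions via fold_back (the stated in-repo
# criterion), applied locus by locus in a plain loop.
oracle_classify_one <- function(ev, genome, params = hairpin_params()) {
  any_hairpin <- function() {
    loci <- ev$genome_loci[[1]]
    for (j in seq_len(nrow(loci))) {
      hp <- fold_back(genome, loci$subject[j], loci$start[j], loci$end[j],
                      loci$strand[j], params = params)
      if (hp$accepted) return(TRUE)
    }
    FALSE
  }
  mat <- ev$hits_mature_ref
  pre_g <- ev$precursor_maps_genome
  tag_g <- ev$tag_maps_genome
  if (mat && pre_g) return("gp1")
  if (mat && !pre_g && tag_g) {
    return(if (any_hairpin()) "gp2a" else "gp2b")
  }
  if (mat && !tag_g) return("gp3")
  if (!mat && tag_g) {
    return(if (any_hairpin()) "gp4" else "UNCLASSIFIED")
  }
  "UNCLASSIFIED"
}

# Brute-force target-site scan: explicit per-window, per-position penalty.
oracle_scan <- function(mirna, transcript, params = target_params()) {
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(transcript, "")[[1]]
  L <- length(m)
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  if (L > length(t)) {
    return(data.frame(start = integer(), penalty = numeric()))
  }
  for (s in seq_len(length(t) - L + 1)) {
    pen <- 0
    for (i in seq_len(L)) {
      tb <- t[s + L - i]
      cost <- if (wc[[m[i]]] == tb) {
        0
      } else if ((m[i] == "G" && tb == "T") || (m[i] == "T" && tb == "G")) {
        params$gu
      } else {
        params$mismatch
      }
      if (i >= params$seed_start && i <= params$seed_end) {
        cost <- cost * params$seed_mult
      }
      pen <- pen + cost
    }
    if (pen <= params$max_penalty + 1e-9) {
      out[[length(out) + 1]] <- data.frame(start = s, penalty = pen)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), penalty = numeric()))
  }
  do.call(rbind, out)
}

random_seq <- function(len) {
  paste(sample(DNAB, len, replace = TRUE), collapse = "")
}

# Count table with library columns from a design and a numeric matrix.
as_counts <- function(m, design, ids = sprintf("f%04d", seq_len(nrow(m)))) {
  colnames(m) <- design$library
  dplyr::bind_cols(tibble::tibble(feature_id = ids), tibble::as_tibble(m))
}

# A tiny config so pipeline-level tests stay fast.
small_config <- function(seed = 7, ...) {
  defaults <- list(
    seed = seed,
    contig_length = 12000L,
    n_mir = c(gp1 = 3L, gp2a = 2L, gp2b = 2L, gp3 = 2L, gp4 = 3L),
    n_transcripts = 30L,
    transcript_len_range = c(400L, 900L),
    n_planted_modules = 4L,
    n_extra_de_mirna = 2L,
    n_extra_de_mrna = 3L,
    n_decoy_tags = 20L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
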