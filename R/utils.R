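#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols distinct
#'   across n row_number rename count pull relocate if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap
#'   list_rbind keep discard
#' @importFrom stats pf pt setNames rnbinom runif rnorm cor sd var
#' @importFrom utils head tail
NULL

# Internal sequence helpers. Sequences are handled as uppercase DNA (U -> T)
# throughout; I/O converts at the boundary.

DNA_BASES <- c("A", "C", "G", "T")

normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

is_valid_seq <- function(x) {
  grepl("^[ACGT]+$", normalize_seq(x))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_to_int <- function(x) {
  # A=1, C=2, G=3, T=4
  match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES)
}

#' Pairing table for an RNA duplex in DNA alphabet
#'
#' Watson-Crick pairs (A:T, T:A, G:C, C:G) score 2, G:U wobble pairs
#' (G:T, T:G) score 1, anything else 0. Used by both the fold-back hairpin
#' test and the target scan.
#' @noRd
pair_class_matrix <- function() {
  m <- matrix(0L, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 1L
  m
}

PAIR_CLASS <- pair_class_matrix()

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Derive a reproducible sub-seed for a named sub-stream so regenerating one
# component never perturbs another. Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1009L + as.integer(h %% 99991L)) %% 2147483587L
}

`%ifna%` <- function(x, y) ifelse(is.na(x), y, x)
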