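#' Counts-per-million normalisation
#'
#' Scales each library so its counts sum to one million:
#' `cpm[i, j] = raw[i, j] / colsum(j) * 1e6`. Rank order within a library
#' is preserved.
#'
#' @param counts A data frame with one id column (first column, or named by
#'   `id_col`) and one non-negative count column per library.
#' @param id_col Name of the feature-id column.
#' @return A tibble of the same shape with normalised values.
#' @export
normalize_cpm <- function(counts, id_col = names(counts)[1]) {
  lib_cols <- setdiff(names(counts), id_col)
  m <- as.matrix(counts[lib_cols])
  if (any(m < 0)) abort("Counts must be non-negative.")
  totals <- colSums(m)
  zero <- totals == 0
  if (any(zero)) {
    abort(sprintf("Library with zero total count: %s",
                  paste(lib_cols[zero], collapse = ", ")))
  }
  cpm <- sweep(m, 2, totals, "/") * 1e6
  bind_cols(counts[id_col], as_tibble(cpm))
}

#' Fragments per kilobase of exon per million mapped reads
#'
#' `FPKM = fragments / (mapped_reads / 1e6 * exon_length / 1e3)` with
#' `exon_length` in nucleotides. Vectorised; zero fragments give zero.
#'
#' @param fragments Fragment (read-pair) count(s) on the feature.
#' @param mapped_reads Total mapped reads in the library (> 0).
#' @param exon_length Feature exon length in nt (> 0).
#' @return Numeric FPKM value(s).
#' @examples
#' fpkm(100, 1e7, 2000)  # 5
#' @export
fpkm <- function(fragments, mapped_reads, exon_length) {
  if (any(mapped_reads <= 0)) abort("`mapped_reads` must be > 0.")
  if (any(exon_length <= 0)) abort("`exon_length` must be > 0.")
  if (any(fragments < 0)) abort("`fragments` must be non-negative.")
  fragments / (mapped_reads / 1e6 * exon_length / 1e3)
}

# log2(CPM + 1) matrix keyed by feature, restricted to given libraries.
log_cpm_matrix <- function(counts, id_col, libraries) {
  norm <- normalize_cpm(counts, id_col = id_col)
  m <- log2(as.matrix(norm[libraries]) + 1)
  rownames(m) <- norm[[id_col]]
  m
}

# Vectorised one-way ANOVA F test across the rows of a matrix.
# Returns a tibble with f_stat and p_value; rows with zero total variance
# get p = 1 by convention.
row_oneway_f <- function(m, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- ncol(m)
  if (k < 2) abort("Need >= 2 groups for ANOVA.")
  if (any(table(groups) < 2)) abort("Need >= 2 replicates per group.")
  grand <- rowMeans(m)
  sst <- rowSums((m - grand)^2)
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    gm <- rowMeans(m[, idx, drop = FALSE])
    ssw <- ssw + rowSums((m[, idx, drop = FALSE] - gm)^2)
  }
  ssb <- sst - ssw
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  # degenerate rows: no variance at all -> F = 0/0; call them null
  p[sst < 1e-12] <- 1
  f[sst < 1e-12] <- 0
  # within-group variance zero but between positive -> F = Inf, p = 0
  p[is.infinite(f)] <- 0
  tibble(f_stat = unname(f), p_value = unname(p))
}

# significance tier flags with the DEM boundary convention (P <= tier)
tier_flags <- function(p, tiers = c(0.01, 0.05, 0.1)) {
  out <- purrr::map(tiers, function(a) p <= a)
  names(out) <- sprintf("sig_%s", vapply(tiers, function(a) {
    sub("^0\\.", "", format(a))
  }, character(1)))
  as_tibble(out)
}

#' Differentially expressed miRNA/gene calling by one-way ANOVA
#'
#' For each feature, a one-way ANOVA F test on `log2(CPM + 1)` across the
#' levels of `factor` (developmental stages within one genotype, or
#' genotypes within one stage). Features with no variance anywhere get
#' `p = 1` by convention. Significance tiers use the inclusive boundary
#' `P <= tier`.
#'
#' @param counts Count table (id column + library columns).
#' @param design Design tibble from [bloom_design()] covering the count
#'   columns.
#' @param factor `"stage"` (test across stages, within one genotype) or
#'   `"genotype"` (across genotypes, within one stage).
#' @param within The genotype (resp. stage) the test is restricted to.
#' @param tiers Significance tiers reported as flag columns.
#' @param id_col Feature id column name.
#' @return A tibble of class `bloom_de`: `feature_id`, `contrast`,
#'   `f_stat`, `p_value`, and one `sig_*` flag per tier.
#' @export
dem_anova <- function(counts, design, factor = c("stage", "genotype"),
                      within, tiers = c(0.01, 0.05, 0.1),
                      id_col = names(counts)[1]) {
  factor <- match.arg(factor)
  sub <- if (factor == "stage") {
    filter(design, .data$genotype == within)
  } else {
    filter(design, .data$stage == within)
  }
  if (nrow(sub) == 0) abort(sprintf("No libraries for within = '%s'.", within))
  missing_libs <- setdiff(sub$library, names(counts))
  if (length(missing_libs) > 0) {
    abort(sprintf("Count table lacks libraries: %s",
                  paste(missing_libs, collapse = ", ")))
  }
  m <- log_cpm_matrix(counts, id_col, sub$library)
  groups <- if (factor == "stage") sub$stage else sub$genotype
  res <- row_oneway_f(m, droplevels(factor(groups)))
  out <- bind_cols(
    tibble(feature_id = rownames(m),
           contrast = sprintf("%s:across_%ss", within, factor)),
    res,
    tier_flags(res$p_value, tiers)
  )
  class(out) <- c("bloom_de", class(out))
  out
}

#' Pairwise differential-expression tests for miRNAs
#'
#' Runs the same ANOVA machinery on two groups at a time (equivalent to an
#' equal-variance t test) for each requested pairwise contrast, and adds a
#' log2 fold change and a direction call. A feature is significant when
#' `P <= alpha` (inclusive boundary); `direction` is `up` when the
#' numerator group (B in "BvsA") has the higher mean.
#'
#' @param counts Count table (id column + library columns).
#' @param design Design tibble.
#' @param contrasts Contrast tibble from [bloom_contrasts()] (or a subset).
#' @param alpha Significance boundary (inclusive).
#' @param pseudocount Added to group-mean CPM before the fold-change ratio.
#' @param tiers Tier flags to report.
#' @param id_col Feature id column name.
#' @return A `bloom_de` tibble: `feature_id`, `contrast`, `family`,
#'   `p_value`, `log2_fc`, `significant`, `direction`, tier flags.
#' @export
dem_pairwise <- function(counts, design, contrasts = bloom_contrasts(design),
                         alpha = 0.05, pseudocount = 1,
                         tiers = c(0.01, 0.05, 0.1),
                         id_col = names(counts)[1]) {
  norm <- normalize_cpm(counts, id_col = id_col)
  rows <- purrr::pmap(contrasts, function(contrast, family, within,
                                          group_b, group_a) {
    libs_b <- if (family == "developmental") {
      design_libraries(design, genotype = within, stage = group_b)
    } else {
      design_libraries(design, genotype = group_b, stage = within)
    }
    libs_a <- if (family == "developmental") {
      design_libraries(design, genotype = within, stage = group_a)
    } else {
      design_libraries(design, genotype = group_a, stage = within)
    }
    m <- log2(as.matrix(norm[c(libs_a, libs_b)]) + 1)
    res <- row_oneway_f(m, rep(c("A", "B"), c(length(libs_a), length(libs_b))))
    mean_a <- rowMeans(as.matrix(norm[libs_a]))
    mean_b <- rowMeans(as.matrix(norm[libs_b]))
    lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
    sig <- res$p_value <= alpha
    bind_cols(
      tibble(feature_id = norm[[id_col]], contrast = contrast,
             family = family, p_value = res$p_value, log2_fc = lfc,
             significant = sig,
             direction = dplyr::case_when(
               sig & lfc > 0 ~ "up",
               sig & lfc < 0 ~ "down",
               .default = "none"
             )),
      tier_flags(res$p_value, tiers)
    )
  })
  out <- list_rbind(rows)
  class(out) <- c("bloom_de", class(out))
  out
}

#' Differentially expressed gene calling with a joint fold-change/P rule
#'
#' Per gene and contrast: fold change is the ratio of group-mean CPM
#' (numerator group B), with a pseudocount for stability; the P value comes
#' from a Welch t test on `log2(CPM + 1)`. A gene is called differentially
#' expressed only when both conditions hold: fold change > `fc_up` or <
#' `fc_down`, and `P < alpha` (strict boundary).
#'
#' @inheritParams dem_pairwise
#' @param fc_up,fc_down Fold-change thresholds (defaults 2 and 0.5).
#' @param alpha Significance boundary (strict, `P < alpha`).
#' @return A `bloom_de` tibble: `feature_id`, `contrast`, `family`,
#'   `fold_change`, `log2_fc`, `p_value`, `significant`, `direction`.
#' @export
deg_call <- function(counts, design, contrasts = bloom_contrasts(design),
                     fc_up = 2, fc_down = 0.5, alpha = 0.05,
                     pseudocount = 1, id_col = names(counts)[1]) {
  norm <- normalize_cpm(counts, id_col = id_col)
  rows <- purrr::pmap(contrasts, function(contrast, family, within,
                                          group_b, group_a) {
    libs_b <- if (family == "developmental") {
      design_libraries(design, genotype = within, stage = group_b)
    } else {
      design_libraries(design, genotype = group_b, stage = within)
    }
    libs_a <- if (family == "developmental") {
      design_libraries(design, genotype = within, stage = group_a)
    } else {
      design_libraries(design, genotype = group_a, stage = within)
    }
    if (length(libs_a) < 2 || length(libs_b) < 2) {
      abort(sprintf("Contrast %s has a group with < 2 replicates.", contrast))
    }
    la <- log2(as.matrix(norm[libs_a]) + 1)
    lb <- log2(as.matrix(norm[libs_b]) + 1)
    p <- row_welch_p(la, lb)
    mean_a <- rowMeans(as.matrix(norm[libs_a]))
    mean_b <- rowMeans(as.matrix(norm[libs_b]))
    fc <- (mean_b + pseudocount) / (mean_a + pseudocount)
    sig <- (fc > fc_up | fc < fc_down) & p < alpha
    tibble(feature_id = norm[[id_col]], contrast = contrast, family = family,
           fold_change = fc, log2_fc = log2(fc), p_value = p,
           significant = sig,
           direction = dplyr::case_when(
             sig & fc > fc_up ~ "up",
             sig & fc < fc_down ~ "down",
             .default = "none"
           ))
  })
  out <- list_rbind(rows)
  class(out) <- c("bloom_de", class(out))
  out
}

# Row-wise Welch t-test p-values between two matrices with equal rows.
row_welch_p <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- apply(a, 1, var)
  vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  # both groups constant and equal -> 0/0; call null
  p[se2 < 1e-24 & abs(mb - ma) < 1e-12] <- 1
  # both constant but different -> infinitely confident
  p[se2 < 1e-24 & abs(mb - ma) >= 1e-12] <- 0
  unname(p)
}

#' Set algebra over differential-expression result collections
#'
#' `de_sets()` extracts the significant feature-id sets per contrast;
#' `set_intersection()`, `set_union()` and `set_exclusive()` implement the
#' "co-expressed across X" (intersection), "unified set" (union) and
#' "specific to X" (difference against all the other sets) operations used
#' to compare differential features across stages and genotypes.
#' `venn_regions()` tabulates every membership pattern.
#'
#' @param de A `bloom_de` tibble.
#' @param sets A named list of character vectors (feature-id sets).
#' @param which For `set_exclusive()`, the name of the set whose exclusive
#'   members are wanted.
#' @return `de_sets()`: named list of id vectors. `set_intersection()` /
#'   `set_union()` / `set_exclusive()`: character vectors.
#'   `venn_regions()`: tibble with one row per observed membership pattern
#'   and its member count.
#' @name set-algebra
NULL

#' @rdname set-algebra
#' @export
de_sets <- function(de) {
  stopifnot(all(c("feature_id", "contrast") %in% names(de)))
  sig <- if ("significant" %in% names(de)) {
    de$significant
  } else {
    de$sig_05
  }
  split(de$feature_id[sig], de$contrast[sig])
}

#' @rdname set-algebra
#' @export
set_intersection <- function(sets) {
  if (length(sets) == 0) return(character(0))
  Reduce(intersect, sets)
}

#' @rdname set-algebra
#' @export
set_union <- function(sets) {
  unique(unlist(sets, use.names = FALSE)) %||% character(0)
}

#' @rdname set-algebra
#' @export
set_exclusive <- function(sets, which) {
  setdiff(sets[[which]], set_union(sets[setdiff(names(sets), which)]))
}

#' @rdname set-algebra
#' @export
venn_regions <- function(sets) {
  ids <- set_union(sets)
  if (length(ids) == 0) {
    return(tibble(pattern = character(), n = integer()))
  }
  membership <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (is.null(dim(membership))) {
    membership <- matrix(membership, nrow = length(ids))
  }
  pattern <- apply(membership, 1, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  as_tibble(table(pattern)) |>
    mutate(n = as.integer(.data$n)) |>
    arrange(dplyr::desc(.data$n), .data$pattern)
}
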