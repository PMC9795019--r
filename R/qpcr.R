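#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale; then for each sample
#' and target gene, `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt_sample - dCt_calibrator`, and `RQ = 2^-ddCt`. The
#' calibrator sample has `RQ = 1` exactly. The reference gene is the
#' assay's internal control (e.g. `EF1-alpha` for mRNA assays, `U6` for
#' miRNA assays).
#'
#' @param measurements A data frame with columns `sample`, `gene`,
#'   `role` (`"target"` or `"reference"`) and `ct`; multiple rows per
#'   (sample, gene, role) are treated as technical replicates and
#'   averaged.
#' @param calibrator The sample label used as calibrator.
#' @return A tibble: `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `rq`.
#' @examples
#' ct <- tibble::tibble(
#'   sample = rep(c("BS", "DE"), each = 2),
#'   gene = rep(c("geneX", "EF1a"), 2),
#'   role = rep(c("target", "reference"), 2),
#'   ct = c(23, 20, 21, 20)
#' )
#' relative_quantity(ct, calibrator = "BS")
#' @export
relative_quantity <- function(measurements, calibrator) {
  needed <- c("sample", "gene", "role", "ct")
  if (!all(needed %in% names(measurements))) {
    abort("`measurements` needs columns sample, gene, role, ct.")
  }
  if (any(!is.finite(measurements$ct)) || any(measurements$ct <= 0)) {
    abort("Ct values must be finite and positive.")
  }
  if (!calibrator %in% measurements$sample) {
    abort(sprintf("Calibrator sample '%s' not present.", calibrator))
  }
  avg <- measurements |>
    group_by(.data$sample, .data$gene, .data$role) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- avg |>
    filter(.data$role == "reference") |>
    group_by(.data$sample) |>
    summarise(ct_ref = mean(.data$ct), .groups = "drop")
  tgt <- filter(avg, .data$role == "target")
  missing_ref <- setdiff(unique(tgt$sample), ref$sample)
  if (length(missing_ref) > 0) {
    abort(sprintf("Samples without a reference-gene Ct: %s",
                  paste(missing_ref, collapse = ", ")))
  }
  d <- tgt |>
    left_join(ref, by = "sample") |>
    mutate(delta_ct = .data$ct - .data$ct_ref)
  cal <- d |>
    filter(.data$sample == calibrator) |>
    select("gene", delta_ct_cal = "delta_ct")
  if (nrow(cal) == 0) {
    abort(sprintf("Calibrator '%s' has no target-gene measurements.",
                  calibrator))
  }
  d |>
    inner_join(cal, by = "gene") |>
    mutate(delta_delta_ct = .data$delta_ct - .data$delta_ct_cal,
           rq = 2^(-.data$delta_delta_ct)) |>
    select("sample", "gene", "delta_ct", "delta_delta_ct", "rq")
}

#' Correlate a qPCR profile with a sequencing expression profile
#'
#' Pearson correlation of the two series on the log2 scale, after aligning
#' them over the same (genotype, stage) cells. A constant series has no
#' defined correlation and is reported as `NA` with a message.
#'
#' @param rq Numeric vector of relative quantities (or any positive
#'   expression measure) per cell.
#' @param expression Numeric vector of pipeline expression values for the
#'   same cells, in the same order.
#' @param log2_scale Correlate on the log2 scale (default).
#' @param offset Added before taking logs, for zero handling.
#' @return A single correlation coefficient (possibly `NA`).
#' @export
profile_correlation <- function(rq, expression, log2_scale = TRUE,
                                offset = 0) {
  if (length(rq) != length(expression)) {
    abort("Series lengths differ.")
  }
  x <- if (log2_scale) log2(rq + offset) else rq
  y <- if (log2_scale) log2(expression + offset) else expression
  if (sd(x) == 0 || sd(y) == 0) {
    inform("profile_correlation: constant series, correlation undefined.")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Simulate qPCR Ct measurements from planted expression profiles
#'
#' Synthesises plausible Ct values for selected miRNA-target pairs from
#' the synthetic dataset's planted per-cell means: the target Ct decreases
#' by one cycle per doubling of expression, the reference gene is flat,
#' and Gaussian technical noise is added. Used to exercise the 2^-ddCt
#' and correlation utilities end-to-end.
#'
#' @param sim A `bloom_sim` object.
#' @param feature_ids Features to assay (default: all module miRNAs and
#'   targets).
#' @param noise_sd Technical noise on the Ct scale (cycles).
#' @param n_technical Technical replicates per reaction.
#' @return A tibble with columns `genotype`, `stage`, `sample`, `gene`,
#'   `role`, `ct`.
#' @export
simulate_qpcr <- function(sim, feature_ids = NULL, noise_sd = 0.15,
                          n_technical = 3L) {
  truth <- sim$truth
  if (is.null(feature_ids)) {
    feature_ids <- unique(c(truth$modules$mirna_id,
                            truth$modules$transcript_id))
  }
  design <- sim$config$design
  cells <- distinct(design, .data$genotype, .data$stage)
  withr::with_seed(sub_seed(sim$config$seed, "qpcr"), {
    rows <- purrr::map(feature_ids, function(f) {
      eff <- truth$cell_effects |> filter(.data$feature_id == f)
      purrr::pmap(cells, function(genotype, stage) {
        lfc <- 0
        hit <- eff |> filter(.data$genotype == !!genotype,
                             .data$stage == !!stage)
        if (nrow(hit) > 0) lfc <- sum(hit$log2fc)
        mu <- log2(sim$config$mean_count) + lfc
        sample_lab <- paste(genotype, stage, sep = "_")
        tibble(
          genotype = as.character(genotype), stage = as.character(stage),
          sample = sample_lab,
          gene = c(rep(f, n_technical), rep("reference", n_technical)),
          role = rep(c("target", "reference"), each = n_technical),
          ct = c(30 - mu + rnorm(n_technical, 0, noise_sd),
                 20 + rnorm(n_technical, 0, noise_sd))
        )
      }) |> list_rbind()
    }) |> list_rbind()
  })
  rows
}
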