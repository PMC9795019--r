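#' Library design for the three-genotype, four-stage flowering experiment
#'
#' Builds the table of sequencing libraries: three genotypes (`FD`, an
#' early-flowering cultivar; `MU`, its earlier-flowering mutant; `LH`, a
#' late-flowering cultivar) sampled at four petal developmental stages
#' (`BS` blooming, `IF` initial flowering, `FB` full blooming, `DE` decay),
#' with replicated libraries per cell. Library labels follow the
#' `<genotype>_<stage>_<replicate>` convention (e.g. `FD_BS_1`).
#'
#' @param genotypes Character vector of genotype codes.
#' @param stages Character vector of developmental stage codes, in
#'   chronological order.
#' @param replicates Number of biological replicates per genotype x stage
#'   cell (must be >= 2 so that per-cell variances exist).
#' @return A tibble with columns `library`, `genotype`, `stage`, `replicate`.
#'   `stage` and `genotype` are factors with levels in the supplied order.
#' @examples
#' bloom_design()
#' @export
bloom_design <- function(genotypes = c("FD", "MU", "LH"),
                         stages = c("BS", "IF", "FB", "DE"),
                         replicates = 3) {
  if (replicates < 2) {
    abort("`replicates` must be >= 2 so per-cell variances are estimable.")
  }
  grid <- expand.grid(
    replicate = seq_len(replicates),
    stage = stages,
    genotype = genotypes,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  out <- tibble(
    library = paste(grid$genotype, grid$stage, grid$replicate, sep = "_"),
    genotype = factor(grid$genotype, levels = genotypes),
    stage = factor(grid$stage, levels = stages),
    replicate = as.integer(grid$replicate)
  )
  stopifnot(!anyDuplicated(out$library))
  out
}

#' Enumerate the pairwise contrasts implied by a design
#'
#' Developmental contrasts compare two stages within one genotype (named
#' e.g. `FD:DEvsBS`, later stage first); varietal contrasts compare two
#' genotypes within one stage (e.g. `BS:MUvsFD`). These are the contrast
#' families whose union sets feed module integration.
#'
#' @param design A design tibble from [bloom_design()].
#' @return A tibble with columns `contrast`, `family`
#'   (`"developmental"`/`"varietal"`), `within`, `group_b`, `group_a`
#'   (the contrast is B vs A, fold change = B/A).
#' @export
bloom_contrasts <- function(design) {
  stages <- levels(design$stage)
  genotypes <- levels(design$genotype)
  dev <- if (length(stages) >= 2) {
    purrr::map(genotypes, function(g) {
      pairs <- utils::combn(stages, 2)
      tibble(
        family = "developmental",
        within = g,
        # later stage is the numerator (B)
        group_b = pairs[2, ],
        group_a = pairs[1, ]
      )
    }) |> list_rbind()
  }
  varietal <- if (length(genotypes) >= 2) {
    purrr::map(stages, function(s) {
      pairs <- utils::combn(genotypes, 2)
      tibble(
        family = "varietal",
        within = s,
        group_b = pairs[2, ],
        group_a = pairs[1, ]
      )
    }) |> list_rbind()
  }
  out <- bind_rows(dev, varietal)
  if (nrow(out) == 0) {
    return(tibble(contrast = character(), family = character(),
                  within = character(), group_b = character(),
                  group_a = character()))
  }
  out$contrast <- paste0(out$within, ":", out$group_b, "vs", out$group_a)
  relocate(out, "contrast")
}

# Libraries belonging to one cell or margin of the design.
design_libraries <- function(design, genotype = NULL, stage = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(genotype)) keep <- keep & design$genotype %in% genotype
  if (!is.null(stage)) keep <- keep & design$stage %in% stage
  design$library[keep]
}
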