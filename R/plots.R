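#' @import ggplot2
NULL

#' Plot a known/predicted miRNA group summary
#'
#' Bar chart of unique miRNA counts per evidence group.
#'
#' @param object A `bloom_group_summary` tibble from [summarize_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bloom_group_summary
#' @export
autoplot.bloom_group_summary <- function(object, ...) {
  df <- filter(object, .data$group != "total", .data$category != "Total")
  ggplot(df, aes(x = .data$group, y = .data$n_mirna,
                 fill = .data$category)) +
    geom_col() +
    labs(x = "evidence group", y = "unique miRNAs", fill = NULL,
         title = "Known and predicted miRNAs by evidence group") +
    theme_minimal()
}

#' Volcano / P-value plot for differential-expression results
#'
#' Pairwise results (with a `log2_fc` column) are drawn as a volcano plot
#' coloured by direction; ANOVA results fall back to a P-value histogram.
#'
#' @param object A `bloom_de` tibble.
#' @param alpha Significance line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bloom_de
#' @export
autoplot.bloom_de <- function(object, alpha = 0.05, ...) {
  if ("log2_fc" %in% names(object)) {
    dir <- if ("direction" %in% names(object)) {
      object$direction
    } else {
      ifelse(object$p_value <= alpha,
             ifelse(object$log2_fc > 0, "up", "down"), "none")
    }
    ggplot(mutate(object, direction = dir),
           aes(x = .data$log2_fc, y = -log10(pmax(.data$p_value, 1e-300)),
               colour = .data$direction)) +
      geom_point(alpha = 0.7, size = 1) +
      scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                     none = "grey70")) +
      geom_hline(yintercept = -log10(alpha), linetype = 2,
                 colour = "grey40") +
      labs(x = "log2 fold change", y = "-log10 P", colour = NULL) +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data$p_value)) +
      geom_histogram(breaks = seq(0, 1, by = 0.05), fill = "grey60",
                     colour = "white") +
      labs(x = "ANOVA P value", y = "features") +
      theme_minimal()
  }
}

#' Degradome t-plot for one transcript
#'
#' Per-position degradome 5'-end density with the expected cleavage
#' position(s) of any supplied target sites marked — the standard visual
#' check that a candidate slicing site is the transcript's dominant
#' degradation signal.
#'
#' @param profiles A `bloom_profiles` tibble from [build_profiles()].
#' @param transcript_id Transcript to plot.
#' @param genotype Library label (default: all libraries, faceted).
#' @param sites Optional [predict_targets()] tibble; expected cleavage
#'   positions on this transcript are marked with dashed lines.
#' @return A ggplot object.
#' @export
plot_tplot <- function(profiles, transcript_id, genotype = NULL,
                       sites = NULL) {
  sub <- profiles[profiles$transcript_id == transcript_id, ]
  if (!is.null(genotype)) sub <- sub[sub$genotype %in% genotype, ]
  if (nrow(sub) == 0) abort("No degradome signal for that transcript.")
  p <- ggplot(sub, aes(x = .data$position, xend = .data$position,
                       y = 0, yend = .data$count)) +
    geom_segment(colour = "grey30") +
    labs(x = "transcript position (nt)", y = "degradome 5'-end count",
         title = transcript_id) +
    theme_minimal()
  if (length(unique(sub$genotype)) > 1) {
    p <- p + facet_wrap(~genotype, ncol = 1)
  }
  if (!is.null(sites)) {
    marks <- sites[sites$transcript_id == transcript_id, ]
    if (nrow(marks) > 0) {
      p <- p + geom_vline(xintercept = marks$cleavage_pos,
                          colour = "#b2182b", linetype = 2)
    }
  }
  p
}

#' Plot module counts by evidence class and TF family
#'
#' @param object A TF-annotated `bloom_modules` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bloom_modules
#' @export
autoplot.bloom_modules <- function(object, ...) {
  df <- mutate(object,
               tf_family = ifelse(is.na(.data$tf_family), "(not TF)",
                                  .data$tf_family))
  ggplot(df, aes(x = .data$evidence_class, fill = .data$tf_family)) +
    geom_bar() +
    labs(x = "evidence class", y = "modules", fill = "TF family",
         title = "Antagonistic miRNA-mRNA(-TF) modules") +
    theme_minimal()
}
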