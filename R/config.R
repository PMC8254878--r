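#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults follow the published filtration and network-construction settings
#' for paired tumor-normal exome calling integrated with a weighted
#' co-expression network: Fisher p < 0.05, sequencing depth >= 10 in both
#' tissues, at most 1 variant-supporting read in normal and at least 3 in
#' tumor, normal VAF <= 0.03 and tumor VAF >= 0.05; population frequency
#' < 0.005 (East-Asian panels) for rarity; CADD-phred >= 30 and at least two
#' damaging predictions for missense severity; soft-threshold power 12,
#' dendrogram cut height 0.4 and sub-network edge threshold TOM >= 0.15; GO
#' terms with >= 10 genes at FDR <= 0.05.
#'
#' @param qc_p_max Maximum somatic Fisher p-value accepted by QC (strict `<`).
#' @param qc_depth_min Minimum read depth required in both tissues.
#' @param qc_normal_alt_max Maximum variant-supporting reads in normal tissue.
#' @param qc_tumor_alt_min Minimum variant-supporting reads in tumor tissue.
#' @param qc_normal_vaf_max Maximum variant allele fraction in normal tissue.
#' @param qc_tumor_vaf_min Minimum variant allele fraction in tumor tissue.
#' @param rare_freq_max Population-frequency cutoff for rarity (strict `<`,
#'   applied to every non-missing panel frequency; missing counts as 0).
#' @param cadd_min CADD-phred score at or above which CADD votes "damaging".
#' @param severe_tool_min Number of damaging predictions (CADD, SIFT,
#'   PolyPhen-2) required to call a missense variant severe.
#' @param soft_power Soft-threshold power for the unsigned adjacency.
#' @param tom_edge_min Topological-overlap threshold for sub-network edges.
#' @param cut_height Static cut height on the 1 - TOM dendrogram.
#' @param min_module_size Smallest cluster kept as a module; smaller clusters
#'   are relabelled "grey".
#' @param go_min_genes Smallest GO term tested for enrichment.
#' @param go_fdr_max Benjamini-Hochberg adjusted-p threshold for significance.
#' @param fisher_alternative `"greater"` (one-sided, tumor alt-read
#'   enrichment; the somatic-calling convention) or `"two.sided"`.
#' @param rng_seed Integer seed recorded with pipeline runs.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$rare_freq_max
#' @export
pipeline_config <- function(qc_p_max = 0.05,
                            qc_depth_min = 10L,
                            qc_normal_alt_max = 1L,
                            qc_tumor_alt_min = 3L,
                            qc_normal_vaf_max = 0.03,
                            qc_tumor_vaf_min = 0.05,
                            rare_freq_max = 0.005,
                            cadd_min = 30,
                            severe_tool_min = 2L,
                            soft_power = 12L,
                            tom_edge_min = 0.15,
                            cut_height = 0.4,
                            min_module_size = 30L,
                            go_min_genes = 10L,
                            go_fdr_max = 0.05,
                            fisher_alternative = c("greater", "two.sided"),
                            rng_seed = 1L) {
  fisher_alternative <- match.arg(fisher_alternative)
  cfg <- list(
    qc_p_max = qc_p_max, qc_depth_min = as.integer(qc_depth_min),
    qc_normal_alt_max = as.integer(qc_normal_alt_max),
    qc_tumor_alt_min = as.integer(qc_tumor_alt_min),
    qc_normal_vaf_max = qc_normal_vaf_max,
    qc_tumor_vaf_min = qc_tumor_vaf_min,
    rare_freq_max = rare_freq_max, cadd_min = cadd_min,
    severe_tool_min = as.integer(severe_tool_min),
    soft_power = as.integer(soft_power), tom_edge_min = tom_edge_min,
    cut_height = cut_height, min_module_size = as.integer(min_module_size),
    go_min_genes = as.integer(go_min_genes), go_fdr_max = go_fdr_max,
    fisher_alternative = fisher_alternative, rng_seed = as.integer(rng_seed)
  )
  fracs <- c("qc_p_max", "qc_normal_vaf_max", "qc_tumor_vaf_min",
             "rare_freq_max", "tom_edge_min", "cut_height", "go_fdr_max")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single fraction in [0, 1]", f))
  }
  ints <- c("qc_depth_min", "qc_normal_alt_max", "qc_tumor_alt_min",
            "severe_tool_min", "soft_power", "min_module_size",
            "go_min_genes")
  for (f in ints) {
    v <- cfg[[f]]
    if (is.na(v) || v < 0L)
      stop(sprintf("'%s' must be a non-negative integer", f))
  }
  if (cfg$soft_power < 1L) stop("'soft_power' must be >= 1")
  if (!is.numeric(cfg$cadd_min) || cfg$cadd_min < 0)
    stop("'cadd_min' must be a non-negative score")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  QC: p < %g, depth >= %d, normal alt <= %d, tumor alt >= %d,\n",
              x$qc_p_max, x$qc_depth_min, x$qc_normal_alt_max,
              x$qc_tumor_alt_min))
  cat(sprintf("      normal VAF <= %g, tumor VAF >= %g (Fisher: %s)\n",
              x$qc_normal_vaf_max, x$qc_tumor_vaf_min, x$fisher_alternative))
  cat(sprintf("  Rarity: all panel frequencies < %g\n", x$rare_freq_max))
  cat(sprintf("  Severity: >= %d of {CADD >= %g, SIFT = D, PolyPhen = D}\n",
              x$severe_tool_min, x$cadd_min))
  cat(sprintf("  Network: power %d, cut height %g, min module %d, TOM edge >= %g\n",
              x$soft_power, x$cut_height, x$min_module_size, x$tom_edge_min))
  cat(sprintf("  GO: terms >= %d genes, FDR <= %g\n",
              x$go_min_genes, x$go_fdr_max))
  invisible(x)
}
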