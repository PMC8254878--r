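#' Fisher exact test for somatic support
#'
#' The statistical core of paired tumor-normal calling: for each site the
#' 2x2 table of (reference, variant) read counts in normal and tumor tissue
#' is tested with a Fisher exact test. The default alternative is one-sided
#' towards variant-read enrichment in the tumor, the convention of paired
#' somatic callers; a two-sided option sums all tables whose conditional
#' hypergeometric probability does not exceed the observed one.
#'
#' Vectorised over sites. Sites with zero total reads in either tissue are
#' undefined and return `NA` (flagged, not computed).
#'
#' @param normal_ref,normal_alt Reference / variant read counts in normal.
#' @param tumor_ref,tumor_alt Reference / variant read counts in tumor.
#' @param alternative `"greater"` (tumor enrichment) or `"two.sided"`.
#' @return Numeric vector of p-values in (0, 1], `NA` where undefined.
#' @examples
#' fisher_somatic_test(40, 0, 25, 15)
#' fisher_somatic_test(10, 0, 10, 0)   # identical rows: p = 1
#' @export
fisher_somatic_test <- function(normal_ref, normal_alt, tumor_ref, tumor_alt,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(normal_ref)
  stopifnot(length(normal_alt) == n, length(tumor_ref) == n,
            length(tumor_alt) == n)
  counts <- cbind(normal_ref, normal_alt, tumor_ref, tumor_alt)
  if (any(counts < 0, na.rm = TRUE)) stop("read counts must be >= 0")
  nd <- normal_ref + normal_alt
  td <- tumor_ref + tumor_alt
  ok <- !is.na(nd) & !is.na(td) & nd > 0 & td > 0
  p <- rep(NA_real_, n)
  if (alternative == "greater") {
    # P(X >= tumor_alt), X ~ Hypergeom drawing the tumor depth from the
    # pooled reads with (normal_alt + tumor_alt) "successes"
    m <- normal_alt + tumor_alt
    p[ok] <- phyper(tumor_alt[ok] - 1L, m[ok], (nd + td - m)[ok], td[ok],
                    lower.tail = FALSE)
  } else {
    for (i in which(ok)) {
      tab <- matrix(c(normal_ref[i], normal_alt[i],
                      tumor_ref[i], tumor_alt[i]), 2L, byrow = TRUE)
      p[i] <- stats::fisher.test(tab)$p.value
    }
  }
  pmin(p, 1)
}

#' Compute somatic calls from variant candidates
#'
#' Adds the Fisher p-value, per-tissue variant allele fractions and the QC
#' verdict to a candidate table.
#'
#' @param candidates Data frame of variant candidates with columns
#'   `patient_id, chrom, pos, ref, alt, normal_ref, normal_alt, tumor_ref,
#'   tumor_alt` (as produced by [read_variant_table()] or
#'   [simulate_variants()]).
#' @param cfg A [pipeline_config()].
#' @return The input with columns `fisher_p`, `normal_vaf`, `tumor_vaf`,
#'   `qc_pass` appended.
#' @export
somatic_calls <- function(candidates, cfg = pipeline_config()) {
  stopifnot(is.data.frame(candidates))
  req <- c("patient_id", "chrom", "pos", "ref", "alt",
           "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")
  miss <- setdiff(req, names(candidates))
  if (length(miss))
    stop("candidate table is missing columns: ", paste(miss, collapse = ", "))
  if (any(candidates$ref == candidates$alt))
    stop("ref and alt alleles must differ")
  out <- candidates
  nd <- out$normal_ref + out$normal_alt
  td <- out$tumor_ref + out$tumor_alt
  out$fisher_p <- fisher_somatic_test(out$normal_ref, out$normal_alt,
                                      out$tumor_ref, out$tumor_alt,
                                      alternative = cfg$fisher_alternative)
  out$normal_vaf <- ifelse(nd > 0, out$normal_alt / nd, NA_real_)
  out$tumor_vaf <- ifelse(td > 0, out$tumor_alt / td, NA_real_)
  out$qc_pass <- apply_qc(out, cfg)
  out
}

#' Quality-control filter for somatic calls
#'
#' A call passes QC iff all of: Fisher p strictly below `qc_p_max`; depth at
#' least `qc_depth_min` in both tissues; normal variant reads at most
#' `qc_normal_alt_max`; tumor variant reads at least `qc_tumor_alt_min`;
#' normal VAF at most `qc_normal_vaf_max`; tumor VAF at least
#' `qc_tumor_vaf_min`. Boundary comparators are exactly as stated.
#'
#' @param calls Data frame with read-count columns and `fisher_p` (as from
#'   [somatic_calls()]; VAFs are recomputed from counts).
#' @param cfg A [pipeline_config()].
#' @return Logical vector, `FALSE` where the Fisher p is undefined.
#' @export
apply_qc <- function(calls, cfg = pipeline_config()) {
  nd <- calls$normal_ref + calls$normal_alt
  td <- calls$tumor_ref + calls$tumor_alt
  nvaf <- ifelse(nd > 0, calls$normal_alt / nd, NA_real_)
  tvaf <- ifelse(td > 0, calls$tumor_alt / td, NA_real_)
  pass <- !is.na(calls$fisher_p) &
    calls$fisher_p < cfg$qc_p_max &
    nd >= cfg$qc_depth_min & td >= cfg$qc_depth_min &
    calls$normal_alt <= cfg$qc_normal_alt_max &
    calls$tumor_alt >= cfg$qc_tumor_alt_min &
    !is.na(nvaf) & nvaf <= cfg$qc_normal_vaf_max &
    !is.na(tvaf) & tvaf >= cfg$qc_tumor_vaf_min
  pass & !is.na(pass)
}

#' Population-rarity flag
#'
#' A variant is rare iff every non-missing of its four population
#' frequencies (1000 Genomes EAS, ExAC EAS, GnomAD genome EAS, GnomAD exome
#' EAS) is strictly below `rare_freq_max`. A missing frequency means the
#' allele was never observed in that panel and counts as 0 — absence is the
#' strongest rarity evidence.
#'
#' @param annotated Data frame with columns `freq_1kg_eas`, `freq_exac_eas`,
#'   `freq_gnomad_genome_eas`, `freq_gnomad_exome_eas` (NA = not observed).
#' @param cfg A [pipeline_config()].
#' @return Logical vector.
#' @export
flag_rare <- function(annotated, cfg = pipeline_config()) {
  cols <- c("freq_1kg_eas", "freq_exac_eas",
            "freq_gnomad_genome_eas", "freq_gnomad_exome_eas")
  miss <- setdiff(cols, names(annotated))
  if (length(miss))
    stop("missing population-frequency columns: ", paste(miss, collapse = ", "))
  fr <- as.matrix(annotated[, cols, drop = FALSE])
  if (any(fr < 0 | fr > 1, na.rm = TRUE))
    stop("population frequencies must lie in [0, 1]")
  fr[is.na(fr)] <- 0
  apply(fr < cfg$rare_freq_max, 1L, all)
}

.severe_consequences <- c("frameshift", "stopgain", "stoploss",
                          "startloss", "splice")

#' Predicted-severity flag
#'
#' Frameshift, stop-gain/-loss, start-loss and splice-site variants are
#' severe by consequence class alone. Missense variants are severe iff at
#' least `severe_tool_min` of the three predictors vote damaging:
#' CADD-phred >= `cadd_min`, SIFT call "D", PolyPhen-2 call "D". A missing
#' prediction never votes damaging. Synonymous variants must have been
#' discarded upstream and raise an error.
#'
#' @param annotated Data frame with columns `consequence`, `cadd_phred`,
#'   `sift_damaging`, `polyphen_damaging` (the latter two logical, NA
#'   allowed).
#' @param cfg A [pipeline_config()].
#' @return Logical vector.
#' @export
flag_severe <- function(annotated, cfg = pipeline_config()) {
  csq <- as.character(annotated$consequence)
  if (any(csq == "synonymous"))
    stop("synonymous variants must be discarded before severity filtering")
  by_class <- csq %in% .severe_consequences
  cadd <- annotated$cadd_phred
  votes <- (!is.na(cadd) & cadd >= cfg$cadd_min) +
    (!is.na(annotated$sift_damaging) & annotated$sift_damaging) +
    (!is.na(annotated$polyphen_damaging) & annotated$polyphen_damaging)
  by_class | (csq == "missense" & votes >= cfg$severe_tool_min)
}

.variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Annotate somatic calls with gene, consequence and predictor columns
#'
#' Joins a per-site annotation table (keyed by chrom/pos/ref/alt) onto the
#' call table and computes the rare / severe / final flags. Synonymous
#' variants are dropped (with a count kept by [run_cascade()]).
#'
#' @param calls Output of [somatic_calls()].
#' @param annotation Data frame keyed by `chrom, pos, ref, alt` with columns
#'   `gene`, `consequence`, the four `freq_*` columns, `cadd_phred`,
#'   `sift_damaging`, `polyphen_damaging`.
#' @return `calls` with annotation columns appended.
#' @export
annotate_calls <- function(calls, annotation) {
  key_c <- .variant_key(calls)
  key_a <- .variant_key(annotation)
  if (anyDuplicated(key_a))
    stop("annotation table has duplicated variant keys")
  idx <- match(key_c, key_a)
  if (anyNA(idx))
    stop(sum(is.na(idx)), " calls have no annotation record")
  keep <- setdiff(names(annotation), c("chrom", "pos", "ref", "alt"))
  cbind(calls, annotation[idx, keep, drop = FALSE], row.names = NULL)
}

#' Run the four-stage filtration cascade
#'
#' Applies the full filtration scheme: synonymous variants are discarded,
#' quality control (QC) is applied, QC-passing variants are filtered by
#' population rarity (P) and predicted severity (S), and the final set is
#' their intersection (F = P & S). Stage counts of mutations and of
#' distinct genes are tabulated overall and per patient.
#'
#' @param candidates Candidate table (see [somatic_calls()]).
#' @param annotation Per-site annotation table (see [annotate_calls()]).
#' @param cfg A [pipeline_config()].
#' @return An object of class `"somatic_cascade"`: a list with `variants`
#'   (annotated calls with logical columns `qc_pass`, `is_rare`, `is_severe`,
#'   `is_final`), `counts` (per-stage mutation and gene counts),
#'   `per_patient` (stage counts by patient), `n_synonymous_dropped`, `cfg`.
#' @examples
#' plan <- simulation_plan(seed = 7)
#' sim <- simulate_variants(plan)
#' casc <- run_cascade(sim$candidates, sim$annotation)
#' casc
#' @export
run_cascade <- function(candidates, annotation, cfg = pipeline_config()) {
  calls <- somatic_calls(candidates, cfg)
  ann <- annotate_calls(calls, annotation)
  syn <- ann$consequence == "synonymous"
  n_syn <- sum(syn)
  v <- ann[!syn, , drop = FALSE]
  if (nrow(v)) {
    v$is_rare <- flag_rare(v, cfg) & v$qc_pass
    v$is_severe <- flag_severe(v, cfg) & v$qc_pass
  } else {
    v$is_rare <- logical(0)
    v$is_severe <- logical(0)
  }
  v$is_final <- v$is_rare & v$is_severe
  stage_counts <- function(flag) {
    c(mutations = sum(flag), genes = length(unique(v$gene[flag])))
  }
  counts <- rbind(QC = stage_counts(v$qc_pass),
                  P = stage_counts(v$is_rare),
                  S = stage_counts(v$is_severe),
                  F = stage_counts(v$is_final))
  pts <- sort(unique(as.character(candidates$patient_id)))
  per_patient <- do.call(rbind, lapply(pts, function(p) {
    sel <- v$patient_id == p
    data.frame(patient_id = p,
               qc = sum(v$qc_pass & sel),
               rare = sum(v$is_rare & sel),
               severe = sum(v$is_severe & sel),
               final = sum(v$is_final & sel))
  }))
  structure(list(variants = v, counts = counts, per_patient = per_patient,
                 n_synonymous_dropped = n_syn, cfg = cfg),
            class = "somatic_cascade")
}

#' @export
print.somatic_cascade <- function(x, ...) {
  cat("Somatic filtration cascade\n")
  cat(sprintf("  %d candidates (%d synonymous discarded)\n",
              nrow(x$variants) + x$n_synonymous_dropped,
              x$n_synonymous_dropped))
  m <- x$counts
  cat(sprintf("  QC-pass: %d mutations / %d genes\n", m["QC", 1], m["QC", 2]))
  cat(sprintf("  rare (P): %d / %d   severe (S): %d / %d\n",
              m["P", 1], m["P", 2], m["S", 1], m["S", 2]))
  cat(sprintf("  final (F = P & S): %d mutations on %d genes\n",
              m["F", 1], m["F", 2]))
  invisible(x)
}

#' @export
summary.somatic_cascade <- function(object, ...) {
  print(object)
  cat("\nPer patient:\n")
  print(object$per_patient, row.names = FALSE)
  invisible(object)
}

#' Final-mutation subset of a cascade
#' @param cascade A `"somatic_cascade"`.
#' @return Data frame of final (rare and severe, QC-passing) mutations.
#' @export
final_mutations <- function(cascade) {
  stopifnot(inherits(cascade, "somatic_cascade"))
  cascade$variants[cascade$variants$is_final, , drop = FALSE]
}

#' Cross-patient recurrence of final mutations
#'
#' For each gene carrying a final mutation, lists the set of patients hit
#' and the mutation count; genes are ordered by decreasing recurrence, ties
#' broken alphabetically.
#'
#' @param finals Data frame of final mutations (from [final_mutations()]).
#' @return Data frame with columns `gene`, `n_patients`, `patients`
#'   (comma-separated, sorted), `n_mutations`.
#' @export
recurrence_summary <- function(finals) {
  if (!nrow(finals))
    return(data.frame(gene = character(0), n_patients = integer(0),
                      patients = character(0), n_mutations = integer(0)))
  sp <- split(as.character(finals$patient_id), as.character(finals$gene))
  out <- data.frame(
    gene = names(sp),
    n_patients = vapply(sp, function(p) length(unique(p)), integer(1)),
    patients = vapply(sp, function(p) paste(sort(unique(p)), collapse = ","),
                      character(1)),
    n_mutations = vapply(sp, length, integer(1)),
    row.names = NULL
  )
  out[order(-out$n_patients, out$gene), , drop = FALSE]
}
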