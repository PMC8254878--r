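#' Map final mutations to co-expression modules
#'
#' Annotates each final mutation with its gene's module label (`"absent"`
#' when the gene is not in the expression data) and tabulates per-module
#' mutation counts by patient.
#'
#' @param finals Data frame of final mutations (see [final_mutations()]).
#' @param module_of Named gene -> module vector (from a fitted network, or
#'   planted labels).
#' @return List with `mutations` (finals plus a `module` column) and
#'   `counts` (patient x module table).
#' @export
map_mutations_to_modules <- function(finals, module_of) {
  mod <- unname(module_of[finals$gene])
  mod[is.na(mod)] <- "absent"
  out <- finals
  out$module <- mod
  counts <- if (nrow(out))
    table(patient = out$patient_id, module = out$module)
  else table(patient = character(0), module = character(0))
  list(mutations = out, counts = counts)
}

#' Build the mutation-anchored sub-network
#'
#' Nodes are the final-mutation genes present in the expression data plus
#' every anchor-module gene whose topological overlap with at least one
#' mutated gene reaches the edge threshold. Edges connect every node pair
#' at TOM >= threshold (neighbour-neighbour edges included, which is what
#' produces large connected components around non-mutated hubs). Mutated
#' genes outside the anchor module enter as nodes but recruit no
#' neighbours of their own.
#'
#' @param net A `"coexpression_network"` (needs `tom`, `module_of`, `kme`).
#' @param mutated_genes Genes carrying final mutations.
#' @param anchor Anchor module label; defaults to [anchor_module()] (the
#'   module with maximal |module-trait r|).
#' @param cfg A [pipeline_config()]; supplies `tom_edge_min`.
#' @return Object of class `"subnetwork"`: `nodes` (gene, is_mutated, kme
#'   in the anchor module, degree, component), `edges` (gene_a, gene_b,
#'   tom), `anchor`, `threshold`.
#' @export
build_subnetwork <- function(net, mutated_genes, anchor = NULL,
                             cfg = pipeline_config()) {
  stopifnot(inherits(net, "coexpression_network"))
  tom <- net$tom
  anchor <- anchor %||% anchor_module(net)
  thr <- cfg$tom_edge_min
  mut <- intersect(unique(mutated_genes), rownames(tom))
  empty_nodes <- data.frame(gene = character(0), is_mutated = logical(0),
                            kme = numeric(0), degree = integer(0),
                            component = integer(0))
  empty_edges <- data.frame(gene_a = character(0), gene_b = character(0),
                            tom = numeric(0))
  if (!length(mut)) {
    warning("no mutated gene present in the expression data")
    return(structure(list(nodes = empty_nodes, edges = empty_edges,
                          anchor = anchor, threshold = thr),
                     class = "subnetwork"))
  }
  anchor_genes <- names(net$module_of)[net$module_of == anchor]
  # recruit anchor-module genes linked to >= 1 mutated gene at threshold
  link <- tom[anchor_genes, mut, drop = FALSE]
  recruited <- anchor_genes[apply(link >= thr, 1L, any)]
  nodes <- union(mut, recruited)
  sub <- tom[nodes, nodes, drop = FALSE]
  ut <- upper.tri(sub)
  hit <- which(ut & sub >= thr, arr.ind = TRUE)
  edges <- if (nrow(hit))
    data.frame(gene_a = nodes[hit[, 1L]], gene_b = nodes[hit[, 2L]],
               tom = sub[hit])
  else empty_edges
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  kme <- if (!is.null(net$kme) && anchor %in% colnames(net$kme))
    net$kme[nodes, anchor] else rep(NA_real_, length(nodes))
  node_df <- data.frame(gene = nodes, is_mutated = nodes %in% mut,
                        kme = unname(kme),
                        degree = as.integer(deg[nodes]),
                        component = as.integer(comp$membership[nodes]),
                        row.names = NULL)
  structure(list(nodes = node_df, edges = edges, anchor = anchor,
                 threshold = thr),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("Sub-network (anchor '%s', TOM >= %g): %d nodes (%d mutated), %d edges, %d components\n",
              x$anchor, x$threshold, nrow(x$nodes), sum(x$nodes$is_mutated),
              nrow(x$edges),
              if (nrow(x$nodes)) max(x$nodes$component) else 0L))
  invisible(x)
}

#' VAF-based two-hit ordering test
#'
#' Tests the temporal reading of the two-hit model: the candidate first hit
#' is the final-mutation gene shared by the most patients (ties broken by
#' higher mean tumor VAF). For each patient, `ordering_holds` is true iff
#' the first-hit variant's tumor VAF strictly exceeds the tumor VAF of
#' every other final mutation in the anchor module (a higher fraction of
#' variant-supporting reads marks the more clonal, hence earlier, event).
#' The cohort is "two-hit consistent" iff every evaluated patient carries
#' at least two anchor-module final mutations and the ordering holds for
#' all of them; patients lacking the first-hit variant are flagged and
#' excluded from the verdict.
#'
#' @param finals Final mutations with a `module` column (from
#'   [map_mutations_to_modules()]) and `tumor_vaf`.
#' @param anchor Anchor module label.
#' @return Object of class `"two_hit_report"`: `first_hit_gene`,
#'   `patients` (per patient: first-hit VAF, number of anchor-module
#'   finals, max secondary VAF, ordering_holds, has_first_hit),
#'   `secondary` (the anchor-module secondary mutations), `cohort`
#'   (verdict and counts).
#' @export
vaf_ordering_test <- function(finals, anchor) {
  stopifnot(all(c("module", "tumor_vaf", "gene", "patient_id") %in%
                  names(finals)))
  if (!nrow(finals)) stop("no final mutations to order")
  rec <- recurrence_summary(finals)
  mean_vaf <- tapply(finals$tumor_vaf, finals$gene, mean)
  rec$mean_vaf <- as.numeric(mean_vaf[rec$gene])
  rec <- rec[order(-rec$n_patients, -rec$mean_vaf, rec$gene), ]
  fh_gene <- rec$gene[1L]
  pts <- sort(unique(as.character(finals$patient_id)))
  per <- lapply(pts, function(pt) {
    mine <- finals[finals$patient_id == pt, , drop = FALSE]
    fh <- mine[mine$gene == fh_gene, , drop = FALSE]
    has_fh <- nrow(fh) > 0L
    fh_vaf <- if (has_fh) max(fh$tumor_vaf) else NA_real_
    sec <- mine[mine$module == anchor & mine$gene != fh_gene, ,
                drop = FALSE]
    n_anchor <- sum(mine$module == anchor)
    max_sec <- if (nrow(sec)) max(sec$tumor_vaf) else NA_real_
    ordering <- !has_fh || !nrow(sec) || fh_vaf > max_sec
    data.frame(patient_id = pt, has_first_hit = has_fh,
               first_hit_vaf = fh_vaf, n_anchor_finals = n_anchor,
               n_secondary = nrow(sec), max_secondary_vaf = max_sec,
               ordering_holds = ordering)
  })
  patients <- do.call(rbind, per)
  secondary <- finals[finals$module == anchor & finals$gene != fh_gene,
                      c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                        "tumor_vaf", "module"), drop = FALSE]
  rownames(secondary) <- NULL
  eval_pts <- patients[patients$has_first_hit, , drop = FALSE]
  consistent <- nrow(eval_pts) > 0L &&
    all(eval_pts$n_anchor_finals >= 2L) && all(eval_pts$ordering_holds)
  structure(list(
    first_hit_gene = fh_gene, anchor_module = anchor, patients = patients,
    secondary = secondary,
    cohort = list(verdict = if (consistent) "two-hit consistent"
                  else "not consistent",
                  two_hit_consistent = consistent,
                  n_patients = length(pts),
                  n_evaluated = nrow(eval_pts),
                  n_flagged_no_first_hit = sum(!patients$has_first_hit))),
    class = "two_hit_report")
}

#' @export
print.two_hit_report <- function(x, ...) {
  cat(sprintf("Two-hit ordering report (anchor module '%s')\n",
              x$anchor_module))
  cat(sprintf("  candidate first hit: %s (carried by %d/%d patients)\n",
              x$first_hit_gene, x$cohort$n_evaluated, x$cohort$n_patients))
  p <- x$patients
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s: first-hit VAF %s, %d anchor-module finals, max secondary VAF %s, ordering %s\n",
                p$patient_id[i],
                ifelse(is.na(p$first_hit_vaf[i]), "-",
                       sprintf("%.3f", p$first_hit_vaf[i])),
                p$n_anchor_finals[i],
                ifelse(is.na(p$max_secondary_vaf[i]), "-",
                       sprintf("%.3f", p$max_secondary_vaf[i])),
                ifelse(p$ordering_holds[i], "holds", "violated")))
  cat(sprintf("  cohort verdict: %s\n", x$cohort$verdict))
  invisible(x)
}
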