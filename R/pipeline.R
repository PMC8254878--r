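#' Run the full pipeline on synthetic inputs
#'
#' End-to-end driver: simulates all inputs under a plan, writes them in the
#' package's external formats, runs the filtration cascade, fits the
#' co-expression network, tests GO over-representation of the anchor
#' module, builds the mutation-anchored sub-network and the two-hit
#' ordering report, and writes every declared output file.
#'
#' Files written to `out_dir`: inputs (`variants.tsv`, `annotation.tsv`,
#' `expression.tsv`, `traits.tsv`, `go_terms.gmt`, `go_parents.tsv`,
#' `truth.tsv`), cascade stages (`qc.tsv`, `rare.tsv`, `severe.tsv`,
#' `final.tsv`, `recurrence.tsv`), network (`modules.tsv`,
#' `eigengenes.tsv`, `kme.tsv`, `module_trait.tsv`), `enrichment.tsv`,
#' sub-network (`subnetwork.sif`, `subnetwork_edges.tsv`,
#' `subnetwork_nodes.tsv`) and `two_hit_report.json`.
#'
#' @param plan A [simulation_plan()] (its seed drives all randomness).
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `cascade`, `network`, `enrichment`,
#'   `mapping`, `subnetwork`, `two_hit`, `sim`, `files`.
#' @examples
#' \donttest{
#' res <- run_pipeline(simulation_plan(seed = 1), out_dir = tempfile())
#' res$two_hit$cohort$verdict
#' }
#' @export
run_pipeline <- function(plan = simulation_plan(),
                         cfg = pipeline_config(),
                         out_dir = "pipeline_out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  tsv <- function(x, f) {
    write.table(x, path(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }

  sim_v <- simulate_variants(plan, cfg)
  sim_e <- simulate_expression(plan)
  sim_g <- simulate_go(plan, sim_e$module_labels,
                       min_term_genes = cfg$go_min_genes)

  files <- character(0)
  files <- c(files, write_variant_table(sim_v$candidates,
                                        path("variants.tsv")))
  files <- c(files, tsv(sim_v$annotation, "annotation.tsv"),
             tsv(sim_v$truth, "truth.tsv"))
  write_expression_matrix(sim_e$expr, path("expression.tsv"),
                          path("traits.tsv"))
  write_gmt(sim_g$structure$term_to_genes, path("go_terms.gmt"))
  write_go_parents(sim_g$structure$parent_of, path("go_parents.tsv"))

  cascade <- run_cascade(sim_v$candidates, sim_v$annotation, cfg)
  v <- cascade$variants
  tsv(v[v$qc_pass, ], "qc.tsv")
  tsv(v[v$is_rare, ], "rare.tsv")
  tsv(v[v$is_severe, ], "severe.tsv")
  finals <- final_mutations(cascade)
  tsv(finals, "final.tsv")
  tsv(recurrence_summary(finals), "recurrence.tsv")

  net <- fit_coexpression_network(sim_e$expr, cfg = cfg)
  tsv(data.frame(gene = names(net$module_of), module = net$module_of),
      "modules.tsv")
  tsv(data.frame(sample = rownames(net$me), net$me, check.names = FALSE),
      "eigengenes.tsv")
  tsv(data.frame(gene = rownames(net$kme), net$kme, check.names = FALSE),
      "kme.tsv")
  tsv(net$module_trait, "module_trait.tsv")

  anchor <- anchor_module(net)
  anchor_genes <- names(net$module_of)[net$module_of == anchor]
  enr <- hypergeom_enrich(anchor_genes, sim_g$structure, cfg)
  tsv(as.data.frame(enr), "enrichment.tsv")

  mapping <- map_mutations_to_modules(finals, net$module_of)
  subnet <- build_subnetwork(net, unique(finals$gene), anchor, cfg)
  write_edge_list(subnet, path("subnetwork.sif"), "sif")
  write_edge_list(subnet, path("subnetwork_edges.tsv"), "tsv")
  tsv(subnet$nodes, "subnetwork_nodes.tsv")

  two_hit <- vaf_ordering_test(mapping$mutations, anchor)
  write_two_hit_report(two_hit, path("two_hit_report.json"))

  declared <- c("variants.tsv", "annotation.tsv", "truth.tsv",
                "expression.tsv", "traits.tsv", "go_terms.gmt",
                "go_parents.tsv", "qc.tsv", "rare.tsv", "severe.tsv",
                "final.tsv", "recurrence.tsv", "modules.tsv",
                "eigengenes.tsv", "kme.tsv", "module_trait.tsv",
                "enrichment.tsv", "subnetwork.sif", "subnetwork_edges.tsv",
                "subnetwork_nodes.tsv", "two_hit_report.json")
  invisible(list(cascade = cascade, network = net, enrichment = enr,
                 mapping = mapping, subnetwork = subnet, two_hit = two_hit,
                 sim = list(variants = sim_v, expression = sim_e,
                            go = sim_g),
                 files = file.path(out_dir, declared)))
}
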