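# A tiny fitted network built from an explicit TOM, for controlled cases.
toy_net <- function(tom, module_of) {
  structure(list(tom = tom, module_of = module_of,
                 kme = NULL, module_trait = NULL),
            class = "coexpression_network")
}

toy_tom <- function() {
  genes <- c("hub", "m1", "m2", "mut_in", "mut_out", "far")
  tom <- matrix(0.01, 6, 6, dimnames = list(genes, genes))
  tom["hub", "m1"] <- tom["m1", "hub"] <- 0.5
  tom["hub", "m2"] <- tom["m2", "hub"] <- 0.4
  tom["hub", "mut_in"] <- tom["mut_in", "hub"] <- 0.3
  tom["m1", "m2"] <- tom["m2", "m1"] <- 0.2
  diag(tom) <- 1
  tom
}

test_that("mutations map to modules, grey and absent genes included", {
  finals <- data.frame(patient_id = c("P1", "P1", "P2"),
                       gene = c("hub", "lonely", "ghost"),
                       tumor_vaf = c(0.4, 0.1, 0.2))
  module_of <- c(hub = "turquoise", lonely = "grey")
  mp <- map_mutations_to_modules(finals, module_of)
  expect_equal(mp$mutations$module, c("turquoise", "grey", "absent"))
  expect_equal(unname(mp$counts["P1", "turquoise"]), 1L)
  # the absent gene is retained in the report
  expect_true("ghost" %in% mp$mutations$gene)
})

test_that("sub-network recruits anchor-module genes through mutated genes only", {
  tom <- toy_tom()
  module_of <- c(hub = "mod", m1 = "mod", m2 = "mod", mut_in = "mod",
                 mut_out = "other", far = "mod")
  net <- toy_net(tom, module_of)
  cfg <- pipeline_config(tom_edge_min = 0.15)
  sub <- build_subnetwork(net, c("mut_in", "mut_out"), anchor = "mod",
                          cfg = cfg)
  # mut_in links hub (0.3 >= 0.15); hub recruits; m1/m2 only touch hub, not
  # a mutated gene, so they are not recruited; "far" has no link at all;
  # mut_out is outside the anchor module and recruits nothing
  expect_setequal(sub$nodes$gene, c("mut_in", "mut_out", "hub"))
  # neighbour-neighbour edges among included nodes only
  expect_equal(nrow(sub$edges), 1L)
  expect_setequal(c(sub$edges$gene_a, sub$edges$gene_b), c("mut_in", "hub"))
  # mutated gene with no neighbour at threshold: isolated, degree zero
  expect_equal(sub$nodes$degree[sub$nodes$gene == "mut_out"], 0L)
  # degree conservation
  expect_equal(sum(sub$nodes$degree), 2L * nrow(sub$edges))
  # every non-mutated node touches a mutated one
  non_mut <- sub$nodes$gene[!sub$nodes$is_mutated]
  for (g in non_mut)
    expect_true(any(tom[g, c("mut_in", "mut_out")] >= cfg$tom_edge_min))
})

test_that("threshold at the ceiling leaves only mutated genes with no edges", {
  net <- toy_net(toy_tom(), c(hub = "mod", m1 = "mod", m2 = "mod",
                              mut_in = "mod", mut_out = "other",
                              far = "mod"))
  sub <- build_subnetwork(net, c("mut_in", "mut_out"), anchor = "mod",
                          cfg = pipeline_config(tom_edge_min = 1))
  expect_setequal(sub$nodes$gene, c("mut_in", "mut_out"))
  expect_equal(nrow(sub$edges), 0L)
})

test_that("sub-network agrees with a brute-force scan and shrinks monotonically", {
  plan <- simulation_plan(seed = 43)
  se <- simulate_expression(plan)
  net <- fit_coexpression_network(se$expr)
  anchor <- anchor_module(net)
  mut <- c("G0001", "G0010", "G0290")
  cfg <- pipeline_config()
  sub <- build_subnetwork(net, mut, anchor, cfg)
  # independent scan over (mutated gene, anchor gene) pairs
  anchor_genes <- names(net$module_of)[net$module_of == anchor]
  mut_in <- intersect(mut, rownames(net$tom))
  recruited <- Filter(function(g)
    any(net$tom[g, mut_in] >= cfg$tom_edge_min), anchor_genes)
  expect_setequal(sub$nodes$gene, union(mut_in, recruited))
  # edge count by exhaustive pairwise threshold scan
  nodes <- sub$nodes$gene
  n_edges <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j && net$tom[nodes[i], nodes[j]] >= cfg$tom_edge_min)
      n_edges <- n_edges + 1L
  }
  expect_equal(nrow(sub$edges), n_edges)
  # the planted hub sits in the dominant component
  comp_sizes <- table(sub$nodes$component)
  hub_comp <- sub$nodes$component[sub$nodes$gene == "G0001"]
  expect_true(all(comp_sizes[as.character(hub_comp)] >=
                    max(comp_sizes[setdiff(names(comp_sizes),
                                           as.character(hub_comp))], 0)))
  # removing a mutated gene never adds nodes or edges
  sub2 <- build_subnetwork(net, mut[-2], anchor, cfg)
  expect_true(all(sub2$nodes$gene %in% sub$nodes$gene))
  expect_lte(nrow(sub2$edges), nrow(sub$edges))
})

test_that("no mutated gene in the expression data yields an empty network", {
  net <- toy_net(toy_tom(), c(hub = "mod"))
  expect_warning(sub <- build_subnetwork(net, "ghost", anchor = "mod"),
                 "no mutated gene")
  expect_equal(nrow(sub$nodes), 0L)
  expect_equal(nrow(sub$edges), 0L)
})

test_that("VAF ordering identifies the shared first hit and applies strict ties", {
  finals <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P3"),
    gene = c("FH", "sec1", "FH", "sec2", "FH"),
    chrom = "chr1", pos = c(1L, 2L, 1L, 3L, 1L), ref = "A", alt = "T",
    tumor_vaf = c(0.40, 0.20, 0.35, 0.30, 0.33),
    module = c("mod", "mod", "mod", "mod", "mod"))
  rep <- vaf_ordering_test(finals, "mod")
  expect_equal(rep$first_hit_gene, "FH")
  expect_true(all(rep$patients$ordering_holds))
  # P3 has a single anchor mutation: ordering vacuously holds but the
  # two-hit criterion (>= 2 per patient) fails
  expect_equal(rep$patients$n_anchor_finals[rep$patients$patient_id == "P3"],
               1L)
  expect_false(rep$cohort$two_hit_consistent)

  # a VAF tie breaks the strict ordering
  tie <- finals[finals$patient_id != "P3", ]
  tie$tumor_vaf[tie$gene == "sec2"] <- 0.35
  rep2 <- vaf_ordering_test(tie, "mod")
  expect_false(rep2$patients$ordering_holds[rep2$patients$patient_id == "P2"])
  expect_false(rep2$cohort$two_hit_consistent)

  # a patient lacking the first hit is flagged and excluded
  no_fh <- rbind(finals,
                 data.frame(patient_id = "P4", gene = "sec3", chrom = "chr1",
                            pos = 9L, ref = "A", alt = "T", tumor_vaf = 0.1,
                            module = "mod"))
  rep3 <- vaf_ordering_test(no_fh, "mod")
  expect_false(rep3$patients$has_first_hit[rep3$patients$patient_id == "P4"])
  expect_equal(rep3$cohort$n_flagged_no_first_hit, 1L)
  expect_equal(rep3$cohort$n_evaluated, 3L)
})

test_that("the two-hit verdict is invariant to row order", {
  plan <- simulation_plan(seed = 47)
  sim <- simulate_variants(plan)
  casc <- run_cascade(sim$candidates, sim$annotation)
  lay <- plan_gene_layout(plan)
  mp <- map_mutations_to_modules(final_mutations(casc), lay$module_labels)
  rep1 <- vaf_ordering_test(mp$mutations, "M1")
  set.seed(1)
  perm <- sample(nrow(mp$mutations))
  rep2 <- vaf_ordering_test(mp$mutations[perm, ], "M1")
  expect_identical(rep1$first_hit_gene, rep2$first_hit_gene)
  expect_identical(rep1$cohort, rep2$cohort)
  expect_identical(rep1$patients, rep2$patients)
})

test_that("ties in recurrence fall to the gene with higher mean VAF", {
  finals <- data.frame(
    patient_id = c("P1", "P2", "P1", "P2"),
    gene = c("low", "low", "high", "high"),
    chrom = "chr1", pos = c(1L, 1L, 2L, 2L), ref = "A", alt = "T",
    tumor_vaf = c(0.2, 0.2, 0.4, 0.4),
    module = "mod")
  expect_equal(vaf_ordering_test(finals, "mod")$first_hit_gene, "high")
})
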