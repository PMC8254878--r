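test_that("fisher test matches the enumeration oracle and handles edge tables", {
  # identical rows carry no evidence
  expect_equal(fisher_somatic_test(10, 0, 10, 0), 1)
  # depletion direction under the tumor-enrichment alternative
  expect_equal(fisher_somatic_test(0, 10, 10, 0), 1)
  # frozen oracle value for (20,0 | 10,10): margins 20/20, 10 alt reads in
  # total, tail is the single table j = 10: C(20,10) / C(40,10)
  expect_equal(fisher_somatic_test(20, 0, 10, 10),
               oracle_fisher_greater(20, 0, 10, 10), tolerance = 1e-12)
  expect_equal(oracle_fisher_greater(20, 0, 10, 10),
               choose(20, 10) / choose(40, 10))
  # random tables against the oracle and against fisher.test
  set.seed(1)
  for (i in 1:25) {
    nr <- sample(0:30, 1); na <- sample(0:10, 1)
    tr <- sample(0:30, 1); ta <- sample(0:10, 1)
    if (nr + na == 0 || tr + ta == 0) next
    p <- fisher_somatic_test(nr, na, tr, ta)
    expect_equal(p, oracle_fisher_greater(nr, na, tr, ta), tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(c(nr, na, tr, ta), 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-8)
  }
})

test_that("two-sided fisher option matches fisher.test", {
  p <- fisher_somatic_test(18, 2, 9, 11, alternative = "two.sided")
  ft <- stats::fisher.test(matrix(c(18, 2, 9, 11), 2, byrow = TRUE))
  expect_equal(p, ft$p.value, tolerance = 1e-10)
})

test_that("zero depth in either tissue is flagged, not computed", {
  expect_true(is.na(fisher_somatic_test(0, 0, 10, 5)))
  calls <- somatic_calls(make_candidates(
    list("E1", "chr1", 1, "A", "T", 0, 0, 10, 5)))
  expect_true(is.na(calls$fisher_p))
  expect_false(calls$qc_pass)
})

test_that("QC applies every threshold with the printed comparators", {
  base <- list(fisher_p = 0.01, normal_ref = 40L, normal_alt = 0L,
               tumor_ref = 47L, tumor_alt = 3L)
  qc1 <- function(mod) {
    row <- utils::modifyList(base, mod)
    apply_qc(as.data.frame(row), pipeline_config())
  }
  # tumor VAF = 3/50 = 0.06: every criterion at or above threshold
  expect_true(qc1(list()))
  # normal depth 9 fails the depth rule
  expect_false(qc1(list(normal_ref = 9L)))
  # two variant reads in the normal are disqualifying
  expect_false(qc1(list(normal_alt = 2L)))
  # boundary behaviour: p is strict, VAFs are inclusive
  expect_false(qc1(list(fisher_p = 0.05)))
  expect_true(qc1(list(tumor_ref = 57L)))          # tumor VAF exactly 0.05
  expect_false(qc1(list(tumor_ref = 58L)))         # just below 0.05
  # normal VAF exactly at 0.03 is inclusive (alt cap relaxed to isolate it)
  row <- as.data.frame(utils::modifyList(base, list(
    normal_ref = 97L, normal_alt = 3L, tumor_ref = 100L, tumor_alt = 100L)))
  expect_true(apply_qc(row, pipeline_config(qc_normal_alt_max = 5)))
  row$normal_ref <- 96L
  expect_false(apply_qc(row, pipeline_config(qc_normal_alt_max = 5)))
  expect_false(qc1(list(tumor_alt = 2L, tumor_ref = 8L)))
})

test_that("rarity requires all four panel frequencies strictly below the cutoff", {
  ann <- data.frame(freq_1kg_eas = c(NA, 0.005, 0.004, 0.004),
                    freq_exac_eas = c(NA, 0.001, 0.004, NA),
                    freq_gnomad_genome_eas = c(NA, 0.001, 0.004, 0.001),
                    freq_gnomad_exome_eas = c(NA, 0.001, 0.004, 0.0049))
  expect_equal(flag_rare(ann), c(TRUE, FALSE, TRUE, TRUE))
  bad <- ann[1, ]; bad$freq_1kg_eas <- 1.2
  expect_error(flag_rare(bad), "\\[0, 1\\]")
})

test_that("severity combines consequence class with a two-predictor vote", {
  ann <- rbind(
    make_annotation("c", 1, "A", "T", "g1", cadd = 32, sift = TRUE, poly = TRUE),
    make_annotation("c", 2, "A", "T", "g2", cadd = 29.6, sift = TRUE, poly = TRUE),
    make_annotation("c", 3, "A", "T", "g3", consequence = "frameshift"),
    make_annotation("c", 4, "A", "T", "g4", cadd = 35),          # one vote
    make_annotation("c", 5, "A", "T", "g5", cadd = 10, sift = FALSE,
                    poly = TRUE),                                 # one vote
    make_annotation("c", 6, "A", "T", "g6", consequence = "stopgain"))
  expect_equal(flag_severe(ann), c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  syn <- make_annotation("c", 7, "A", "T", "g7", consequence = "synonymous")
  expect_error(flag_severe(syn), "synonymous")
})

test_that("cascade handles empty input and basic set algebra", {
  empty <- make_candidates(list("E1", "chr1", 1, "A", "T", 1, 1, 1, 1))[0, ]
  casc <- run_cascade(empty, make_annotation("c", 1, "A", "T", "g")[0, ])
  expect_true(all(casc$counts == 0L))

  # a rare-but-benign variant sits in P but neither S nor F
  cand <- make_candidates(list("E1", "chr1", 10, "A", "T", 200, 0, 150, 50))
  ann <- make_annotation("chr1", 10, "A", "T", "g1",
                         cadd = 5, sift = FALSE, poly = FALSE)
  casc <- run_cascade(cand, ann)
  expect_equal(unname(casc$counts[, "mutations"]),
               c(1L, 1L, 0L, 0L))  # QC, P, S, F
})

test_that("stage sets are nested and shrink when thresholds tighten", {
  sim <- simulate_variants(simulation_plan(seed = 31))
  casc <- run_cascade(sim$candidates, sim$annotation)
  v <- casc$variants
  expect_true(all(!v$is_rare | v$qc_pass))
  expect_true(all(!v$is_severe | v$qc_pass))
  expect_true(all(v$is_final == (v$is_rare & v$is_severe)))

  tight <- pipeline_config(qc_p_max = 0.01, qc_depth_min = 20,
                           rare_freq_max = 0.001, severe_tool_min = 3,
                           qc_tumor_vaf_min = 0.10)
  casc2 <- run_cascade(sim$candidates, sim$annotation, tight)
  v2 <- casc2$variants
  for (col in c("qc_pass", "is_rare", "is_severe", "is_final"))
    expect_true(all(!v2[[col]] | v[[col]]))
})

test_that("cascade results are invariant to input order", {
  sim <- simulate_variants(simulation_plan(seed = 8))
  casc <- run_cascade(sim$candidates, sim$annotation)
  set.seed(2)
  perm <- sample(nrow(sim$candidates))
  casc_p <- run_cascade(sim$candidates[perm, ], sim$annotation)
  expect_identical(casc$counts, casc_p$counts)
  key <- function(v) paste(v$patient_id, v$chrom, v$pos, v$ref, v$alt)
  a <- casc$variants; b <- casc_p$variants
  b <- b[match(key(a), key(b)), ]
  expect_equal(a$is_final, b$is_final)
  expect_identical(casc$per_patient, casc_p$per_patient)
})

test_that("recurrence summary counts patients per gene and conserves mutations", {
  plan <- simulation_plan(seed = 17)
  sim <- simulate_variants(plan)
  casc <- run_cascade(sim$candidates, sim$annotation)
  finals <- final_mutations(casc)
  rec <- recurrence_summary(finals)
  hub <- plan_gene_layout(plan)$hub_gene
  expect_equal(rec$n_patients[rec$gene == hub], plan$n_patients)
  expect_equal(rec$gene[1], hub)  # sorted by recurrence
  expect_equal(sum(rec$n_mutations), nrow(finals))
  # a private background passenger recurs in exactly one patient
  priv <- sim$truth$gene[sim$truth$role == "background_final"]
  priv <- setdiff(priv, priv[duplicated(priv)])[1]
  expect_equal(rec$n_patients[rec$gene == priv], 1L)
})
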