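## Synthetic inputs with the statistical structure the pipeline assumes:
## a shared high-VAF first-hit mutation, lower-VAF secondary hits in a
## trait-associated co-expression module, passengers that each fail one
## named filter, a block-correlated factor-model expression matrix, and a
## GO annotation with one term concentrated in the disease module.

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Simulation plan
#'
#' The study conditions for the synthetic cohort. Defaults mirror the kind
#' of design the pipeline targets: four patients sequenced deep (1000x), a
#' shared first-hit mutation at tumor VAF 0.35, one to a few secondary hits
#' per patient at VAFs drawn from \[0.05, 0.25\] (strictly below the first
#' hit, so the planted temporal ordering is recoverable), a 300-gene
#' expression matrix with three planted modules of loading 0.9 over 12
#' samples, and a disease-module factor shifted down by 4 SD in tumors
#' (which yields a module-trait correlation magnitude around 0.9).
#'
#' @param n_patients Number of tumor-normal pairs.
#' @param n_sites_per_patient Total candidate sites per patient; must cover
#'   1 first hit + `n_secondary_per_patient` + the 5 planted filter-failure
#'   passengers. The remainder become rare, severe passengers in background
#'   genes.
#' @param n_secondary_per_patient Secondary disease-module hits per patient.
#' @param first_hit_vaf True tumor VAF of the shared first-hit site.
#' @param secondary_vaf_range VAF interval for secondary hits; its maximum
#'   must stay below `first_hit_vaf`.
#' @param mean_depth Mean sequencing depth (Poisson).
#' @param n_genes,n_modules,module_sizes Gene universe and planted module
#'   sizes (module 1 is the disease module; leftover genes are background).
#' @param loading Factor loading of module genes.
#' @param noise_sd Residual standard deviation of the factor model.
#' @param n_normal_samples,n_tumor_samples Expression sample counts.
#' @param tumor_shift Shift (factor SD units, negative = down-regulated in
#'   tumor) applied to the disease-module factor in tumor samples.
#' @param seed Integer seed; identical plans give byte-identical output.
#' @return List of class `"simulation_plan"`.
#' @export
simulation_plan <- function(n_patients = 4L,
                            n_sites_per_patient = 10L,
                            n_secondary_per_patient = 2L,
                            first_hit_vaf = 0.35,
                            secondary_vaf_range = c(0.05, 0.25),
                            mean_depth = 1000L,
                            n_genes = 300L,
                            n_modules = 3L,
                            module_sizes = c(80L, 70L, 60L),
                            loading = 0.9,
                            noise_sd = 0.1,
                            n_normal_samples = 6L,
                            n_tumor_samples = 6L,
                            tumor_shift = -4,
                            seed = 1L) {
  plan <- list(n_patients = as.integer(n_patients),
               n_sites_per_patient = as.integer(n_sites_per_patient),
               n_secondary_per_patient = as.integer(n_secondary_per_patient),
               first_hit_vaf = first_hit_vaf,
               secondary_vaf_range = as.numeric(secondary_vaf_range),
               mean_depth = as.integer(mean_depth),
               n_genes = as.integer(n_genes),
               n_modules = as.integer(n_modules),
               module_sizes = as.integer(module_sizes),
               loading = loading, noise_sd = noise_sd,
               n_normal_samples = as.integer(n_normal_samples),
               n_tumor_samples = as.integer(n_tumor_samples),
               tumor_shift = tumor_shift, seed = as.integer(seed))
  if (plan$n_patients < 1L) stop("need at least one patient")
  if (length(plan$secondary_vaf_range) != 2L ||
      diff(plan$secondary_vaf_range) < 0)
    stop("secondary_vaf_range must be an increasing interval")
  if (plan$first_hit_vaf <= max(plan$secondary_vaf_range))
    stop("first_hit_vaf must exceed the secondary VAF range, otherwise the ",
         "planted ordering is not recoverable")
  if (any(c(plan$first_hit_vaf, plan$secondary_vaf_range) < 0) ||
      any(c(plan$first_hit_vaf, plan$secondary_vaf_range) > 1))
    stop("VAFs must lie in [0, 1]")
  if (length(plan$module_sizes) != plan$n_modules)
    stop("module_sizes must have n_modules entries")
  if (sum(plan$module_sizes) > plan$n_genes)
    stop("module sizes exceed n_genes")
  if (plan$noise_sd <= 0) stop("noise_sd must be positive")
  if (plan$loading < 0 || plan$loading > 1)
    stop("loading must be a fraction in [0, 1]")
  min_sites <- 1L + plan$n_secondary_per_patient + 5L
  if (plan$n_sites_per_patient < min_sites)
    stop("n_sites_per_patient must be >= ", min_sites,
         " (first hit + secondaries + 5 filter-failure passengers)")
  structure(plan, class = "simulation_plan")
}

#' Planted gene layout of a plan
#'
#' Deterministic gene naming shared by the variant and expression
#' generators: genes `G0001..`, planted modules `M1..Mk` occupying the
#' first `sum(module_sizes)` genes (module `M1` is the disease module,
#' whose first gene is the designated first-hit hub), the rest background.
#'
#' @param plan A [simulation_plan()].
#' @return List with `gene_ids`, `module_labels` (named vector), `modules`
#'   (planted labels), `disease_module`, `hub_gene`.
#' @export
plan_gene_layout <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  gene_ids <- sprintf("G%04d", seq_len(plan$n_genes))
  labels <- rep("background", plan$n_genes)
  at <- 1L
  for (m in seq_len(plan$n_modules)) {
    labels[at:(at + plan$module_sizes[m] - 1L)] <- paste0("M", m)
    at <- at + plan$module_sizes[m]
  }
  names(labels) <- gene_ids
  list(gene_ids = gene_ids, module_labels = labels,
       modules = paste0("M", seq_len(plan$n_modules)),
       disease_module = "M1", hub_gene = gene_ids[1L])
}

## Depth draw for sites that must survive depth QC: Poisson truncated from
## below so the planted fate is realisable.
.draw_depth <- function(n, mean_depth, floor_depth) {
  pmax(rpois(n, mean_depth), floor_depth)
}

## Tumor-side counts for sites meant to pass QC: binomial draws are
## rejection-sampled (then clamped) so the realised counts satisfy the
## tumor-side thresholds their planted fate requires.
.draw_pass_tumor_alt <- function(depth, vaf, cfg) {
  for (i in 1:50) {
    alt <- rbinom(1L, depth, vaf)
    if (alt >= cfg$qc_tumor_alt_min && alt / depth >= cfg$qc_tumor_vaf_min)
      return(alt)
  }
  max(cfg$qc_tumor_alt_min, ceiling(cfg$qc_tumor_vaf_min * depth))
}

## Normal-side counts for sites meant to pass QC: sequencing-error draws
## clamped to the normal-side thresholds (contamination-free matched normal).
.draw_pass_normal_alt <- function(depth, cfg) {
  min(rbinom(1L, depth, 0.002), cfg$qc_normal_alt_max,
      floor(cfg$qc_normal_vaf_max * depth))
}

.rare_freqs <- function() {
  # never observed in any panel (NA) or well below the rarity cutoff
  if (runif(1) < 0.5) rep(NA_real_, 4L) else runif(4L, 0, 0.004)
}

#' Simulate paired tumor-normal variant candidates
#'
#' Plants, per patient: one shared first-hit site in the disease-module hub
#' gene at `first_hit_vaf`; `n_secondary_per_patient` secondary hits in
#' other disease-module genes at VAFs from `secondary_vaf_range`; five
#' passengers each designed to fail one named filter (low depth, variant
#' reads in the normal, common in population panels, benign predictions,
#' synonymous consequence); and rare, severe background-gene passengers for
#' any remaining site budget. Read counts are binomial at the planted VAF
#' with Poisson depth; the truth table records each site's intended fate
#' through the cascade.
#'
#' @param plan A [simulation_plan()].
#' @param cfg A [pipeline_config()]; the generator guarantees fates against
#'   these thresholds.
#' @return List with `candidates` (variant table), `annotation` (per-site
#'   annotation), `truth` (per patient-site: role, planted module, true
#'   VAF, expected stage flags).
#' @export
simulate_variants <- function(plan, cfg = pipeline_config()) {
  stopifnot(inherits(plan, "simulation_plan"))
  if (plan$mean_depth < cfg$qc_depth_min + 10L)
    stop("mean_depth too low to realise the planted VAF categories")
  if (plan$mean_depth * min(plan$secondary_vaf_range) < cfg$qc_tumor_alt_min)
    stop("mean_depth too low for the secondary VAF range")
  layout <- plan_gene_layout(plan)
  dis_genes <- names(layout$module_labels)[
    layout$module_labels == layout$disease_module]
  sec_pool <- setdiff(dis_genes, layout$hub_gene)
  bg_pool <- names(layout$module_labels)[layout$module_labels == "background"]
  if (length(sec_pool) < plan$n_secondary_per_patient)
    stop("disease module too small for the secondary hits")
  n_extra <- plan$n_sites_per_patient - 1L -
    plan$n_secondary_per_patient - 5L
  floor_depth <- cfg$qc_depth_min + 5L

  .with_seed(plan$seed, {
    pts <- sprintf("P%02d", seq_len(plan$n_patients))
    rows <- list(); truth <- list(); ann <- list()
    site_counter <- 0L
    new_pos <- function() {
      site_counter <<- site_counter + 1L
      1000000L + site_counter * 100L
    }
    add_site <- function(pt, gene, role, vaf, expect,
                         consequence, ref = "C", alt = "G",
                         freqs = .rare_freqs(), cadd = NA_real_,
                         sift = NA, poly = NA, pos = NULL,
                         low_depth = FALSE, normal_vaf = NULL) {
      pos <- pos %||% new_pos()
      if (low_depth) {
        dn <- sample((cfg$qc_depth_min - 4L):(cfg$qc_depth_min - 1L), 1L)
        dt <- sample((cfg$qc_depth_min - 4L):(cfg$qc_depth_min - 1L), 1L)
        ta <- rbinom(1L, dt, vaf)
        na_ <- 0L
      } else {
        dn <- .draw_depth(1L, plan$mean_depth, floor_depth)
        dt <- .draw_depth(1L, plan$mean_depth, floor_depth)
        if (is.null(normal_vaf)) {
          na_ <- .draw_pass_normal_alt(dn, cfg)
          ta <- .draw_pass_tumor_alt(dt, vaf, cfg)
        } else {
          na_ <- max(rbinom(1L, dn, normal_vaf), cfg$qc_normal_alt_max + 1L)
          ta <- .draw_pass_tumor_alt(dt, vaf, cfg)
        }
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = pt, chrom = "chr1", pos = pos, ref = ref, alt = alt,
        normal_ref = as.integer(dn - na_), normal_alt = as.integer(na_),
        tumor_ref = as.integer(dt - ta), tumor_alt = as.integer(ta))
      truth[[length(truth) + 1L]] <<- data.frame(
        patient_id = pt, chrom = "chr1", pos = pos, ref = ref, alt = alt,
        gene = gene, role = role,
        module = unname(layout$module_labels[gene]), true_vaf = vaf,
        expect_qc = expect[1L], expect_rare = expect[2L],
        expect_severe = expect[3L], expect_final = expect[1L] &
          expect[2L] & expect[3L],
        expect_synonymous = consequence == "synonymous")
      ann[[length(ann) + 1L]] <<- data.frame(
        chrom = "chr1", pos = pos, ref = ref, alt = alt, gene = gene,
        consequence = consequence,
        freq_1kg_eas = freqs[1L], freq_exac_eas = freqs[2L],
        freq_gnomad_genome_eas = freqs[3L],
        freq_gnomad_exome_eas = freqs[4L],
        cadd_phred = cadd, sift_damaging = sift, polyphen_damaging = poly)
      invisible(NULL)
    }

    first_hit_pos <- 100000L
    for (pt in pts) {
      # shared first hit: missense, never seen in any panel, damaging by
      # all three predictors
      add_site(pt, layout$hub_gene, "first_hit", plan$first_hit_vaf,
               c(TRUE, TRUE, TRUE), "missense", ref = "A", alt = "T",
               freqs = rep(NA_real_, 4L), cadd = 32, sift = TRUE,
               poly = TRUE, pos = first_hit_pos)
      # secondary disease-module hits, strictly below the first-hit VAF
      sec_genes <- sample(sec_pool, plan$n_secondary_per_patient)
      for (j in seq_along(sec_genes)) {
        vaf <- runif(1L, plan$secondary_vaf_range[1L],
                     plan$secondary_vaf_range[2L])
        if (j %% 2L == 1L)
          add_site(pt, sec_genes[j], "secondary", vaf, c(TRUE, TRUE, TRUE),
                   "missense", cadd = 25, sift = TRUE, poly = TRUE)
        else
          add_site(pt, sec_genes[j], "secondary", vaf, c(TRUE, TRUE, TRUE),
                   "frameshift", ref = "CT", alt = "C")
      }
      # one passenger per named filter failure
      bg <- sample(bg_pool, 5L + max(n_extra, 0L))
      add_site(pt, bg[1L], "fail_qc_depth", 0.8, c(FALSE, FALSE, FALSE),
               "missense", cadd = 35, sift = TRUE, poly = TRUE,
               low_depth = TRUE)
      add_site(pt, bg[2L], "fail_qc_normal", 0.35, c(FALSE, FALSE, FALSE),
               "missense", cadd = 35, sift = TRUE, poly = TRUE,
               normal_vaf = 0.12)
      add_site(pt, bg[3L], "fail_rare", 0.2, c(TRUE, FALSE, TRUE),
               "missense", freqs = runif(4L, 0.01, 0.2), cadd = 35,
               sift = TRUE, poly = TRUE)
      add_site(pt, bg[4L], "fail_severe", 0.2, c(TRUE, TRUE, FALSE),
               "missense", cadd = 8, sift = FALSE, poly = FALSE)
      # discarded before the cascade, so it belongs to no stage set
      add_site(pt, bg[5L], "synonymous", 0.2, c(FALSE, FALSE, FALSE),
               "synonymous")
      # remaining budget: rare, severe passengers in background genes
      if (n_extra > 0L) for (j in seq_len(n_extra)) {
        vaf <- runif(1L, plan$secondary_vaf_range[1L],
                     plan$secondary_vaf_range[2L])
        add_site(pt, bg[5L + j], "background_final", vaf,
                 c(TRUE, TRUE, TRUE), "stopgain")
      }
    }
    candidates <- do.call(rbind, rows)
    truth <- do.call(rbind, truth)
    ann <- do.call(rbind, ann)
    ann <- ann[!duplicated(.variant_key(ann)), , drop = FALSE]
    rownames(candidates) <- rownames(truth) <- rownames(ann) <- NULL
    list(candidates = candidates, annotation = ann, truth = truth)
  })
}

#' Simulate a block-modular expression dataset
#'
#' Factor model `x_gs = loading * f_m(g),s + e_gs` with independent
#' standard-normal factors per planted module and sample, `e ~ N(0,
#' noise_sd^2)`; background genes are pure noise. The disease module's
#' factor mean is shifted by `tumor_shift` in tumor samples, so its
#' eigengene tracks the normal/tumor trait.
#'
#' @param plan A [simulation_plan()].
#' @return List with `expr` (an [expression_dataset()]), `module_labels`
#'   (planted gene labels), `disease_module`, `hub_gene`.
#' @export
simulate_expression <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  n_s <- plan$n_normal_samples + plan$n_tumor_samples
  if (n_s < 4L)
    stop("need at least 4 samples (normal + tumor) for correlation work")
  layout <- plan_gene_layout(plan)
  .with_seed(plan$seed + 1L, {
    samples <- c(sprintf("N%02d", seq_len(plan$n_normal_samples)),
                 sprintf("T%02d", seq_len(plan$n_tumor_samples)))
    trait <- rep(c(0L, 1L), c(plan$n_normal_samples, plan$n_tumor_samples))
    f <- matrix(stats::rnorm(plan$n_modules * n_s), plan$n_modules, n_s,
                dimnames = list(layout$modules, samples))
    f[layout$disease_module, trait == 1L] <-
      f[layout$disease_module, trait == 1L] + plan$tumor_shift
    x <- matrix(stats::rnorm(plan$n_genes * n_s, sd = plan$noise_sd),
                plan$n_genes, n_s,
                dimnames = list(layout$gene_ids, samples))
    for (m in layout$modules) {
      idx <- layout$module_labels == m
      x[idx, ] <- x[idx, ] + plan$loading * matrix(f[m, ], sum(idx), n_s,
                                                   byrow = TRUE)
    }
    list(expr = expression_dataset(x, trait),
         module_labels = layout$module_labels,
         disease_module = layout$disease_module,
         hub_gene = layout$hub_gene)
  })
}

#' Simulate a GO-BP annotation with one planted enriched term
#'
#' Builds a term-to-gene map over the plan's gene universe: one term
#' concentrated in the disease module (80% of its genes from it), a parent
#' term that is a strict superset of it, and several size-matched random
#' terms; all terms have at least `min_term_genes` genes.
#'
#' @param plan A [simulation_plan()].
#' @param module_labels Planted gene labels (from [simulate_expression()]
#'   or [plan_gene_layout()]).
#' @param n_random_terms Number of size-matched random terms.
#' @param min_term_genes Smallest term size (matches the enrichment
#'   filter's default of 10).
#' @return List with `structure` (a [go_structure()]), `enriched_term`,
#'   `parent_term`.
#' @export
simulate_go <- function(plan, module_labels, n_random_terms = 8L,
                        min_term_genes = 10L) {
  stopifnot(inherits(plan, "simulation_plan"))
  genes <- names(module_labels)
  layout <- plan_gene_layout(plan)
  dis <- genes[module_labels == layout$disease_module]
  if (length(dis) < min_term_genes)
    stop("disease module smaller than the minimum term size")
  .with_seed(plan$seed + 2L, {
    size <- max(min_term_genes, min(30L, length(dis)))
    n_dis <- ceiling(0.8 * size)
    enriched <- c(sample(dis, n_dis),
                  sample(setdiff(genes, dis), size - n_dis))
    parent <- unique(c(enriched, sample(setdiff(genes, enriched), 15L)))
    terms <- list(GO_DISEASE = enriched, GO_DISEASE_PARENT = parent)
    for (i in seq_len(n_random_terms))
      terms[[sprintf("GO_RAND%02d", i)]] <- sample(genes, size)
    structure_ <- go_structure(terms,
                               parent_of = list(GO_DISEASE = "GO_DISEASE_PARENT"))
    list(structure = structure_, enriched_term = "GO_DISEASE",
         parent_term = "GO_DISEASE_PARENT")
  })
}
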