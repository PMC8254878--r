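---
title: "Methods: somatic filtration, co-expression networks and two-hit ordering"
author: "amelonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic filtration, co-expression networks and two-hit ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amelonet)
```

amelonet implements an integrative analysis for small paired tumor–normal
cohorts, motivated by odontogenic tumors such as ameloblastoma where a
recurrent kinase mutation (the classic example is BRAF V600E) is necessary
but apparently not sufficient for tumorigenesis. The pipeline asks three
questions: which somatic mutations survive a strict filtration cascade;
which co-expression module of a companion expression dataset is disrupted
in tumors; and whether the variant allele fractions (VAFs) of the
filtered mutations support a two-hit temporal ordering — a shared,
high-VAF "first hit" preceding private, lower-VAF "second hits" in the
same disrupted module.

This vignette documents the models, the tunable parameters with their
defaults and rationale, the synthetic data generator used for testing, and
the numerical choices and limitations a maintainer should know about. It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

## Somatic calling and the filtration cascade

For each candidate site the paired read counts form a 2×2 table
(reference/variant × normal/tumor). `fisher_somatic_test()` computes the
Fisher exact p-value, by default one-sided towards variant-read enrichment
in the tumor — the convention of paired somatic callers, where depletion
of variant reads in the tumor is not evidence of a somatic event. The
one-sided p is the upper hypergeometric tail over tables with the observed
margins; a two-sided option (summing all tables at most as probable as the
observed one) is available through
`pipeline_config(fisher_alternative = "two.sided")`. Sites with zero depth
in either tissue are flagged undefined (`NA`) rather than computed.

`run_cascade()` applies four stages, after discarding synonymous variants:

* **QC** — all of: Fisher p < 0.05 (strict); depth ≥ 10 in both tissues;
  variant-supporting reads ≤ 1 in normal and ≥ 3 in tumor; normal VAF
  ≤ 0.03; tumor VAF ≥ 0.05. Boundary comparators are applied exactly as
  stated, so a tumor VAF of exactly 0.05 passes while p = 0.05 fails.
* **P (rare)** — every non-missing of four East-Asian population
  frequencies (1000 Genomes, ExAC, GnomAD genome, GnomAD exome) strictly
  below 0.005. A missing frequency counts as zero: absence from a large
  population panel is the strongest rarity evidence available.
* **S (severe)** — frameshift, stop-gain/-loss, start-loss and splice
  variants by consequence class alone; missense variants when at least two
  of three predictors vote damaging (CADD-phred ≥ 30, SIFT "D",
  PolyPhen-2 "D"). Predictors are consumed as binary calls; raw scores are
  carried for reporting only. A missing prediction never votes.
* **F (final)** — the intersection P ∩ S. P and S are defined within the
  QC-passing set, so F ⊆ P ⊆ QC and F ⊆ S ⊆ QC by construction, and
  tightening any threshold can only shrink every set.

Variants are keyed by (patient, chromosome, 1-based position, ref, alt);
multi-allelic records are split before testing, and indels are consumed as
the caller left them (no re-normalisation).

## The co-expression network fit

`fit_coexpression_network()` is the package's central model fit. Its
components, all written against a genes × samples matrix with a binary
normal/tumor trait:

* **Unsigned adjacency** `a_ij = |cor(x_i, x_j)|^β`, diagonal zeroed. The
  default power β = 12 is the conventional unsigned default and can be
  chosen by `pick_soft_threshold()`, which reports the signed scale-free
  fit index (R² of log-frequency vs log-connectivity, negated when the
  slope is positive) and picks the smallest power reaching 0.85, falling
  back to the argmax when no power qualifies. On block-modular data —
  including this package's generator, whose three equal planted blocks are
  deliberately not scale-free — the fallback governs, which is why the fit
  table is returned for inspection rather than trusted blindly.
* **Topological overlap**
  `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
  `L_ij = Σ_u a_iu a_uj`, `TOM_ii = 1`. The denominator is positive
  because `a_ij ≤ min(k_i, k_j)`.
* **Module detection** — average-linkage hierarchical clustering of
  `1 − TOM`, cut statically at height 0.4, clusters below 30 genes
  relabelled "grey". A single named cut height is the signature of a
  static cut, so that is the tested default; average linkage is the field
  default for TOM dendrograms. No module-merging step is applied.
  Surviving modules are named by decreasing size after the conventional
  colour palette (turquoise first).
* **Module eigengene (ME)** — first right-singular direction of the
  gene-standardised module submatrix, scaled to unit variance, sign fixed
  so the ME correlates non-negatively with mean standardised module
  expression. The sign rule makes "down-regulated in tumors" map
  deterministically to a negative ME shift in tumor samples.
* **Module–trait correlation** — Pearson r between each ME and the binary
  trait (normal = 0, tumor = 1), with the two-sided Student-t p-value on
  n − 2 degrees of freedom. `correlation_pvalue(0.93, 6)` and
  `correlation_pvalue(0.85, 6)` reproduce the r/p pairs this machinery is
  validated against.
* **kME** — signed correlation of each gene with each ME; the module hub
  is the member gene with the largest |kME|, so strong negative-side hubs
  are recognised as hubs.

## GO over-representation

`hypergeom_enrich()` tests each term with at least 10 annotated genes
(after intersection with the universe, by default all annotated genes; a
custom universe can be supplied when the background should be the assayed
genes instead). The p-value is the upper tail P(X ≥ k) including the
observed overlap, adjusted by Benjamini–Hochberg. Among significant terms
(FDR ≤ 0.05), `nonredundant_filter()` drops every term that is an ancestor
of another significant term. "Parent" is interpreted transitively — the
stricter reading, and the only one that guarantees no kept term subsumes
another; a direct-parent-only switch exists. Only is_a-style edges are
consumed.

## Mutation–network integration and the two-hit test

`build_subnetwork()` anchors on the module with the strongest trait
correlation. Nodes are the final-mutation genes present in the expression
data plus every anchor-module gene with TOM ≥ 0.15 to at least one mutated
gene; edges join **all** node pairs at TOM ≥ 0.15, not only
mutated-to-neighbour pairs — neighbour–neighbour edges are what allow
large connected components centred on non-mutated hubs, the structure this
analysis is designed to expose. Mutated genes outside the anchor module
enter as nodes but recruit no neighbours of their own, since the
sub-network is a sub-network *of the anchor module*.

`vaf_ordering_test()` operationalises the two-hit reading. The candidate
first hit is the final-mutation gene shared by the most patients (ties
broken by higher mean tumor VAF — the more clonal candidate), chosen from
the data rather than hard-coded so the test generalises. "Ratio of
variant-support reads" is read as the tumor VAF
(`tumor_alt / (tumor_alt + tumor_ref)`): with normal variant reads capped
at 1 by QC, a tumor/normal read ratio would be mostly infinite, so the
tumor VAF is the only finite, standard interpretation. Per patient the
ordering holds iff the first-hit VAF **strictly** exceeds every other
anchor-module final mutation's VAF; ties are violations. The cohort is
"two-hit consistent" iff every evaluated patient carries ≥ 2 anchor-module
final mutations and the ordering holds for all; patients lacking the
first-hit variant are flagged and excluded from the verdict. No tumor
purity correction is applied, so VAF comparisons assume comparable purity
across the sites of one patient.

## The synthetic study conditions

`simulation_plan()` fixes the conditions every test runs under; they are
study conditions, not tuning knobs.

* **Cohort**: 4 patients, 10 candidate sites each. Each patient carries
  the shared first-hit site (tumor VAF 0.35) in the disease module's
  designated hub gene, two secondary hits in other disease-module genes at
  VAFs uniform on [0.05, 0.25] (strictly below the first hit, so the
  planted ordering is recoverable), five passengers each designed to fail
  exactly one named filter (low depth, variant reads in the normal, common
  in the population panels, benign predictions, synonymous), and two rare,
  severe passengers in background genes.
* **Read counts**: depth ~ Poisson(1000) — deep targeted exomes — truncated
  below at depth-QC + 5 for sites that must survive depth QC; tumor
  variant reads ~ Binomial(depth, VAF); normal variant reads
  ~ Binomial(depth, 0.002) for sequencing error. For sites whose planted
  fate is to pass QC, the normal draw is clamped at the normal-side
  thresholds and the tumor draw is rejection-sampled (≤ 50 tries) into the
  tumor-side thresholds: at 1000× depth an unclamped 0.002 error rate
  alone would fail ~60% of genuinely somatic sites on the "≤ 1 normal
  read" rule, and the truth table must describe realisable fates for the
  cascade to be testable against it exactly.
* **Expression**: 300 genes, three planted modules of 80/70/60 genes
  (module 1 is the disease module), 6 normal + 6 tumor samples. Factor
  model `x = 0.9 f + ε`, `ε ~ N(0, 0.1²)`, factors standard normal and
  independent across modules; background genes are pure noise. Loading
  0.9 with noise 0.1 gives within-module correlations near 0.99, i.e.
  within-module TOM dissimilarity well below the 0.4 cut height — at
  substantially higher noise the prescribed static cut cannot recover any
  planted partition, so these are the conditions under which module
  recovery is a meaningful check. The disease-module factor mean is
  shifted by −4 SD in tumor samples, which yields module–trait correlation
  magnitudes around 0.9, the regime the analytic r/p validation pairs come
  from.
* **GO**: one term with 80% of its genes from the disease module, a strict
  superset parent term, and eight size-matched random terms; all terms
  ≥ 10 genes.

What the generator does **not** emulate: tumor purity and copy-number
distortion of VAFs, mutational signatures, array-specific noise and batch
structure, overlapping or hierarchically nested modules, and realistic GO
DAG depth. Passing tests therefore show the machinery is correct under
block-correlated, purity-free conditions; they do not certify performance
on real exomes or arrays.

## Numerical choices and degenerate inputs

* Hypergeometric tails (Fisher and enrichment) are computed with
  `phyper`; tests verify them against independent `choose()`-based
  enumeration to 1e-10/1e-12.
* Average-linkage heights are rounded to 12 decimals before `cutree`:
  tied dissimilarities can otherwise lose strict monotonicity to floating
  rounding and `cutree` refuses the tree.
* Expression matrices are serialised with `%.17g`, so a write/read
  round-trip is bit-identical.
* Zero depth → `NA` Fisher p and automatic QC failure; an empty candidate
  table yields zero counts everywhere; a cut height of 0 isolates every
  gene and returns all-grey with a warning; an empty query or a query
  disjoint from the universe returns an empty enrichment table with a
  warning.
* Generators save and restore the session RNG state, so simulation is
  deterministic in the plan seed without disturbing the caller's stream.

## Problem sizes used by the test suite

The suite exercises: the full 2×2 table grid with margins ≤ 40 for the
Fisher oracle; 20 random 15-gene adjacencies for the TOM oracle; 20 seeds
of the default 300-gene design for module recovery; 100 seeds for
first-hit/secondary VAF separability and for the two-hit verdict; and 200
random-query seeds for the enrichment false-positive band. These sizes
make the whole suite run in well under a minute while keeping the
repetition studies' binomial error bounds meaningful.

## Known limitations

* The static cut at 0.4 assumes tight modules; diffuse modules (TOM
  dissimilarity above the cut) dissolve into grey rather than merging, and
  the optional merge-by-ME step is deliberately absent.
* The two-hit verdict is a VAF comparison, not clonal deconvolution; it
  cannot distinguish ordering from purity or copy-number effects.
* The scale-free fit index is reported but rarely decisive on strongly
  modular designs; the fixed default power is the recommended setting for
  small-sample data.
* Rarity treats a missing panel frequency as zero; a variant absent from
  the annotation entirely is an error, not an implicit pass.
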