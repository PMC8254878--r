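## External representations. Variants are keyed (patient, chrom, pos, ref,
## alt) with 1-based VCF positions; indels are consumed as given, never
## re-normalised. TSV is the canonical dialect; VCF is read-only convenience.

.variant_cols <- c("patient_id", "chrom", "pos", "ref", "alt",
                   "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")

#' Read a variant candidate table
#'
#' Two dialects are supported. `"tsv"`: a whitespace-delimited table with a
#' header naming the nine canonical columns (`patient_id chrom pos ref alt
#' normal_ref normal_alt tumor_ref tumor_alt`). `"vcf"`: a VCF whose
#' genotype columns carry AD-style ref,alt depths for a NORMAL and a TUMOR
#' sample; multi-allelic records are split into one candidate per alternate
#' allele. Positions are 1-based throughout.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param patient_id Patient identifier for the VCF dialect (one VCF per
#'   patient); defaults to the file name without extension.
#' @param normal_sample,tumor_sample Sample-column names in the VCF;
#'   matched case-insensitively.
#' @return Data frame of variant candidates.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               patient_id = NULL,
                               normal_sample = "NORMAL",
                               tumor_sample = "TUMOR") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    .read_variant_tsv(path)
  } else {
    .read_variant_vcf(path, patient_id, normal_sample, tumor_sample)
  }
}

.read_variant_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty variant table: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1L]]
  if (!identical(header, .variant_cols))
    stop("variant TSV header must be: ", paste(.variant_cols, collapse = " "))
  rows <- fields[-1L]
  n_bad <- which(lengths(rows) != 9L)
  if (length(n_bad))
    stop(sprintf("malformed variant row at line %d: expected 9 fields, got %d",
                 n_bad[1L] + 1L, length(rows[[n_bad[1L]]])))
  m <- do.call(rbind, rows)
  num <- c("pos", "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")
  out <- data.frame(patient_id = m[, 1L], chrom = m[, 2L],
                    pos = suppressWarnings(as.integer(m[, 3L])),
                    ref = m[, 4L], alt = m[, 5L],
                    normal_ref = suppressWarnings(as.integer(m[, 6L])),
                    normal_alt = suppressWarnings(as.integer(m[, 7L])),
                    tumor_ref = suppressWarnings(as.integer(m[, 8L])),
                    tumor_alt = suppressWarnings(as.integer(m[, 9L])))
  bad <- which(Reduce(`|`, lapply(out[num], is.na)))
  if (length(bad))
    stop(sprintf("malformed variant row at line %d: non-numeric count field",
                 bad[1L] + 1L))
  if (any(out$ref == out$alt))
    stop("ref and alt alleles must differ")
  out
}

.read_variant_vcf <- function(path, patient_id, normal_sample, tumor_sample) {
  if (is.null(patient_id))
    patient_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  ni <- match(toupper(normal_sample), toupper(samples))
  ti <- match(toupper(tumor_sample), toupper(samples))
  if (length(samples) < 2L || is.na(ni) || is.na(ti))
    stop("VCF format error: need both '", normal_sample, "' and '",
         tumor_sample, "' sample columns (found: ",
         paste(samples, collapse = ", "), ")")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || anyNA(ad[, c(ni, ti)]))
    stop("VCF format error: AD (allelic depth) missing for some records")
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    nad <- as.integer(strsplit(ad[i, ni], ",", fixed = TRUE)[[1L]])
    tad <- as.integer(strsplit(ad[i, ti], ",", fixed = TRUE)[[1L]])
    if (length(nad) != length(alts) + 1L || length(tad) != length(alts) + 1L)
      stop("VCF format error: AD field length mismatch at record ", i)
    out[[i]] <- data.frame(
      patient_id = patient_id, chrom = unname(fix[i, "CHROM"]),
      pos = as.integer(fix[i, "POS"]), ref = unname(fix[i, "REF"]),
      alt = alts, normal_ref = nad[1L], normal_alt = nad[-1L],
      tumor_ref = tad[1L], tumor_alt = tad[-1L], row.names = NULL)
  }
  do.call(rbind, out)
}

#' Write a variant candidate table (canonical TSV dialect)
#' @param candidates Data frame of variant candidates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(candidates, path) {
  write.table(candidates[, .variant_cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with its sample-trait file
#'
#' The matrix is a TSV whose first column holds gene identifiers and whose
#' header row holds sample identifiers. The companion trait file is a
#' two-column TSV (`sample`, `type`) with type `normal` or `tumor`.
#'
#' @param path Matrix TSV path.
#' @param trait_path Trait TSV path.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, trait_path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene ID in expression matrix: ",
         genes[duplicated(genes)][1L])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- genes
  tr <- read.table(trait_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("sample", "type") %in% names(tr)))
    stop("trait file must have columns 'sample' and 'type'")
  idx <- match(colnames(m), tr$sample)
  if (anyNA(idx))
    stop("samples missing from trait file: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  type <- tr$type[idx]
  if (!all(type %in% c("normal", "tumor")))
    stop("trait 'type' must be 'normal' or 'tumor'")
  expression_dataset(m, trait = as.integer(type == "tumor"))
}

#' Write an expression dataset as matrix + trait TSVs
#' @param expr An [expression_dataset()].
#' @param path Matrix TSV path.
#' @param trait_path Trait TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, trait_path) {
  # %.17g keeps doubles bit-exact through the text round-trip
  vals <- matrix(sprintf("%.17g", expr$matrix), nrow = nrow(expr$matrix))
  tab <- data.frame(gene = rownames(expr$matrix), vals, check.names = FALSE)
  names(tab)[-1L] <- colnames(expr$matrix)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- data.frame(sample = colnames(expr$matrix),
                   type = ifelse(expr$trait == 1L, "tumor", "normal"))
  write.table(tr, trait_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a sub-network edge list for Cytoscape
#'
#' SIF lines read `geneA tom geneB`; the TSV format adds the topological
#' overlap weight with six decimals. Each undirected edge is written once,
#' lexicographically smaller node first. An empty network yields an empty
#' SIF file, or a header-only TSV.
#'
#' @param net A `"subnetwork"` (see [build_subnetwork()]).
#' @param path Output path.
#' @param format `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "subnetwork"))
  e <- net$edges
  a <- pmin(e$gene_a, e$gene_b)
  b <- pmax(e$gene_a, e$gene_b)
  o <- order(a, b)
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(a[o], "tom", b[o]) else character(0), path)
  } else {
    lines <- c("gene_a\ttom\tgene_b\tweight",
               if (nrow(e)) sprintf("%s\ttom\t%s\t%.6f", a[o], b[o], e$tom[o]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read/write GMT-style term-to-gene files
#'
#' Each GMT line is `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path File path.
#' @return `read_gmt`: named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 fields")
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, character(1), 1L))
}

#' @param term_to_genes Named list of gene vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(term_to_genes, path) {
  writeLines(vapply(names(term_to_genes), function(t) {
    paste(c(t, "na", term_to_genes[[t]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read/write the GO parent-relation table
#'
#' A two-column TSV (`child`, `parent`) listing direct is_a-style edges.
#'
#' @param path File path.
#' @return `read_go_parents`: named list mapping child term to its direct
#'   parents.
#' @export
read_go_parents <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(tab)))
    stop("parent table must have columns 'child' and 'parent'")
  split(tab$parent, tab$child)
}

#' @param parent_of Named list mapping child term to parent terms.
#' @rdname read_go_parents
#' @export
write_go_parents <- function(parent_of, path) {
  ch <- rep(names(parent_of), lengths(parent_of))
  tab <- data.frame(child = ch, parent = unlist(parent_of, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a two-hit report as JSON
#' @param report A `"two_hit_report"` (see [vaf_ordering_test()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_two_hit_report <- function(report, path) {
  stopifnot(inherits(report, "two_hit_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
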