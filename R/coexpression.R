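#' Expression dataset container
#'
#' A genes x samples expression matrix with a binary per-sample trait
#' (normal = 0, tumor = 1). Zero-variance genes cannot enter a
#' correlation network and are removed with a warning; at least four
#' samples with both classes are sensible for module-trait work, and fewer
#' than four samples is an error.
#'
#' @param matrix Numeric genes x samples matrix with row and column names.
#' @param trait Integer/logical vector, one per sample: 0 normal, 1 tumor.
#' @return List of class `"expression_dataset"` with elements `matrix`,
#'   `gene_ids`, `sample_ids`, `trait`.
#' @export
expression_dataset <- function(matrix, trait) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(m))) stop("duplicated gene IDs")
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (ncol(m) < 4L) stop("at least 4 samples are required")
  trait <- as.integer(trait)
  if (length(trait) != ncol(m))
    stop("trait length must equal the number of samples")
  if (!all(trait %in% c(0L, 1L))) stop("trait must be binary (0/1)")
  v <- apply(m, 1L, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance genes removed")
    m <- m[v > 0, , drop = FALSE]
  }
  structure(list(matrix = m, gene_ids = rownames(m),
                 sample_ids = colnames(m), trait = trait),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d samples (%d normal, %d tumor)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$trait == 0L),
              sum(x$trait == 1L)))
  invisible(x)
}

.expr_matrix <- function(expr) {
  if (inherits(expr, "expression_dataset")) expr$matrix else as.matrix(expr)
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with the diagonal set to zero, so that the
#' connectivity `k_i = sum_j a_ij` excludes self-adjacency.
#'
#' @param expr An [expression_dataset()] or genes x samples matrix.
#' @param power Soft-threshold power `beta >= 1`.
#' @return Symmetric adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
adjacency_matrix <- function(expr, power = 12L) {
  m <- .expr_matrix(expr)
  if (power < 1) stop("power must be >= 1")
  if (ncol(m) < 4L) stop("at least 4 samples are required")
  if (any(apply(m, 1L, var) == 0))
    stop("zero-variance genes must be filtered before adjacency")
  a <- abs(cor(t(m)))^power
  diag(a) <- 0
  a
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power the gene connectivities `k_i` are binned
#' (equal-width bins over the k range) and the scale-free fit index is the
#' squared correlation between `log10` bin frequency and `log10` mean bin
#' connectivity, reported with a negative sign when the log-log slope is
#' positive (the signed-R^2 convention). The chosen power is the smallest
#' whose signed fit reaches `r2_cut`, falling back to the power with the
#' maximum signed fit when none does.
#'
#' @param expr An [expression_dataset()] or genes x samples matrix.
#' @param powers Candidate powers.
#' @param n_bins Number of connectivity bins.
#' @param r2_cut Signed-R^2 threshold (default 0.85).
#' @return List with `power` (chosen) and `fit_table` (data frame: power,
#'   signed R^2, slope, mean/median/max connectivity). Powers with too few
#'   occupied bins to fit are reported as `NA` and never chosen.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, n_bins = 10L,
                                r2_cut = 0.85) {
  if (!length(powers)) stop("'powers' must be non-empty")
  m <- .expr_matrix(expr)
  absr <- abs(cor(t(m)))
  diag(absr) <- 0
  rows <- lapply(powers, function(b) {
    k <- colSums(absr^b)
    fit <- .scale_free_fit(k, n_bins)
    data.frame(power = b, sft_r2 = fit$r2, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$sft_r2)
  if (!any(ok)) stop("scale-free fit undefined for every candidate power")
  hit <- which(ok & tab$sft_r2 >= r2_cut)
  chosen <- if (length(hit)) tab$power[hit[1L]]
            else tab$power[ok][which.max(tab$sft_r2[ok])]
  list(power = as.integer(chosen), fit_table = tab)
}

.scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L) return(list(r2 = NA_real_, slope = NA_real_))
  bins <- cut(k, n_bins)
  freq <- tapply(k, bins, length)
  meank <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(list(r2 = NA_real_, slope = NA_real_))
  x <- log10(meank[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2L])
  list(r2 = -sign(slope) * r2, slope = slope)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `L_ij = sum_u a_iu a_uj` counts shared-neighbour strength and
#' `k_i` is the connectivity; `TOM_ii = 1`. The denominator is at least
#' `1 - a_ij` plus the smaller connectivity, which is positive since
#' `a_ij <= min(k_i, k_j)`.
#'
#' @param a Symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return TOM matrix, symmetric in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  l <- a %*% a
  tom <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

#' Module detection by average-linkage clustering of 1 - TOM
#'
#' Genes are clustered by average-linkage hierarchical clustering of the
#' dissimilarity `1 - TOM` and the tree is cut at a fixed height. Clusters
#' below `min_module_size` are relabelled `"grey"` (unassigned); surviving
#' modules are named by decreasing size after the conventional palette
#' (turquoise, blue, brown, ...).
#'
#' @param tom TOM matrix with gene dimnames.
#' @param cut_height Static cut height on the dendrogram (default 0.4).
#' @param min_module_size Smallest retained module (default 30).
#' @return Named character vector: gene -> module label.
#' @export
detect_modules <- function(tom, cut_height = 0.4, min_module_size = 30L) {
  genes <- rownames(tom)
  if (is.null(genes)) stop("TOM needs gene dimnames")
  d <- 1 - tom
  diag(d) <- 0
  tree <- hclust(stats::as.dist(d), method = "average")
  # average-linkage heights can lose strict monotonicity to rounding on
  # tied dissimilarities; cutree insists on a sorted height vector
  tree$height <- round(tree$height, 12L)
  raw <- cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  if (!length(keep)) {
    warning("no cluster reached min_module_size; all genes grey")
    return(labels)
  }
  ord <- keep[order(-sizes[keep], as.integer(keep))]
  for (i in seq_along(ord))
    labels[raw == as.integer(ord[i])] <- .module_palette(i)
  labels
}

.module_palette <- function(i) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan")
  if (i <= length(pal)) pal[i] else sprintf("module%02d", i)
}

.standardize_genes <- function(m) {
  t(scale(t(m)))
}

#' Module eigengene
#'
#' The first right-singular direction of the gene-standardised module
#' submatrix, scaled to unit variance across samples, with the sign fixed
#' so the eigengene correlates non-negatively with the module's mean
#' standardised expression.
#'
#' @param expr An [expression_dataset()] or genes x samples matrix.
#' @param module_genes Gene identifiers of the module (non-empty).
#' @return Numeric per-sample vector with unit variance.
#' @export
module_eigengene <- function(expr, module_genes) {
  m <- .expr_matrix(expr)
  if (!length(module_genes)) stop("module is empty")
  miss <- setdiff(module_genes, rownames(m))
  if (length(miss)) stop("genes not in expression data: ",
                         paste(utils::head(miss, 3L), collapse = ", "))
  x <- .standardize_genes(m[module_genes, , drop = FALSE])
  if (ncol(x) < 2L) stop("eigengene undefined for single-sample data")
  sv <- svd(x, nu = 0L, nv = 1L)
  me <- sv$v[, 1L]
  avg <- colMeans(x)
  if (sum(me * avg) < 0) me <- -me
  me <- me / sd(me)
  names(me) <- colnames(m)
  me
}

#' Eigengenes for every (non-grey) module
#' @param expr An [expression_dataset()] or matrix.
#' @param module_of Named gene -> module label vector.
#' @return Samples x modules matrix of unit-variance eigengenes.
#' @export
module_eigengenes <- function(expr, module_of) {
  mods <- setdiff(sort(unique(module_of)), "grey")
  if (!length(mods)) stop("no modules to summarise")
  sapply(mods, function(mod)
    module_eigengene(expr, names(module_of)[module_of == mod]))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Student-t transform: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of paired observations (>= 4 for a stable test here).
#' @return Two-sided p-value(s); \code{p = 1} at \code{r = 0}.
#' @examples
#' correlation_pvalue(0.93, 6)  # ~0.007
#' correlation_pvalue(0.85, 6)  # ~0.03
#' @export
correlation_pvalue <- function(r, n) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  if (n < 3L) stop("n must be >= 3")
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  pmin(2 * pt(-abs(tval), df = n - 2), 1)
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and the binary sample
#' trait, with the two-sided Student-t p-value.
#'
#' @param me Samples x modules eigengene matrix (or one vector).
#' @param trait Binary per-sample trait (both classes present).
#' @return Data frame with columns \code{module}, \code{r}, \code{p}.
#' @export
module_trait_correlation <- function(me, trait) {
  if (length(unique(trait)) < 2L) stop("trait is constant")
  me <- as.matrix(me)
  n <- nrow(me)
  if (n < 4L) stop("at least 4 samples are required")
  if (length(trait) != n) stop("trait length must match samples")
  r <- as.numeric(cor(me, trait))
  data.frame(module = colnames(me) %||% "ME", r = r,
             p = correlation_pvalue(r, n), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Module-membership (kME) table
#'
#' `kME_gm = cor(x_g, ME_m)`, the signed correlation of each gene with each
#' module eigengene; the hub of a module is the member gene with the
#' largest `|kME|` in its own module.
#'
#' @param expr An [expression_dataset()] or matrix.
#' @param me Samples x modules eigengene matrix.
#' @return Genes x modules matrix of signed correlations.
#' @export
kme_table <- function(expr, me) {
  m <- .expr_matrix(expr)
  cor(t(m), as.matrix(me))
}

#' Hub gene per module from a kME table
#' @param kme Genes x modules kME matrix.
#' @param module_of Named gene -> module assignment.
#' @return Named character vector: module -> hub gene.
#' @export
module_hubs <- function(kme, module_of) {
  mods <- intersect(colnames(kme), unique(module_of))
  vapply(mods, function(mod) {
    members <- intersect(names(module_of)[module_of == mod], rownames(kme))
    members[which.max(abs(kme[members, mod]))]
  }, character(1))
}
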