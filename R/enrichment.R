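#' GO structure container
#'
#' Holds a term-to-gene annotation and an is_a-style parent relation. The
#' parent relation must be acyclic; ancestors are derived transitively.
#'
#' @param term_to_genes Named list: term -> character vector of genes.
#' @param parent_of Named list: child term -> character vector of direct
#'   parent terms. Terms absent from the list have no recorded parents.
#' @return List of class `"go_structure"`.
#' @export
go_structure <- function(term_to_genes, parent_of = list()) {
  stopifnot(is.list(term_to_genes), !is.null(names(term_to_genes)))
  term_to_genes <- lapply(term_to_genes, unique)
  for (term in names(parent_of)) {
    anc <- go_ancestors(parent_of, term)
    if (term %in% anc)
      stop("cycle in parent relation involving term '", term, "'")
  }
  structure(list(term_to_genes = term_to_genes, parent_of = parent_of),
            class = "go_structure")
}

#' Transitive ancestors of a term
#'
#' Breadth-first closure over the direct-parent relation. A term that is
#' reachable from itself (a cycle) appears in its own ancestor set, which
#' [go_structure()] rejects.
#'
#' @param parent_of Named list of direct parents (or a `"go_structure"`).
#' @param term Term identifier.
#' @return Character vector of all (transitive) ancestor terms.
#' @export
go_ancestors <- function(parent_of, term) {
  if (inherits(parent_of, "go_structure")) parent_of <- parent_of$parent_of
  anc <- character(0)
  frontier <- term
  repeat {
    nxt <- setdiff(unique(unlist(parent_of[frontier], use.names = FALSE)),
                   anc)
    if (!length(nxt)) return(anc)
    anc <- c(anc, nxt)
    frontier <- nxt
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with the usual monotonicity
#' enforcement and capping at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric GO over-representation test
#'
#' For each annotated term with at least `go_min_genes` genes (after
#' intersection with the universe), computes the upper-tail hypergeometric
#' p-value `P(X >= k)` of observing `k` query genes in a term of size `K`
#' when `n` query genes are drawn from a universe of `N`, adjusts across
#' tested terms by Benjamini-Hochberg, and flags the non-redundant
#' significant terms (no kept term is an ancestor of another significant
#' term).
#'
#' @param query Character vector of genes of interest; intersected with the
#'   universe before testing.
#' @param structure A [go_structure()].
#' @param cfg A [pipeline_config()].
#' @param universe Background gene set; defaults to all annotated genes.
#' @param transitive Treat "parent" transitively (ancestors) in the
#'   redundancy filter; `FALSE` restricts to direct parents.
#' @return Data frame of class `"enrichment_result"` sorted by adjusted p:
#'   `term`, `overlap`, `query_size`, `term_size`, `universe_size`, `p`,
#'   `p_adjust`, `significant`, `kept_nonredundant`.
#' @export
hypergeom_enrich <- function(query, structure, cfg = pipeline_config(),
                             universe = NULL, transitive = TRUE) {
  stopifnot(inherits(structure, "go_structure"))
  if (is.null(universe))
    universe <- unique(unlist(structure$term_to_genes, use.names = FALSE))
  universe <- unique(universe)
  terms <- lapply(structure$term_to_genes, intersect, universe)
  terms <- terms[lengths(terms) >= cfg$go_min_genes]
  q <- intersect(unique(query), universe)
  if (!length(q) || !length(terms)) {
    warning("empty query after intersecting with the annotated universe")
    out <- data.frame(term = character(0), overlap = integer(0),
                      query_size = integer(0), term_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      p_adjust = numeric(0), significant = logical(0),
                      kept_nonredundant = logical(0))
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  n <- length(q)
  N <- length(universe)
  K <- lengths(terms)
  k <- vapply(terms, function(g) length(intersect(g, q)), integer(1))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(terms), overlap = k, query_size = n,
                    term_size = unname(K), universe_size = N, p = unname(p),
                    p_adjust = bh_adjust(unname(p)), row.names = NULL)
  out$significant <- out$p_adjust <= cfg$go_fdr_max
  out <- nonredundant_filter(out, structure, transitive = transitive)
  out <- out[order(out$p_adjust, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Parent-term redundancy filter
#'
#' Among significant terms, drops every term that is an ancestor
#' (transitive parent by default) of another significant term, so no kept
#' pathway subsumes another.
#'
#' @param rows Enrichment table with columns `term` and `significant`.
#' @param structure A [go_structure()] (or a direct-parent list).
#' @param transitive Use transitive ancestors (default) or direct parents.
#' @return `rows` with a logical `kept_nonredundant` column (FALSE for
#'   non-significant rows).
#' @export
nonredundant_filter <- function(rows, structure, transitive = TRUE) {
  parent_of <- if (inherits(structure, "go_structure"))
    structure$parent_of else structure
  sig <- rows$term[rows$significant]
  drop <- character(0)
  for (term in sig) {
    anc <- if (transitive) go_ancestors(parent_of, term)
           else unlist(parent_of[term], use.names = FALSE)
    drop <- union(drop, intersect(anc, sig))
  }
  rows$kept_nonredundant <- rows$significant & !(rows$term %in% drop)
  rows
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GO over-representation: %d terms tested, %d significant, %d kept non-redundant\n",
              nrow(x), sum(x$significant), sum(x$kept_nonredundant)))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x), 10L)
    show$p <- signif(show$p, 3)
    show$p_adjust <- signif(show$p_adjust, 3)
    print(show, row.names = FALSE)
  }
  invisible(x)
}
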