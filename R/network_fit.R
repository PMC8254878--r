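#' Fit a weighted gene co-expression network
#'
#' The package's central fit: unsigned soft-threshold adjacency,
#' topological overlap, average-linkage module detection at a fixed cut
#' height, module eigengenes, module-trait correlation and kME. The power
#' is either fixed (default 12) or chosen by the scale-free criterion when
#' `power = "auto"`.
#'
#' @param expr An [expression_dataset()].
#' @param power Integer soft-threshold power, or `"auto"` to select via
#'   [pick_soft_threshold()].
#' @param cfg A [pipeline_config()]; supplies `cut_height`,
#'   `min_module_size` and the default power.
#' @param keep_adjacency Keep the adjacency matrix in the fit (the TOM is
#'   always kept).
#' @return Object of class `"coexpression_network"` with elements `power`,
#'   `fit_table` (when auto-selected), `tom`, `module_of`, `me`
#'   (samples x modules eigengenes), `kme`, `module_trait`, `hubs`,
#'   `trait`, `gene_ids`, `sample_ids` and optionally `adjacency`.
#' @examples
#' plan <- simulation_plan(seed = 3)
#' expr <- simulate_expression(plan)$expr
#' net <- fit_coexpression_network(expr)
#' net
#' @export
fit_coexpression_network <- function(expr, power = NULL,
                                     cfg = pipeline_config(),
                                     keep_adjacency = FALSE) {
  stopifnot(inherits(expr, "expression_dataset"))
  fit_table <- NULL
  if (identical(power, "auto")) {
    sft <- pick_soft_threshold(expr)
    power <- sft$power
    fit_table <- sft$fit_table
  } else if (is.null(power)) {
    power <- cfg$soft_power
  }
  a <- adjacency_matrix(expr, power = power)
  tom <- topological_overlap(a)
  module_of <- detect_modules(tom, cut_height = cfg$cut_height,
                              min_module_size = cfg$min_module_size)
  mods <- setdiff(unique(module_of), "grey")
  if (length(mods)) {
    me <- module_eigengenes(expr, module_of)
    mt <- module_trait_correlation(me, expr$trait)
    kme <- kme_table(expr, me)
    hubs <- module_hubs(kme, module_of)
  } else {
    me <- NULL; mt <- NULL; kme <- NULL; hubs <- NULL
  }
  out <- list(power = as.integer(power), fit_table = fit_table, tom = tom,
              module_of = module_of, me = me, kme = kme, module_trait = mt,
              hubs = hubs, trait = expr$trait, gene_ids = expr$gene_ids,
              sample_ids = expr$sample_ids, cfg = cfg)
  if (keep_adjacency) out$adjacency <- a
  structure(out, class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  sizes <- sort(table(x$module_of[x$module_of != "grey"]), decreasing = TRUE)
  cat(sprintf("Co-expression network: %d genes, power %d, %d modules (%d grey)\n",
              length(x$module_of), x$power, length(sizes),
              sum(x$module_of == "grey")))
  if (length(sizes)) {
    for (m in names(sizes)) {
      mt <- x$module_trait[x$module_trait$module == m, ]
      cat(sprintf("  %-12s %4d genes  trait r = %+.2f (p = %.3g)  hub %s\n",
                  m, sizes[[m]], mt$r, mt$p, x$hubs[[m]]))
    }
  }
  invisible(x)
}

#' @export
summary.coexpression_network <- function(object, ...) {
  print(object)
  if (!is.null(object$fit_table)) {
    cat("\nScale-free fit by power:\n")
    print(object$fit_table, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Dendrogram plot of a fitted network
#'
#' Plots the average-linkage gene dendrogram of `1 - TOM` with the cut
#' height and a module colour bar underneath.
#'
#' @param x A `"coexpression_network"`.
#' @param ... Passed to [plot.hclust()].
#' @return `x`, invisibly.
#' @export
plot.coexpression_network <- function(x, ...) {
  d <- 1 - x$tom
  diag(d) <- 0
  tree <- hclust(stats::as.dist(d), method = "average")
  graphics::plot(tree, labels = FALSE, hang = -1,
                 main = "Gene dendrogram (1 - TOM)", xlab = "", sub = "", ...)
  graphics::abline(h = x$cfg$cut_height, col = "red", lty = 2)
  cols <- x$module_of[tree$order]
  cols[!cols %in% grDevices::colors()] <- "grey"
  graphics::points(seq_along(cols), rep(graphics::par("usr")[3], length(cols)),
                   col = cols, pch = 15, xpd = NA)
  invisible(x)
}

#' Module with the strongest trait association
#' @param net A `"coexpression_network"`.
#' @return Module label with maximal `|r|` against the trait.
#' @export
anchor_module <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  if (is.null(net$module_trait)) stop("network has no modules")
  mt <- net$module_trait
  mt$module[which.max(abs(mt$r))]
}
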