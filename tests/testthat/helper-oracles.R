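# Independent oracles used to check the package's statistical core.

# One-sided Fisher p by exhaustive enumeration over all 2x2 tables with the
# observed margins, summing conditional probabilities computed from first
# principles with choose().
oracle_fisher_greater <- function(nr, na, tr, ta) {
  n1 <- nr + na
  n2 <- tr + ta
  m <- na + ta
  js <- max(0L, m - n1):min(m, n2)
  probs <- choose(n2, js) * choose(n1, m - js) / choose(n1 + n2, m)
  sum(probs[js >= ta])
}

# Topological overlap by the defining triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Upper-tail hypergeometric P(X >= k) by direct combinatorial summation.
oracle_hyper_upper <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js) / choose(N, n))
}

# First principal component of the gene-standardised module submatrix via
# an eigendecomposition of the sample covariance (independent of svd()).
oracle_pc1 <- function(x_std) {
  cv <- crossprod(x_std) / nrow(x_std)
  eigen(cv, symmetric = TRUE)$vectors[, 1L]
}

# Two-sided correlation p via numerical integration of the t density.
oracle_cor_p <- function(r, n) {
  tval <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::integrate(function(x) stats::dt(x, df = n - 2),
                       lower = tval, upper = Inf,
                       rel.tol = 1e-12)$value
}

# Small helper to assemble candidate rows in the canonical column order.
make_candidates <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], chrom = r[[2]], pos = as.integer(r[[3]]),
               ref = r[[4]], alt = r[[5]],
               normal_ref = as.integer(r[[6]]), normal_alt = as.integer(r[[7]]),
               tumor_ref = as.integer(r[[8]]), tumor_alt = as.integer(r[[9]]))
  }))
}

# Annotation row with benign defaults; override fields by name.
make_annotation <- function(chrom, pos, ref, alt, gene,
                            consequence = "missense",
                            freqs = rep(NA_real_, 4),
                            cadd = NA_real_, sift = NA, poly = NA) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, consequence = consequence,
             freq_1kg_eas = freqs[1], freq_exac_eas = freqs[2],
             freq_gnomad_genome_eas = freqs[3],
             freq_gnomad_exome_eas = freqs[4],
             cadd_phred = cadd, sift_damaging = sift,
             polyphen_damaging = poly)
}
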