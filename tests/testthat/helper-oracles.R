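# Independent oracles used across tests.

# Inverse standard-normal CDF by bisection on pnorm; independent of qnorm.
bisect_quantile <- function(p, lower = -10, upper = 10, tol = 1e-9) {
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (stats::pnorm(mid) < p) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# n-subsets of an N-element background with K marked elements.
enum_fisher_p <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# Small deterministic evidence table built by hand.
make_evidence <- function(proteins, hl_pairs, replicate = "rep1") {
  do.call(rbind, lapply(seq_along(proteins), function(i) {
    p <- hl_pairs[[i]]
    data.frame(
      peptide = sprintf("PEP%d_%d", i, seq_len(nrow(p))),
      protein_id = proteins[i],
      charge = 2L,
      intensity_H = p[, 1],
      intensity_L = p[, 2],
      replicate = replicate,
      stringsAsFactors = FALSE
    )
  }))
}

# Quantify-and-merge shortcut for synthetic datasets.
merged_quant <- function(dataset, min_ratio_count = 2) {
  merge_replicates(
    quantify_experiment(dataset$evidence[[1]], min_ratio_count),
    quantify_experiment(dataset$evidence[[2]], min_ratio_count)
  )$quant
}
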