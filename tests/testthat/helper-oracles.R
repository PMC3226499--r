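# Independent brute-force references used to check the package's
# vectorized implementations on small random inputs.

# Recompute one (chemical, pathway) perturbation score by explicit loops.
naive_pathway_score <- function(m, ann, genes, chem, min_targets) {
  genes <- tolower(genes)
  hits <- c(); active_genes <- c()
  for (j in seq_len(ncol(m))) {
    g <- tolower(ann$gene_symbol[match(colnames(m)[j], ann$assay_id)])
    if (!is.na(g) && g %in% genes) {
      v <- unclass(m)[chem, j]
      if (v < inactive_sentinel()) {
        hits <- c(hits, v)
        active_genes <- c(active_genes, g)
      }
    }
  }
  n <- length(unique(active_genes))
  list(n = n, score = if (n >= min_targets) min(hits) else NA_real_)
}

# Pair-counting AUC with ties credited one half.
naive_auc <- function(s, y) {
  pairs <- 0; wins <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    pairs <- pairs + 1
    wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  wins / pairs
}
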