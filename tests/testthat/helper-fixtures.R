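# Shared fixture builders and independent oracles.

# Proportions concentrated on one category (or the null experiment).
only_category <- function(category) {
  p <- setNames(rep(0, length(REGULATION_CATEGORIES)), REGULATION_CATEGORIES)
  p[category] <- 1
  p
}

null_config <- function(n_genes, dispersion = 0.05, seed = 1, ...) {
  sim_config(n_genes = n_genes, dispersion = dispersion, seed = seed,
             category_proportions = only_category("unregulated"), ...)
}

# A small two-condition, two-assay count matrix with explicit per-cell
# means (genes x 4 cells: rna_A, rna_B, ribo_A, ribo_B), Poisson-free.
deterministic_counts <- function(means, n_replicates = 2,
                                 conditions = c("A", "B")) {
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         assay = c("rna", "ribo"), condition = conditions,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_%d", samples$condition, samples$assay,
                               samples$replicate)
  samples <- samples[, c("sample_id", "assay", "condition", "replicate")]
  cols <- paste(samples$assay, samples$condition, sep = "_")
  counts <- means[, cols, drop = FALSE]
  colnames(counts) <- samples$sample_id
  storage.mode(counts) <- "integer"
  list(counts = counts, samples = samples)
}

# Brute-force one-sided hypergeometric tail by explicit enumeration over
# all achievable overlap values (independent of phyper).
hyper_tail_oracle <- function(a, k, m, N) {
  hi <- min(k, m)
  i <- a:hi
  sum(choose(m, i) * choose(N - m, k - i)) / choose(N, k)
}

# One-row stats table for classifier unit tests.
stats_row <- function(lfc_rna = 0, fdr_rna = 1, lfc_ribo = 0, fdr_ribo = 1,
                      lfc_te = 0, fdr_te = 1, gene_id = "g1") {
  data.frame(gene_id = gene_id,
             log2fc_rna = lfc_rna, fdr_rna = fdr_rna,
             log2fc_ribo = lfc_ribo, fdr_ribo = fdr_ribo,
             log2fc_te = lfc_te, fdr_te = fdr_te,
             stringsAsFactors = FALSE)
}
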