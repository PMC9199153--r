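#' Per-gene translation efficiency in one condition
#'
#' TE is the ratio of ribosome-footprint abundance to mRNA abundance:
#' `(mean normalized ribo count + pseudocount) /
#'  (mean normalized rna count + pseudocount)`, replicate means taken after
#' size-factor normalization. The pseudocount (default 0.5 normalized
#' counts) keeps TE finite and positive for zero-count cells.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample sheet matching `counts`.
#' @param condition condition label; both assays must be present.
#' @param pseudocount non-negative pseudocount added to both means.
#' @param sf optional precomputed size factors.
#' @return Named numeric vector of per-gene TE values.
#' @export
compute_te <- function(counts, samples, condition, pseudocount = 0.5,
                       sf = NULL) {
  assert_count_matrix(counts, "te")
  samples <- assert_sample_sheet(samples, counts, "te")
  if (pseudocount < 0) stop_stage("te", "pseudocount must be non-negative")
  in_cond <- samples$condition == condition
  if (!any(in_cond)) stop_stage("te", paste("condition not found:", condition))
  for (a in c("ribo", "rna"))
    if (!any(in_cond & samples$assay == a))
      stop_stage("te", paste("assay", a, "missing in condition", condition))
  norm <- normalize_counts(counts, sf)
  ribo <- rowMeans(norm[, in_cond & samples$assay == "ribo", drop = FALSE])
  rna <- rowMeans(norm[, in_cond & samples$assay == "rna", drop = FALSE])
  te <- (ribo + pseudocount) / (rna + pseudocount)
  setNames(te, rownames(counts))
}

#' Flag extreme-TE genes
#'
#' Labels each gene `"high"` when `TE > hi`, `"low"` when `TE < lo`, and
#' `"neither"` otherwise (strict inequalities). The default cutoffs (3 and
#' 0.33) match the conventional extreme translation-efficiency flags.
#'
#' @param te positive per-gene TE values.
#' @param hi,lo high/low cutoffs.
#' @return Character vector in `{"high", "low", "neither"}`.
#' @export
flag_extreme_te <- function(te, hi = 3, lo = 0.33) {
  if (any(te <= 0, na.rm = TRUE)) stop_stage("te", "TE values must be positive")
  out <- rep("neither", length(te))
  out[te > hi] <- "high"
  out[te < lo] <- "low"
  names(out) <- names(te)
  out
}

#' Pearson correlation between RNA-seq and Ribo-seq abundance
#'
#' Correlation, across genes, of log-transformed (pseudocount-added) mean
#' normalized counts of the two assays within one condition. High values
#' indicate that footprint abundance tracks mRNA abundance; the correlation
#' typically drops when translational control strengthens.
#'
#' @inheritParams compute_te
#' @param pseudocount added before the log transform.
#' @return Single numeric correlation coefficient.
#' @export
cross_assay_correlation <- function(counts, samples, condition,
                                    pseudocount = 1, sf = NULL) {
  assert_count_matrix(counts, "te")
  samples <- assert_sample_sheet(samples, counts, "te")
  in_cond <- samples$condition == condition
  if (!any(in_cond)) stop_stage("te", paste("condition not found:", condition))
  norm <- normalize_counts(counts, sf)
  ribo <- rowMeans(norm[, in_cond & samples$assay == "ribo", drop = FALSE])
  rna <- rowMeans(norm[, in_cond & samples$assay == "rna", drop = FALSE])
  cor(log(rna + pseudocount), log(ribo + pseudocount), method = "pearson")
}
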