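#' Significance thresholds for the regulatory classification
#'
#' A contrast is called significant for a gene when
#' `|log2FC| > min_abs_log2fc` and `FDR < max_fdr` (strict inequalities).
#' The defaults encode the conventional twofold-change / FDR 0.01 rule,
#' applied uniformly to the mRNA, footprint and TE contrasts.
#'
#' @param min_abs_log2fc minimum absolute log2 fold change (1 = twofold).
#' @param max_fdr FDR ceiling in (0, 1].
#' @return An object of class `te_thresholds`.
#' @export
te_thresholds <- function(min_abs_log2fc = 1, max_fdr = 0.01) {
  if (min_abs_log2fc < 0) stop_stage("classify", "min_abs_log2fc must be >= 0")
  if (max_fdr <= 0 || max_fdr > 1)
    stop_stage("classify", "max_fdr must lie in (0, 1]")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_fdr = max_fdr),
            class = "te_thresholds")
}

is_sig <- function(log2fc, fdr, th) {
  !is.na(log2fc) & !is.na(fdr) &
    abs(log2fc) > th$min_abs_log2fc & fdr < th$max_fdr
}

#' Assign genes to the seven regulatory categories
#'
#' Decision tree over the three per-gene contrasts (mRNA, footprint, TE)
#' between two conditions, with `sig(x) = |log2FC_x| > threshold &
#' FDR_x < max_fdr`:
#'
#' * sig(TE), TE up: `translationally_induced` when the footprint change is
#'   also significantly up, else `rna_down_te_up` (buffering);
#' * sig(TE), TE down: `translationally_repressed` when footprints are
#'   significantly down, else `rna_up_te_down` (buffering);
#' * TE not significant: `up_te_constant` / `down_te_constant` when both
#'   mRNA and footprints change significantly in the same direction, else
#'   `unregulated`.
#'
#' Genes with missing statistics in any contrast are unclassifiable and get
#' `NA`; they are reported via the `n_unclassified` attribute.
#'
#' @param stats data.frame with columns `gene_id`, `log2fc_rna`, `fdr_rna`,
#'   `log2fc_ribo`, `fdr_ribo`, `log2fc_te`, `fdr_te`.
#' @param thresholds a [te_thresholds()].
#' @return `stats` with a `category` column appended (factor over
#'   [REGULATION_CATEGORIES]); attribute `n_unclassified` counts `NA` rows.
#' @export
classify_genes <- function(stats, thresholds = te_thresholds()) {
  need <- c("log2fc_rna", "fdr_rna", "log2fc_ribo", "fdr_ribo",
            "log2fc_te", "fdr_te")
  if (!all(need %in% names(stats)))
    stop_stage("classify", paste("stats needs columns:",
                                 paste(need, collapse = ", ")))
  th <- thresholds
  complete <- complete.cases(stats[, need])
  sig_rna <- is_sig(stats$log2fc_rna, stats$fdr_rna, th)
  sig_ribo <- is_sig(stats$log2fc_ribo, stats$fdr_ribo, th)
  sig_te <- is_sig(stats$log2fc_te, stats$fdr_te, th)

  cat <- rep(NA_character_, nrow(stats))
  te_up <- sig_te & stats$log2fc_te > 0
  te_dn <- sig_te & stats$log2fc_te < 0
  cat[complete] <- "unregulated"
  cat[complete & !sig_te & sig_rna & sig_ribo &
        stats$log2fc_rna > 0 & stats$log2fc_ribo > 0] <- "up_te_constant"
  cat[complete & !sig_te & sig_rna & sig_ribo &
        stats$log2fc_rna < 0 & stats$log2fc_ribo < 0] <- "down_te_constant"
  cat[complete & te_up] <- ifelse(
    (sig_ribo & stats$log2fc_ribo > 0)[complete & te_up],
    "translationally_induced", "rna_down_te_up")
  cat[complete & te_dn] <- ifelse(
    (sig_ribo & stats$log2fc_ribo < 0)[complete & te_dn],
    "translationally_repressed", "rna_up_te_down")

  stats$category <- factor(cat, levels = REGULATION_CATEGORIES)
  attr(stats, "n_unclassified") <- sum(!complete)
  stats
}

#' Category counts and the TE-significance partition
#'
#' Tabulates a classification into per-category counts plus the structural
#' aggregates: the two buffering classes and the two translation-driven
#' classes together make up the TE-significant total, and all seven classes
#' sum to the background size.
#'
#' @param classification output of [classify_genes()].
#' @return data.frame with `category` and `n`, including aggregate rows
#'   `te_changed` (buffered + translation-driven), `buffered`,
#'   `translation_driven`, `de_te_constant` and `background`.
#' @export
category_counts <- function(classification) {
  tab <- table(classification$category)
  n <- as.integer(tab[REGULATION_CATEGORIES])
  buffered <- sum(tab[c("rna_up_te_down", "rna_down_te_up")])
  driven <- sum(tab[c("translationally_induced", "translationally_repressed")])
  data.frame(
    category = c(REGULATION_CATEGORIES, "de_te_constant", "buffered",
                 "translation_driven", "te_changed", "background"),
    n = c(n, sum(tab[c("up_te_constant", "down_te_constant")]),
          buffered, driven, buffered + driven, sum(tab)),
    stringsAsFactors = FALSE
  )
}

#' Run all three contrasts and classify every gene
#'
#' Convenience wrapper: tests the mRNA shift, the footprint shift and the
#' TE shift for `cond_b` versus `cond_a`, merges the per-gene statistics and
#' applies [classify_genes()].
#'
#' @inheritParams test_te_shift
#' @param thresholds a [te_thresholds()].
#' @param ... passed to the shift tests (`variance`, `prior_df`, ...).
#' @return list with `stats` (classified per-gene table) and `counts`
#'   (the [category_counts()] summary).
#' @export
classify_all <- function(counts, samples, cond_a, cond_b,
                         thresholds = te_thresholds(), sf = NULL, ...) {
  sf <- sf %||% size_factors(counts)
  rna <- test_assay_shift(counts, samples, "rna", cond_a, cond_b, sf, ...)
  ribo <- test_assay_shift(counts, samples, "ribo", cond_a, cond_b, sf, ...)
  te <- test_te_shift(counts, samples, cond_a, cond_b, sf, ...)
  stats <- data.frame(
    gene_id = rna$gene_id,
    log2fc_rna = rna$log2fc, fdr_rna = rna$fdr, p_rna = rna$p,
    log2fc_ribo = ribo$log2fc, fdr_ribo = ribo$fdr, p_ribo = ribo$p,
    log2fc_te = te$log2fc, fdr_te = te$fdr, p_te = te$p,
    stringsAsFactors = FALSE
  )
  stats <- classify_genes(stats, thresholds)
  list(stats = stats, counts = category_counts(stats))
}
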