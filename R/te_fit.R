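#' Fit the translational-control model for one contrast
#'
#' One-call analysis of a paired Ribo-seq/RNA-seq experiment: filters the
#' expression background, computes median-of-ratios size factors, tests the
#' mRNA, footprint and TE shifts between the two contrast conditions with
#' the per-gene count model, computes per-condition TE and extreme-TE flags,
#' and classifies every background gene into the seven regulatory
#' categories.
#'
#' @param counts gene x sample raw count matrix.
#' @param samples sample sheet (`sample_id`, `assay`, `condition`,
#'   `replicate`).
#' @param contrast length-2 character: `c(cond_b, cond_a)` — fold changes
#'   are reported for the first element versus the second (e.g.
#'   `c("Neuron", "NPC")`).
#' @param thresholds a [te_thresholds()].
#' @param filter a [background_filter()].
#' @param pseudocount pseudocount for the per-condition TE values.
#' @param te_extreme length-2 numeric `c(hi, lo)` extreme-TE cutoffs.
#' @param variance,prior_df passed to the shift tests; see
#'   [test_assay_shift()].
#' @return An object of class `te_fit`: a list with `stats` (the classified
#'   per-gene table), `counts` (background raw counts), `norm` (normalized
#'   counts), `samples`, `sf`, `te` (gene x condition TE matrix),
#'   `te_flags`, `correlations` (per-condition cross-assay Pearson r),
#'   `category_counts`, `dispersion` (method-of-moments estimates),
#'   `contrast`, `thresholds`, `background_size`, `n_input_genes`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, seed = 3))
#' fit <- te_fit(sim$counts, sim$samples, contrast = c("Neuron", "NPC"))
#' fit
#' head(coef(fit))
#' @export
te_fit <- function(counts, samples, contrast, thresholds = te_thresholds(),
                   filter = background_filter(), pseudocount = 0.5,
                   te_extreme = c(3, 0.33), variance = "quasi",
                   prior_df = 4) {
  assert_count_matrix(counts, "fit")
  samples <- assert_sample_sheet(samples, counts, "fit")
  if (length(contrast) != 2 || !all(contrast %in% samples$condition))
    stop_stage("fit", "contrast must name two conditions in the sample sheet")
  cond_b <- contrast[1]; cond_a <- contrast[2]

  bg <- filter_background(counts, filter)
  if (nrow(bg) == 0) stop_stage("fit", "background is empty after filtering")
  sf <- size_factors(bg)
  norm <- normalize_counts(bg, sf)

  cls <- classify_all(bg, samples, cond_a, cond_b, thresholds, sf,
                      variance = variance, prior_df = prior_df)
  conditions <- unique(samples$condition)
  te <- vapply(conditions, function(cond)
    compute_te(bg, samples, cond, pseudocount, sf), numeric(nrow(bg)))
  correlations <- vapply(conditions, function(cond)
    cross_assay_correlation(bg, samples, cond, sf = sf), numeric(1))

  stats <- cls$stats
  stats$te_flag <- flag_extreme_te(te[, cond_b], te_extreme[1], te_extreme[2])
  for (cond in conditions) stats[[paste0("te_", cond)]] <- te[, cond]

  cells <- interaction(samples$assay, samples$condition, drop = TRUE)
  structure(list(
    stats = stats, counts = bg, norm = norm, samples = samples, sf = sf,
    te = te, correlations = correlations, category_counts = cls$counts,
    dispersion = estimate_dispersion(bg, cells, sf), cells = cells,
    contrast = c(cond_b = cond_b, cond_a = cond_a), thresholds = thresholds,
    pseudocount = pseudocount, background_size = nrow(bg),
    n_input_genes = nrow(counts)
  ), class = "te_fit")
}

#' @export
print.te_fit <- function(x, ...) {
  cat(sprintf("Translational-control fit: %s vs %s\n",
              x$contrast["cond_b"], x$contrast["cond_a"]))
  cat(sprintf("  background: %d of %d genes (%d samples)\n",
              x$background_size, x$n_input_genes, ncol(x$counts)))
  cc <- x$category_counts
  n_of <- function(k) cc$n[cc$category == k]
  cat(sprintf("  DE, TE constant: %d | TE changed: %d (buffered %d, translation-driven %d)\n",
              n_of("de_te_constant"), n_of("te_changed"), n_of("buffered"),
              n_of("translation_driven")))
  cat(sprintf("  thresholds: |log2FC| > %g, FDR < %g\n",
              x$thresholds$min_abs_log2fc, x$thresholds$max_fdr))
  invisible(x)
}

#' @export
summary.te_fit <- function(object, ...) {
  structure(list(
    contrast = object$contrast,
    background_size = object$background_size,
    n_input_genes = object$n_input_genes,
    category_counts = object$category_counts,
    correlations = object$correlations,
    te_flag_counts = table(object$stats$te_flag),
    thresholds = object$thresholds
  ), class = "summary.te_fit")
}

#' @export
print.summary.te_fit <- function(x, ...) {
  cat(sprintf("Translational-control analysis, %s vs %s\n",
              x$contrast["cond_b"], x$contrast["cond_a"]))
  cat(sprintf("Background: %d genes (of %d input)\n\n",
              x$background_size, x$n_input_genes))
  cat("Category counts:\n")
  print(x$category_counts, row.names = FALSE)
  cat("\nCross-assay Pearson correlation (log scale):\n")
  print(round(x$correlations, 3))
  cat(sprintf("\nExtreme TE in %s: high %d, low %d\n", x$contrast["cond_b"],
              x$te_flag_counts[["high"]] %||% 0L,
              x$te_flag_counts[["low"]] %||% 0L))
  invisible(x)
}

#' @export
coef.te_fit <- function(object, ...) {
  m <- as.matrix(object$stats[, c("log2fc_rna", "log2fc_ribo", "log2fc_te")])
  rownames(m) <- object$stats$gene_id
  m
}

#' @export
fitted.te_fit <- function(object, ...) {
  mo <- cell_moments(object$norm, object$cells)
  mu <- mo$means[, as.character(object$cells), drop = FALSE]
  colnames(mu) <- colnames(object$norm)
  mu
}

#' Pearson residuals of the fitted count model
#'
#' `(normalized count - cell mean) / sqrt(mean + alpha * mean^2)` with the
#' gene's method-of-moments dispersion.
#'
#' @param object a [te_fit()] object.
#' @param ... unused.
#' @return Matrix of residuals, genes x samples.
#' @export
residuals.te_fit <- function(object, ...) {
  mu <- fitted(object)
  v <- mu + object$dispersion * mu^2
  (object$norm - mu) / sqrt(pmax(v, .Machine$double.eps))
}

#' Parametric-bootstrap count matrices from a fitted model
#'
#' Draws negative-binomial counts from the fitted per-cell means (scaled by
#' the size factors) and the per-gene dispersion estimates.
#'
#' @param object a [te_fit()] object.
#' @param nsim number of simulated matrices.
#' @param seed integer seed or `NULL`.
#' @param ... unused.
#' @return List of `nsim` integer count matrices shaped like the background.
#' @export
simulate.te_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- sweep(fitted(object), 2, object$sf, "*")
  alpha <- pmax(object$dispersion, 1e-8)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    m <- matrix(
      as.integer(rnbinom(length(mu), mu = as.vector(mu),
                         size = rep(1 / alpha, ncol(mu)))),
      nrow(mu), ncol(mu), dimnames = dimnames(object$norm))
    m
  }))
}

#' Fold-change-plane plot of the classification
#'
#' Scatter of footprint versus mRNA log2 fold changes, colored by
#' regulatory category — genes on the diagonal change concordantly in both
#' assays (TE constant); vertical/horizontal departures mark
#' translation-driven and buffered genes.
#'
#' @param x a [te_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.te_fit <- function(x, ...) {
  s <- x$stats
  pal <- setNames(
    c("#1f78b4", "#e31a1c", "#08306b", "#67000d", "#000000", "#33a02c",
      "grey75"),
    REGULATION_CATEGORIES)
  ord <- order(s$category == "unregulated", decreasing = TRUE)
  plot(s$log2fc_rna[ord], s$log2fc_ribo[ord],
       col = pal[as.character(s$category[ord])], pch = 16, cex = 0.5,
       xlab = sprintf("log2FC mRNA (%s vs %s)", x$contrast[1], x$contrast[2]),
       ylab = "log2FC footprints", ...)
  abline(0, 1, lty = 2, col = "grey50")
  legend("topleft", legend = names(pal), col = pal, pch = 16, cex = 0.7,
         bty = "n")
  invisible(x)
}
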