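#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values, monotone in the p-value ordering and clipped to
#' `[0, 1]`. `NA` entries (untested genes) stay `NA` and do not count toward
#' the number of tests.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop_stage("difftest", "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Negative-binomial GLM fit by iteratively reweighted least squares
#'
#' Log-link NB regression with fixed dispersion `alpha`
#' (`variance = mu + alpha * mu^2`): weights `mu / (1 + alpha * mu)`,
#' working response on the linear-predictor scale, convergence on the
#' maximum absolute coefficient change. For a design whose columns span
#' group indicators (the saturated designs used by the shift tests) the
#' fixed point is the log of the group means, for any `alpha`.
#'
#' @param y non-negative response vector (counts, possibly normalized).
#' @param X design matrix (full column rank).
#' @param alpha NB dispersion (0 = Poisson).
#' @param offset optional offset on the log scale.
#' @param max_iter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return list with `coefficients`, `fitted`, `cov` (inverse Fisher
#'   information), `converged`, `iterations`.
#' @export
nb_irls <- function(y, X, alpha = 0, offset = 0, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop_stage("difftest", "design matrix is rank-deficient")
  offset <- rep_len(offset, length(y))
  eta <- log(pmax(y, 0.5)) - offset
  beta <- qr.solve(X, eta)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    new_beta <- solve(XtW %*% X, XtW %*% z)
    delta <- max(abs(new_beta - beta))
    beta <- drop(new_beta)
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- exp(drop(X %*% beta) + offset)
  w <- mu / (1 + alpha * mu)
  list(coefficients = setNames(beta, colnames(X)), fitted = mu,
       cov = solve(t(X * w) %*% X), converged = converged, iterations = it)
}

# Shared engine for the shift tests. Fits the per-gene count model on
# depth-normalized counts; for the saturated designs used here the NB/IRLS
# fixed point is the per-cell mean, so cell means are computed directly.
# Variance of the log2 contrast:
#   * "quasi" (default): pooled total squared CV per gene, moderated toward
#     a lowess trend on the gene mean with `prior_df` pseudo-df; scale-free,
#     hence exactly invariant to rescaling any single sample's counts.
#   * "nb": classic NB information (1 + alpha*m)/(n*m) per cell, with the
#     method-of-moments dispersion.
# `use` names the cells entering the contrast, `coef` their +/-1 weights.
contrast_engine <- function(counts, samples, use, coef, sf = NULL,
                            variance = c("quasi", "nb"), prior_df = 4,
                            dispersion = NULL) {
  variance <- match.arg(variance)
  assert_count_matrix(counts, "difftest")
  samples <- assert_sample_sheet(samples, counts, "difftest")
  cells <- interaction(samples$assay, samples$condition, drop = TRUE)
  sf <- sf %||% size_factors(counts)
  norm <- normalize_counts(counts, sf)
  mo <- cell_moments(norm, cells)
  if (mo$df < 1)
    stop_stage("difftest", "design has no replicated group; cannot test")
  miss <- setdiff(use, colnames(mo$means))
  if (length(miss))
    stop_stage("difftest", paste("missing assay/condition cells:",
                                 paste(miss, collapse = ", ")))

  m <- mo$means[, use, drop = FALSE]
  n <- mo$nrep[use]
  tested <- rowSums(m > 0) == length(use)
  log2fc <- rep(NA_real_, nrow(counts))
  log2fc[tested] <- drop(log2(m[tested, , drop = FALSE]) %*% coef)

  if (variance == "quasi") {
    phi <- (mo$df * mo$phi +
              prior_df * trend_fit(mo$pooled_mean, mo$phi)) /
      (mo$df + prior_df)
    var_log <- phi * sum(coef^2 / n)
    df_t <- mo$df + prior_df
  } else {
    alpha <- dispersion %||%
      pmax(0, ifelse(mo$pooled_mean > 0,
                     (mo$pooled_var - mo$pooled_mean) / mo$pooled_mean^2, 0))
    var_log <- rowSums(sweep((1 + alpha * m) / m, 2, coef^2 / n, "*"))
    df_t <- Inf
  }
  se <- sqrt(var_log) / log(2)
  stat <- log2fc / se
  p <- rep(NA_real_, length(stat))
  p[tested] <- 2 * pt(-abs(stat[tested]), df = df_t)
  data.frame(gene_id = rownames(counts), log2fc = log2fc, se = se,
             stat = stat, p = p, fdr = bh_adjust(p), tested = tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Test per-gene expression shift of one assay between two conditions
#'
#' Per-gene negative-binomial model of the chosen assay's depth-normalized
#' counts with a condition effect; Wald test of the condition coefficient.
#' `log2fc` is reported for `cond_b` versus `cond_a`; FDR is
#' Benjamini-Hochberg over tested genes (genes with a zero mean in either
#' condition carry `tested = FALSE` and missing statistics).
#'
#' @param counts gene x sample count matrix (may contain further conditions
#'   and the other assay; those samples inform normalization and the
#'   variance pooling).
#' @param samples sample sheet matching `counts`.
#' @param assay assay to test (`"rna"` or `"ribo"`).
#' @param cond_a,cond_b reference and comparison condition labels.
#' @param sf optional precomputed size factors.
#' @param variance `"quasi"` (default; moderated total-CV variance, exactly
#'   invariant to per-sample depth rescaling) or `"nb"` (classic NB
#'   information with method-of-moments dispersion).
#' @param prior_df moderation weight of the variance trend (quasi mode).
#' @param dispersion optional per-gene dispersions (nb mode).
#' @return data.frame: `gene_id`, `log2fc`, `se`, `stat`, `p`, `fdr`,
#'   `tested`.
#' @export
test_assay_shift <- function(counts, samples, assay, cond_a, cond_b,
                             sf = NULL, variance = c("quasi", "nb"),
                             prior_df = 4, dispersion = NULL) {
  use <- paste(assay, c(cond_a, cond_b), sep = ".")
  contrast_engine(counts, samples, use, c(-1, 1), sf, variance, prior_df,
                  dispersion)
}

#' Test per-gene translation-efficiency shift between two conditions
#'
#' Fits the per-gene count model with assay, condition and
#' assay x condition interaction structure; the interaction coefficient is
#' the TE log2 fold-change,
#' `log2FC(TE) = log2FC(ribo) - log2FC(rna)`, tested by Wald with BH FDR.
#' Both assays must be present in both conditions.
#'
#' @inheritParams test_assay_shift
#' @return data.frame as in [test_assay_shift()], where `log2fc` is the TE
#'   (interaction) log2 fold-change for `cond_b` versus `cond_a`.
#' @export
test_te_shift <- function(counts, samples, cond_a, cond_b, sf = NULL,
                          variance = c("quasi", "nb"), prior_df = 4,
                          dispersion = NULL) {
  use <- c(paste("ribo", c(cond_a, cond_b), sep = "."),
           paste("rna", c(cond_a, cond_b), sep = "."))
  contrast_engine(counts, samples, use, c(-1, 1, 1, -1), sf, variance,
                  prior_df, dispersion)
}
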