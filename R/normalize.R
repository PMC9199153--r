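#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors computed by the median-of-ratios
#' method: for each gene expressed in every sample, the ratio of its count
#' to its geometric mean across samples; the per-sample median of those
#' ratios is the factor. Factors are rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @examples
#' m <- matrix(c(2, 4, 8, 16), 2, 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(m)  # ~ 0.7071, 1.4142
#' @export
size_factors <- function(counts) {
  assert_count_matrix(counts, "normalize")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop_stage("normalize",
               "no gene has nonzero counts in all samples; filter the matrix first")
  lc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  logsf <- apply(lc, 2, function(col) median(col - loggeo))
  logsf <- logsf - mean(logsf)  # geometric mean 1
  setNames(exp(logsf), colnames(counts))
}

#' Depth-normalized counts
#'
#' Divides each sample's counts by its size factor.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors; computed with [size_factors()] when `NULL`.
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  sf <- sf %||% size_factors(counts)
  if (any(sf <= 0)) stop_stage("normalize", "size factors must be positive")
  sweep(counts, 2, sf, "/")
}

# Per-gene within-cell summaries on normalized counts.
# cells: factor over samples (assay x condition). Returns per-gene pooled
# squared CV (phi_hat, total variability on the ratio scale), pooled
# within-cell variance and mean, residual df, and per-cell means.
cell_moments <- function(norm, cells) {
  cells <- droplevels(as.factor(cells))
  lev <- levels(cells)
  means <- vapply(lev, function(l)
    rowMeans(norm[, cells == l, drop = FALSE]), numeric(nrow(norm)))
  if (nrow(norm) == 1) means <- matrix(means, 1, dimnames = list(rownames(norm), lev))
  nrep <- as.vector(table(cells)[lev])
  ss <- matrix(0, nrow(norm), length(lev), dimnames = dimnames(means))
  for (i in seq_along(lev)) {
    if (nrep[i] >= 2) {
      dev <- norm[, cells == lev[i], drop = FALSE] - means[, i]
      ss[, i] <- rowSums(dev^2)
    }
  }
  df <- sum(pmax(nrep - 1, 0))
  ok <- means > 0
  cv2 <- ifelse(ok, ss / ifelse(ok, means, 1)^2, 0)
  phi <- rowSums(cv2) / max(df, 1)
  pooled_var <- rowSums(ss) / max(df, 1)
  pooled_mean <- rowSums(sweep(means, 2, nrep, "*")) / sum(nrep)
  list(means = means, nrep = setNames(nrep, lev), df = df, phi = phi,
       pooled_var = pooled_var, pooled_mean = pooled_mean)
}

# Lowess trend of y against log(x); shift-equivariant in log(x), so exactly
# invariant under a global rescaling of normalized counts.
trend_fit <- function(x, y, f = 0.5) {
  ok <- is.finite(x) & x > 0 & is.finite(y)
  if (sum(ok) < 10) return(rep(max(mean(y[ok]), 0), length(y)))
  lx <- log(x[ok])
  if (length(unique(lx)) < 2) return(rep(max(mean(y[ok]), 0), length(y)))
  lo <- lowess(lx, y[ok], f = f, iter = 0)
  out <- approx(lo$x, lo$y, xout = ifelse(ok, log(pmax(x, 1e-300)), NA),
                rule = 2, ties = "ordered")$y
  out[!ok] <- mean(y[ok])
  pmax(out, 0)
}

#' Per-gene negative-binomial dispersion by method of moments
#'
#' Estimates the NB dispersion `alpha` in `variance = mu + alpha * mu^2`
#' from replicate variability: on depth-normalized counts, the within-group
#' variance `s^2` and mean `mu_bar` are pooled across the design groups and
#' `alpha_hat = max(0, (s^2 - mu_bar) / mu_bar^2)`. `alpha = 0` is the
#' Poisson limit. Optionally each estimate is shrunk toward a smooth trend
#' on the gene's mean with weight `prior_df` pseudo-degrees of freedom.
#'
#' @param counts gene x sample count matrix.
#' @param groups factor or vector assigning each sample to a design group
#'   (typically assay x condition); at least one group needs >= 2 replicates.
#' @param sf size factors (computed when `NULL`).
#' @param prior_df non-negative shrinkage weight toward the trend; 0 (the
#'   default) returns the raw method-of-moments estimates.
#' @return Named numeric vector of per-gene dispersion estimates (>= 0).
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL, prior_df = 0) {
  assert_count_matrix(counts, "dispersion")
  if (length(groups) != ncol(counts))
    stop_stage("dispersion", "groups must have one entry per sample")
  if (max(table(groups)) < 2)
    stop_stage("dispersion",
               "no group has replicates; dispersion is not estimable")
  norm <- normalize_counts(counts, sf)
  mo <- cell_moments(norm, groups)
  mu <- mo$pooled_mean
  alpha <- ifelse(mu > 0, pmax(0, (mo$pooled_var - mu) / mu^2), 0)
  if (prior_df > 0) {
    trend <- trend_fit(mu, alpha)
    alpha <- (mo$df * alpha + prior_df * trend) / (mo$df + prior_df)
  }
  setNames(alpha, rownames(counts))
}
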