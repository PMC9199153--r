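# Vectorized one-sided enrichment p-value: upper hypergeometric tail
# P(X >= a) with a successes among k draws, m marked genes, background N.
hyper_enrich_p <- function(a, k, m, N) {
  phyper(a - 1, m, N - m, k, lower.tail = FALSE)
}

#' Fisher-exact overlap of a gene category with a gene set
#'
#' Builds the 2x2 table of a category against a gene list within the
#' expression background (the list is intersected with the background
#' first) and computes the one-sided enrichment p-value — the upper
#' hypergeometric tail `P(overlap >= a)`, identical to Fisher's exact test
#' with `alternative = "greater"`. The odds ratio is `(a*d)/(b*c)`, with a
#' 0.5 continuity correction only when a zero cell occurs (flagged in the
#' `continuity` column). `pct_intersect` is `100 * a / |set ∩ background|`.
#'
#' @param category_genes gene ids in the category (must lie in `background`).
#' @param gene_set a gene set (`list(name, description, genes)`) or a plain
#'   character vector of gene ids.
#' @param background character vector: the post-filter gene universe.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`
#'   (delegated to [stats::fisher.test()]).
#' @return One-row data.frame: `set`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `continuity`, `p`, `pct_intersect`, `testable`. Empty category or set
#'   after background intersection gives `testable = FALSE` and missing `p`.
#' @examples
#' bg <- paste0("g", 1:20)
#' fisher_overlap(bg[1:10], bg[1:10], bg)$p  # 1 / choose(20, 10)
#' @export
fisher_overlap <- function(category_genes, gene_set, background,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  set_name <- "set"
  if (is.list(gene_set)) {
    set_name <- gene_set$name %||% "set"
    gene_set <- gene_set$genes
  }
  if (!all(category_genes %in% background))
    stop_stage("enrich", "category genes must be a subset of the background")
  set_bg <- unique(gene_set[gene_set %in% background])
  cat_bg <- unique(category_genes)
  N <- length(unique(background))
  k <- length(cat_bg)
  m <- length(set_bg)
  a <- length(intersect(cat_bg, set_bg))
  b <- k - a
  cc <- m - a
  d <- N - k - cc
  if (k == 0 || m == 0) {
    return(data.frame(set = set_name, a = a, b = b, c = cc, d = d,
                      odds_ratio = NA_real_, continuity = FALSE,
                      p = NA_real_, pct_intersect = NA_real_,
                      testable = FALSE, stringsAsFactors = FALSE))
  }
  continuity <- any(c(a, b, cc, d) == 0)
  or <- if (continuity) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  p <- if (alternative == "greater") hyper_enrich_p(a, k, m, N)
       else fisher.test(matrix(c(a, b, cc, d), 2), alternative = "two.sided")$p.value
  data.frame(set = set_name, a = a, b = b, c = cc, d = d, odds_ratio = or,
             continuity = continuity, p = p,
             pct_intersect = 100 * a / m, testable = TRUE,
             stringsAsFactors = FALSE)
}

#' Enrichment of every regulatory category in every gene set
#'
#' Runs [fisher_overlap()] for each (category, set) pair against the
#' background, adjusts p-values by Benjamini-Hochberg across all testable
#' rows, and orders rows by category then p.
#'
#' @param classification classified per-gene table ([classify_genes()]
#'   output, or any data.frame with `gene_id` and `category`).
#' @param gene_sets named list of gene sets ([read_gmt()] output).
#' @param background gene universe; defaults to `classification$gene_id`.
#' @param alternative passed to [fisher_overlap()].
#' @return data.frame with one row per (category, set): the 2x2 cells,
#'   odds ratio, `p`, `fdr`, `pct_intersect`, `testable`.
#' @export
enrich_all <- function(classification, gene_sets,
                       background = classification$gene_id,
                       alternative = "greater") {
  cats <- REGULATION_CATEGORIES[REGULATION_CATEGORIES %in%
                                  unique(as.character(classification$category))]
  rows <- list()
  for (cat in cats) {
    cat_genes <- classification$gene_id[
      !is.na(classification$category) & classification$category == cat]
    for (s in gene_sets) {
      r <- fisher_overlap(cat_genes, s, background, alternative)
      r <- cbind(category = cat, r, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(match(out$category, REGULATION_CATEGORIES), out$p), ]
  rownames(out) <- NULL
  out
}

#' Plot-ready enrichment scatter table
#'
#' Exports the axes of the classic enrichment scatter: `-log10(p)` against
#' the percentage of the gene list intersected by each category.
#'
#' @param enrichment output of [enrich_all()].
#' @param path optional TSV output path.
#' @return data.frame with `category`, `set`, `minus_log10_p`,
#'   `pct_intersect`.
#' @export
enrichment_scatter <- function(enrichment, path = NULL) {
  out <- data.frame(category = enrichment$category, set = enrichment$set,
                    minus_log10_p = -log10(enrichment$p),
                    pct_intersect = enrichment$pct_intersect,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv(out, path)
  out
}
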