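test_that("TE is the ratio of normalized footprint to mRNA abundance", {
  means <- cbind(rna_A = c(10, 20), ribo_A = c(30, 20))
  rownames(means) <- c("g1", "g2")
  d <- deterministic_counts(means, n_replicates = 2, conditions = "A")
  sf1 <- setNames(rep(1, 4), d$samples$sample_id)
  te <- compute_te(d$counts, d$samples, "A", pseudocount = 0, sf = sf1)
  expect_equal(unname(te), c(3, 1))  # ribo 30 / rna 10; equal means -> 1

  expect_error(compute_te(d$counts, d$samples, "B"), "condition")
  expect_error(compute_te(d$counts, d$samples, "A", pseudocount = -1),
               "non-negative")

  # pseudocount keeps TE finite on zero counts
  means0 <- cbind(rna_A = c(0, 10), ribo_A = c(5, 10))
  rownames(means0) <- c("gz", "g2")
  d0 <- deterministic_counts(means0, conditions = "A")
  te0 <- compute_te(d0$counts, d0$samples, "A", pseudocount = 0.5, sf = sf1)
  expect_true(all(is.finite(te0) & te0 > 0))
})

test_that("extreme-TE flags use strict cutoffs", {
  expect_equal(unname(flag_extreme_te(c(4, 0.1, 1, 3, 0.33))),
               c("high", "low", "neither", "neither", "neither"))
  expect_error(flag_extreme_te(c(1, -2)), "positive")
})

test_that("the classification decision tree covers all seven categories", {
  th <- te_thresholds()
  classify1 <- function(...) as.character(classify_genes(stats_row(...), th)$category)

  expect_equal(classify1(), "unregulated")
  expect_equal(classify1(lfc_te = 2, fdr_te = 1e-5, lfc_ribo = 2,
                         fdr_ribo = 1e-5), "translationally_induced")
  expect_equal(classify1(lfc_te = 2, fdr_te = 1e-5, lfc_rna = -2,
                         fdr_rna = 1e-5), "rna_down_te_up")
  expect_equal(classify1(lfc_te = -2, fdr_te = 1e-5, lfc_ribo = -2,
                         fdr_ribo = 1e-5), "translationally_repressed")
  expect_equal(classify1(lfc_te = -2, fdr_te = 1e-5, lfc_rna = 2,
                         fdr_rna = 1e-5), "rna_up_te_down")
  expect_equal(classify1(lfc_rna = 2, fdr_rna = 1e-5, lfc_ribo = 2,
                         fdr_ribo = 1e-5), "up_te_constant")
  expect_equal(classify1(lfc_rna = -2, fdr_rna = 1e-5, lfc_ribo = -2,
                         fdr_ribo = 1e-5), "down_te_constant")
  # mRNA-only significance stays unregulated
  expect_equal(classify1(lfc_rna = 3, fdr_rna = 1e-5), "unregulated")
  # strict thresholds: |log2FC| exactly at the cutoff is not significant
  expect_equal(classify1(lfc_te = 1, fdr_te = 1e-9), "unregulated")
  expect_equal(classify1(lfc_te = 2, fdr_te = 0.01), "unregulated")
})

test_that("a strongly TE-induced gene with footprint gain is induced", {
  # TE rising 1.5 -> 14 between stages with a significant footprint increase
  r <- stats_row(lfc_rna = 0.4, fdr_rna = 0.3,
                 lfc_ribo = 3.6, fdr_ribo = 1e-8,
                 lfc_te = log2(14 / 1.5), fdr_te = 1e-8)
  expect_equal(as.character(classify_genes(r)$category),
               "translationally_induced")
})

test_that("missing statistics are unclassifiable and reported", {
  s <- rbind(stats_row(gene_id = "g1"),
             stats_row(gene_id = "g2", lfc_te = NA))
  cls <- classify_genes(s)
  expect_equal(as.character(cls$category), c("unregulated", NA))
  expect_equal(attr(cls, "n_unclassified"), 1)
})

test_that("category counts partition the background", {
  sim <- simulate_counts(sim_config(n_genes = 800, seed = 24))
  cls <- classify_all(sim$counts, sim$samples, "NPC", "Neuron")
  cc <- cls$counts
  n_of <- function(k) cc$n[cc$category == k]
  expect_equal(sum(cc$n[cc$category %in% REGULATION_CATEGORIES]),
               n_of("background"))
  expect_equal(n_of("buffered") + n_of("translation_driven"),
               n_of("te_changed"))
  expect_equal(n_of("background"), nrow(sim$counts))
})

test_that("raising max_fdr never moves a regulated gene to unregulated", {
  set.seed(25)
  n <- 400
  s <- data.frame(gene_id = paste0("g", 1:n),
                  log2fc_rna = rnorm(n, 0, 2), fdr_rna = runif(n),
                  log2fc_ribo = rnorm(n, 0, 2), fdr_ribo = runif(n),
                  log2fc_te = rnorm(n, 0, 2), fdr_te = runif(n))
  strict <- classify_genes(s, te_thresholds(max_fdr = 0.05))$category
  loose <- classify_genes(s, te_thresholds(max_fdr = 0.5))$category
  expect_false(any(strict != "unregulated" & loose == "unregulated"))
})

test_that("negating the contrast mirrors the category labels", {
  set.seed(26)
  n <- 300
  s <- data.frame(gene_id = paste0("g", 1:n),
                  log2fc_rna = rnorm(n, 0, 2), fdr_rna = runif(n),
                  log2fc_ribo = rnorm(n, 0, 2), fdr_ribo = runif(n),
                  log2fc_te = rnorm(n, 0, 2), fdr_te = runif(n))
  fwd <- classify_genes(s)$category
  s2 <- s
  s2$log2fc_rna <- -s$log2fc_rna
  s2$log2fc_ribo <- -s$log2fc_ribo
  s2$log2fc_te <- -s$log2fc_te
  rev <- classify_genes(s2)$category
  map <- c(up_te_constant = "down_te_constant",
           down_te_constant = "up_te_constant",
           translationally_induced = "translationally_repressed",
           translationally_repressed = "translationally_induced",
           rna_up_te_down = "rna_down_te_up",
           rna_down_te_up = "rna_up_te_down",
           unregulated = "unregulated")
  expect_equal(as.character(rev), unname(map[as.character(fwd)]))
})

test_that("cross-assay correlation matches its closed form", {
  # identical assays: r = 1
  means <- cbind(rna_A = c(5, 50, 500), ribo_A = c(5, 50, 500))
  rownames(means) <- paste0("g", 1:3)
  d <- deterministic_counts(means, conditions = "A")
  sf1 <- setNames(rep(1, 4), d$samples$sample_id)
  expect_equal(cross_assay_correlation(d$counts, d$samples, "A", sf = sf1), 1)

  # antisymmetric log pattern: r = -1 (pseudocount 0, size factors 1)
  x <- c(-2, -1, 0, 1, 2)
  means2 <- cbind(rna_A = 2^x, ribo_A = 2^(-x)) * 64
  rownames(means2) <- paste0("g", 1:5)
  d2 <- deterministic_counts(means2, conditions = "A")
  r <- cross_assay_correlation(d2$counts, d2$samples, "A", pseudocount = 0,
                               sf = setNames(rep(1, 4), d2$samples$sample_id))
  expect_equal(r, -1, tolerance = 1e-12)

  # hand-sized example against the direct Pearson formula
  rna <- c(12, 40, 7, 300, 95)
  ribo <- c(30, 22, 9, 180, 410)
  means3 <- cbind(rna_A = rna, ribo_A = ribo)
  rownames(means3) <- paste0("g", 1:5)
  d3 <- deterministic_counts(means3, conditions = "A")
  r3 <- cross_assay_correlation(d3$counts, d3$samples, "A", pseudocount = 1,
                                sf = setNames(rep(1, 4), d3$samples$sample_id))
  lx <- log(rna + 1); ly <- log(ribo + 1)
  hand <- sum((lx - mean(lx)) * (ly - mean(ly))) /
    sqrt(sum((lx - mean(lx))^2) * sum((ly - mean(ly))^2))
  expect_equal(r3, hand, tolerance = 1e-12)
})
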