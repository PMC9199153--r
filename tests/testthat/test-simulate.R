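test_that("count simulation is deterministic and truth-aligned", {
  cfg <- sim_config(n_genes = 200, seed = 99)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(rownames(a$counts), a$truth$gene_id)
  expect_identical(colnames(a$counts), a$samples$sample_id)
  expect_equal(ncol(a$counts), 12)  # 3 conditions x 2 assays x 2 replicates

  c <- simulate_counts(sim_config(n_genes = 200, seed = 100))
  expect_false(identical(a$counts, c$counts))
})

test_that("category proportions are realized exactly by largest remainder", {
  cfg <- sim_config(n_genes = 157, seed = 3)
  sim <- simulate_counts(cfg)
  tab <- table(factor(sim$truth$category, REGULATION_CATEGORIES))
  expect_equal(sum(tab), 157)
  target <- cfg$category_proportions * 157
  expect_true(all(abs(as.numeric(tab) - target[names(tab)]) < 1))
})

test_that("planted effects match the category taxonomy", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 7,
                                    effect_log2fc = 2))
  tr <- sim$truth
  expect_true(all(tr$log2fc_te == tr$log2fc_ribo - tr$log2fc_rna))
  expect_true(all(tr$log2fc_rna[tr$category == "unregulated"] == 0))
  expect_true(all(tr$log2fc_te[tr$category == "translationally_induced"] == 2 &
                    tr$log2fc_ribo[tr$category == "translationally_induced"] == 2))
  expect_true(all(tr$log2fc_te[tr$category == "rna_up_te_down"] == -2 &
                    tr$log2fc_ribo[tr$category == "rna_up_te_down"] == 0))
  expect_true(all(tr$log2fc_te[tr$category %in%
                                 c("up_te_constant", "down_te_constant")] == 0))

  null_sim <- simulate_counts(null_config(100, seed = 2))
  expect_true(all(null_sim$truth$log2fc_rna == 0 &
                    null_sim$truth$log2fc_ribo == 0))
})

test_that("the intermediate condition carries no planted effects", {
  sim <- simulate_counts(sim_config(n_genes = 3000, seed = 21,
                                    dispersion = 0,
                                    base_mean_range = c(2000, 2000)))
  ed <- rowMeans(sim$counts[, sim$samples$condition == "ED"])
  npc <- rowMeans(sim$counts[, sim$samples$condition == "NPC"])
  expect_lt(max(abs(log2(ed / npc))), 0.5)  # Poisson noise only
})

test_that("Poisson limit concentrates sample means near planted means", {
  sim <- simulate_counts(null_config(1000, dispersion = 0, seed = 4,
                                     base_mean_range = c(1000, 1000)))
  gene_means <- rowMeans(sim$counts)
  expect_gte(mean(abs(gene_means - 1000) / 1000 < 0.10), 0.99)
})

test_that("NB counts realize variance ~ mu + dispersion * mu^2", {
  sim <- simulate_counts(sim_config(
    n_genes = 300, conditions = "A", n_replicates = 150, dispersion = 0.1,
    base_mean_range = c(500, 500), seed = 8,
    category_proportions = only_category("unregulated")))
  rna <- sim$counts[, sim$samples$assay == "rna"]
  ratio <- apply(rna, 1, var) / (500 + 0.1 * 500^2)
  expect_gt(median(ratio), 0.8)
  expect_lt(median(ratio), 1.2)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "positive integer")
  expect_error(sim_config(dispersion = -1), "non-negative")
  expect_error(sim_config(depth_factors = c(1, -1)), "positive")
  bad_p <- default_category_proportions()
  bad_p["unregulated"] <- bad_p["unregulated"] + 0.01
  expect_error(sim_config(category_proportions = bad_p), "sum to 1")
  expect_error(sim_config(effect_condition = "nope"), "conditions")
})

test_that("simulated FASTQ reads carry correct artifacts and ground truth", {
  clean_only <- simulate_fastq(50, artifact_fraction = 0, seed = 1)
  expect_identical(clean_only$seq, clean_only$clean)
  expect_true(all(clean_only$artifact_len == 0))

  art <- simulate_fastq(100, artifact_fraction = 1, run_range = c(5, 5),
                        seed = 2)
  expect_true(all(art$artifact_len == 5))
  expect_true(all(substr(art$seq, 1, 5) ==
                    strrep(art$artifact_base, 5)))
  expect_true(all(nchar(art$seq) == nchar(art$clean) + 5))
  expect_true(all(nchar(art$qual) == nchar(art$seq)))

  # file round trip with ground-truth comments
  path <- withr::local_tempfile(fileext = ".fastq.gz")
  simulate_fastq(20, seed = 3, path = path)
  back <- read_fastq(path)
  expect_equal(nrow(back), 20)
  expect_match(back$desc[1], "^clean=[ACGT]+ artifact=")
})

test_that("simulated gene lists oversample the requested category", {
  sim <- simulate_counts(sim_config(n_genes = 2000, seed = 5))
  sets <- simulate_gene_lists(sim$truth, "translationally_induced",
                              list_size = 150, enrichment_factor = 10,
                              seed = 6)
  genes <- sets[[1]]$genes
  expect_equal(length(genes), 150)
  in_cat <- sim$truth$gene_id[sim$truth$category == "translationally_induced"]
  bg_rate <- length(in_cat) / nrow(sim$truth)
  expect_gt(mean(genes %in% in_cat), 3 * bg_rate)

  unif <- simulate_gene_lists(sim$truth, "translationally_induced",
                              list_size = 150, enrichment_factor = 1,
                              seed = 6)
  expect_lt(mean(unif[[1]]$genes %in% in_cat), 3 * bg_rate)

  expect_error(simulate_gene_lists(sim$truth, list_size = 1e6), "larger")
  expect_error(simulate_gene_lists(sim$truth, enrichment_factor = 0.5), ">= 1")

  # empty category degenerates to a background draw
  null_truth <- simulate_counts(null_config(200, seed = 7))$truth
  bgdraw <- simulate_gene_lists(null_truth, "rna_up_te_down", list_size = 50,
                                enrichment_factor = 10, seed = 8)
  expect_equal(length(bgdraw[[1]]$genes), 50)
})
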