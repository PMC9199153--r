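test_that("Benjamini-Hochberg adjustment matches hand computation", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # step-up by hand: sorted p * m / rank with cumulative minimum
  p <- c(0.005, 0.011, 0.02, 0.8)
  expect_equal(bh_adjust(p), c(0.02, 0.022, 0.8 / 30, 0.8), tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("NB IRLS solves the saturated design at the group means", {
  set.seed(31)
  y <- rnbinom(8, mu = rep(c(40, 160), each = 4), size = 10)
  X <- cbind(1, rep(c(0, 1), each = 4))
  fit <- nb_irls(y, X, alpha = 0.1)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), log(mean(y[1:4])), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients[2]),
               log(mean(y[5:8]) / mean(y[1:4])), tolerance = 1e-7)
  # Poisson limit agrees with stats::glm
  ref <- glm(y ~ X[, 2], family = poisson())
  fit0 <- nb_irls(y, X, alpha = 0)
  expect_equal(unname(fit0$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit0$cov))),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-5)
  expect_error(nb_irls(y, cbind(1, 1)), "rank")
})

test_that("identical replicate sets give zero fold change and p = 1", {
  sim <- simulate_counts(null_config(120, seed = 17))
  counts <- sim$counts
  # make condition B an exact copy of condition A, per assay
  for (a in c("rna", "ribo")) {
    src <- sim$samples$assay == a & sim$samples$condition == "NPC"
    dst <- sim$samples$assay == a & sim$samples$condition == "Neuron"
    counts[, dst] <- counts[, src]
  }
  res <- test_assay_shift(counts, sim$samples, "rna", "NPC", "Neuron")
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p == 1))
  te <- test_te_shift(counts, sim$samples, "NPC", "Neuron")
  expect_true(all(te$log2fc == 0))
})

test_that("planted assay shifts are recovered with calibrated FDR", {
  cfg <- sim_config(n_genes = 1500, base_mean_range = c(500, 500),
                    dispersion = 0.01, effect_log2fc = 3, seed = 18,
                    category_proportions = c(only_category("unregulated") * 0.8 +
                                               only_category("up_te_constant") * 0.2))
  sim <- simulate_counts(cfg)
  res <- test_assay_shift(sim$counts, sim$samples, "rna", "NPC", "Neuron")
  up <- sim$truth$category == "up_te_constant"
  hit <- abs(res$log2fc[up] - 3) < 0.5 & res$fdr[up] < 0.01
  expect_gte(mean(hit), 0.95)
})

test_that("TE interaction equals the difference of the assay shifts", {
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 19))
  sf <- size_factors(sim$counts)
  rna <- test_assay_shift(sim$counts, sim$samples, "rna", "NPC", "Neuron", sf)
  ribo <- test_assay_shift(sim$counts, sim$samples, "ribo", "NPC", "Neuron", sf)
  te <- test_te_shift(sim$counts, sim$samples, "NPC", "Neuron", sf)
  expect_equal(te$log2fc, ribo$log2fc - rna$log2fc, tolerance = 1e-6)
})

test_that("planted TE shifts are recovered by the interaction test", {
  cfg <- sim_config(n_genes = 1000, base_mean_range = c(500, 500),
                    dispersion = 0.01, effect_log2fc = 2, seed = 20,
                    category_proportions =
                      c(only_category("unregulated") * 0.8 +
                          only_category("translationally_induced") * 0.2))
  sim <- simulate_counts(cfg)
  te <- test_te_shift(sim$counts, sim$samples, "NPC", "Neuron")
  planted <- sim$truth$category == "translationally_induced"
  expect_gte(mean(abs(te$log2fc[planted] - 2) < 0.5), 0.95)
})

test_that("swapping the condition order negates fold changes, keeps p", {
  sim <- simulate_counts(sim_config(n_genes = 200, seed = 21))
  fwd <- test_te_shift(sim$counts, sim$samples, "NPC", "Neuron")
  rev <- test_te_shift(sim$counts, sim$samples, "Neuron", "NPC")
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
})

test_that("interaction p-values are uniform under the global null", {
  sim <- simulate_counts(null_config(2000, seed = 22))
  te <- test_te_shift(sim$counts, sim$samples, "NPC", "Neuron")
  ks <- suppressWarnings(ks.test(te$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("contrast errors are informative", {
  sim <- simulate_counts(sim_config(n_genes = 50, seed = 23))
  expect_error(test_assay_shift(sim$counts, sim$samples, "rna", "NPC", "nope"),
               "missing assay/condition")
  # all-zero gene is flagged untested with missing statistics
  counts <- sim$counts
  counts[1, ] <- 0L
  res <- test_assay_shift(counts, sim$samples, "rna", "NPC", "Neuron")
  expect_false(res$tested[1])
  expect_true(is.na(res$p[1]) && is.na(res$log2fc[1]))
  expect_true(all(res$tested[-1]))
})
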