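#' Simulation configuration for a paired Ribo-seq/RNA-seq experiment
#'
#' Builds and validates the configuration used by [simulate_counts()]. The
#' defaults emulate a three-stage neuronal differentiation design:
#' neuroprogenitors (NPC), early differentiation (ED) and 30-day neurons,
#' each profiled by RNA-seq and Ribo-seq in duplicate (12 libraries).
#' Regulatory effects are planted in `effect_condition` only; the
#' intermediate ED stage stays at baseline, reflecting the observation that
#' early differentiation shows essentially no TE changes.
#'
#' @param n_genes number of genes to simulate.
#' @param conditions ordered condition labels; the first is the reference.
#' @param n_replicates replicates per condition x assay cell.
#' @param base_mean_range positive length-2 numeric; per-gene baseline means
#'   are drawn log-uniformly from this interval (counts at size factor 1).
#' @param dispersion negative-binomial dispersion `alpha` in the
#'   `variance = mu + alpha * mu^2` parameterization; 0 gives Poisson counts.
#' @param depth_factors per-sample sequencing-depth multipliers, recycled to
#'   the number of samples; all must be positive.
#' @param category_proportions named numeric vector over
#'   [REGULATION_CATEGORIES] summing to 1; realized gene counts per category
#'   are allocated exactly by largest remainder, then shuffled.
#' @param effect_log2fc planted absolute log2 fold-change magnitude.
#' @param effect_condition condition that receives the planted effects
#'   (default: the last condition).
#' @param seed integer seed; identical configurations with the same seed
#'   produce bitwise-identical output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 14159,
                       conditions = c("NPC", "ED", "Neuron"),
                       n_replicates = 2,
                       base_mean_range = c(10, 5000),
                       dispersion = 0.05,
                       depth_factors = 1,
                       category_proportions = default_category_proportions(),
                       effect_log2fc = 2.0,
                       effect_condition = conditions[length(conditions)],
                       seed = 1L) {
  if (length(n_genes) != 1 || n_genes < 1 || n_genes != round(n_genes))
    stop_stage("simulate", "n_genes must be a positive integer")
  if (length(conditions) < 1 || anyDuplicated(conditions))
    stop_stage("simulate", "conditions must be distinct labels")
  if (n_replicates < 1 || n_replicates != round(n_replicates))
    stop_stage("simulate", "n_replicates must be a positive integer")
  if (length(base_mean_range) != 2 || any(base_mean_range <= 0) ||
      base_mean_range[1] > base_mean_range[2])
    stop_stage("simulate", "base_mean_range must be an increasing positive pair")
  if (length(dispersion) != 1 || dispersion < 0 || !is.finite(dispersion))
    stop_stage("simulate", "dispersion must be a non-negative real")
  n_samples <- length(conditions) * 2L * n_replicates
  depth_factors <- rep_len(depth_factors, n_samples)
  if (any(depth_factors <= 0))
    stop_stage("simulate", "depth_factors must be positive")
  p <- category_proportions
  if (is.null(names(p)) || !setequal(names(p), REGULATION_CATEGORIES))
    stop_stage("simulate",
               "category_proportions must be named over REGULATION_CATEGORIES")
  p <- p[REGULATION_CATEGORIES]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_stage("simulate", "category_proportions must be >= 0 and sum to 1")
  if (effect_log2fc <= 0)
    stop_stage("simulate", "effect_log2fc must be positive")
  if (!effect_condition %in% conditions)
    stop_stage("simulate", "effect_condition must be one of conditions")
  structure(
    list(n_genes = as.integer(n_genes), conditions = conditions,
         n_replicates = as.integer(n_replicates),
         base_mean_range = base_mean_range, dispersion = dispersion,
         depth_factors = depth_factors, category_proportions = p,
         effect_log2fc = effect_log2fc, effect_condition = effect_condition,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default planted-category proportions
#'
#' Mirrors the composition reported for the NPC-to-neuron background of
#' 14,159 genes: roughly 15% differentially expressed with constant TE,
#' 12% translationally buffered, 9% translation-driven, the rest
#' unregulated.
#'
#' @return Named numeric vector over [REGULATION_CATEGORIES] summing to 1.
#' @export
default_category_proportions <- function() {
  c(up_te_constant = 0.076, down_te_constant = 0.076,
    translationally_induced = 0.046, translationally_repressed = 0.046,
    rna_up_te_down = 0.0605, rna_down_te_up = 0.0605,
    unregulated = 0.635)
}

# Largest-remainder allocation: exact integer composition for proportions.
allocate_categories <- function(proportions, n) {
  target <- proportions * n
  base <- floor(target)
  remainder <- n - sum(base)
  if (remainder > 0) {
    frac <- target - base
    extra <- order(-frac, seq_along(frac))[seq_len(remainder)]
    base[extra] <- base[extra] + 1
  }
  rep(names(proportions), times = base)
}

# Planted per-assay log2 fold changes implied by a category label.
category_effects <- function(category, e) {
  rna <- ribo <- numeric(length(category))
  rna[category == "up_te_constant"] <- e
  ribo[category == "up_te_constant"] <- e
  rna[category == "down_te_constant"] <- -e
  ribo[category == "down_te_constant"] <- -e
  ribo[category == "translationally_induced"] <- e
  ribo[category == "translationally_repressed"] <- -e
  rna[category == "rna_up_te_down"] <- e
  rna[category == "rna_down_te_up"] <- -e
  data.frame(log2fc_rna = rna, log2fc_ribo = ribo)
}

#' Simulate a paired Ribo-seq/RNA-seq count experiment with planted truth
#'
#' Draws a gene x sample matrix of negative-binomial counts
#' (`variance = mu + dispersion * mu^2`; `dispersion = 0` degenerates to
#' Poisson). Each gene carries a planted regulatory category; the implied
#' log2 fold changes are applied to the `effect_condition` samples of the
#' matching assay, so the TE effect equals `log2fc_ribo - log2fc_rna`.
#'
#' @param config a [sim_config()] object.
#'
#' @return A list of class `te_sim` with elements `counts` (integer matrix),
#'   `samples` (sample sheet: `sample_id`, `assay`, `condition`,
#'   `replicate`), `truth` (per-gene `gene_id`, `category`, `log2fc_rna`,
#'   `log2fc_ribo`, `log2fc_te`) and `config`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$category)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    stop_stage("simulate", "config must be built with sim_config()")
  n <- config$n_genes
  samples <- expand.grid(
    replicate = seq_len(config$n_replicates),
    assay = c("rna", "ribo"),
    condition = config$conditions,
    stringsAsFactors = FALSE
  )[, c("assay", "condition", "replicate")]
  samples$sample_id <- sprintf("%s_%s_%d", samples$condition, samples$assay,
                               samples$replicate)
  samples <- samples[, c("sample_id", "assay", "condition", "replicate")]
  gene_id <- sprintf("gene_%05d", seq_len(n))

  with_seed(config$seed, {
    category <- allocate_categories(config$category_proportions, n)
    category <- category[sample.int(n)]
    base <- exp(runif(n, log(config$base_mean_range[1]),
                      log(config$base_mean_range[2])))
    eff <- category_effects(category, config$effect_log2fc)

    fc <- matrix(0, n, nrow(samples))
    hit <- samples$condition == config$effect_condition
    fc[, hit & samples$assay == "rna"] <- eff$log2fc_rna
    fc[, hit & samples$assay == "ribo"] <- eff$log2fc_ribo
    mu <- base * 2^fc
    mu <- sweep(mu, 2, config$depth_factors, "*")

    counts <- if (config$dispersion == 0) {
      rpois(length(mu), lambda = as.vector(mu))
    } else {
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion)
    }
    counts <- matrix(as.integer(counts), n, nrow(samples),
                     dimnames = list(gene_id, samples$sample_id))

    truth <- data.frame(
      gene_id = gene_id, category = category,
      log2fc_rna = eff$log2fc_rna, log2fc_ribo = eff$log2fc_ribo,
      log2fc_te = eff$log2fc_ribo - eff$log2fc_rna,
      base_mean = base, stringsAsFactors = FALSE
    )
    structure(list(counts = counts, samples = samples, truth = truth,
                   config = config),
              class = "te_sim")
  })
}

#' @export
print.te_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated Ribo-seq/RNA-seq experiment: %d genes x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(x$config$conditions, collapse = "/")
  ))
  print(table(x$truth$category)[REGULATION_CATEGORIES])
  invisible(x)
}

#' Simulate footprint-length FASTQ reads with template-switch artifacts
#'
#' Generates reads with inserts of footprint-like length and, for a chosen
#' fraction, a prepended homopolymer run of an artifact base (poly-C or
#' poly-T by default), emulating non-templated bases added by
#' template-switching library chemistry. The clean insert is recorded in the
#' FASTQ comment (`clean=<seq> artifact=<base><len>`), giving a per-read
#' ground truth for trimmer validation.
#'
#' A read is flagged `recoverable = FALSE` when trimming cannot restore the
#' recorded insert by construction: the artifact run is shorter than
#' `spec$min_run`, the insert itself starts with the artifact base (the runs
#' merge), or — for artifact-free reads — the insert starts with a
#' homopolymer run of an artifact base at least `min_run` long.
#'
#' @param n_reads number of reads (>= 0).
#' @param artifact_fraction fraction of reads carrying an artifact run.
#' @param spec a [trim_spec()] describing the artifact (bases, end,
#'   minimum run).
#' @param run_range integer pair: artifact run lengths are drawn uniformly
#'   from this range.
#' @param insert_range integer pair of clean insert lengths (default 26-34
#'   nt, ribosome-footprint scale).
#' @param seed integer seed or `NULL`.
#' @param path optional FASTQ output path (`.gz` handled transparently).
#'
#' @return A data.frame with `id`, `seq`, `qual`, `clean`, `artifact_base`,
#'   `artifact_len` (0 when absent) and `recoverable`; written to `path`
#'   as FASTQ when requested (invisibly returns the data.frame then too).
#' @export
simulate_fastq <- function(n_reads, artifact_fraction = 0.5,
                           spec = trim_spec(), run_range = c(3L, 8L),
                           insert_range = c(26L, 34L), seed = NULL,
                           path = NULL) {
  if (n_reads < 0 || n_reads != round(n_reads))
    stop_stage("simulate", "n_reads must be a non-negative integer")
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop_stage("simulate", "artifact_fraction must be in [0, 1]")
  if (any(run_range < 1) || run_range[1] > run_range[2])
    stop_stage("simulate", "run_range must be an increasing positive pair")

  # sample from a range without the scalar-x surprise of sample()
  sample_range <- function(rng, n) {
    v <- rng[1]:rng[2]
    v[sample.int(length(v), n, replace = TRUE)]
  }
  reads <- with_seed(seed, {
    n <- as.integer(n_reads)
    len <- if (n) sample_range(insert_range, n) else integer()
    clean <- vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""), "")
    has_art <- if (n) runif(n) < artifact_fraction else logical()
    art_base <- rep(NA_character_, n)
    art_len <- integer(n)
    if (any(has_art)) {
      art_base[has_art] <- spec$bases[sample.int(length(spec$bases),
                                                 sum(has_art), replace = TRUE)]
      art_len[has_art] <- sample_range(run_range, sum(has_art))
    }
    seq <- clean
    if (any(has_art)) {
      run <- strrep(art_base[has_art], art_len[has_art])
      seq[has_art] <- if (spec$end == "5prime")
        paste0(run, clean[has_art]) else paste0(clean[has_art], run)
    }
    qual <- vapply(nchar(seq), function(l)
      intToUtf8(sample(66:73, l, TRUE)), "")

    first <- function(s) substr(s, 1, 1)
    leading_run <- function(s) nchar(s) - nchar(sub("^(.)\\1*", "", s))
    anchor <- if (spec$end == "5prime") clean else reverse_chars(clean)
    # non-recoverable by construction: the artifact run merges with the
    # insert's own leading base, the insert itself starts with a qualifying
    # artifact-base run (breaks recovery and idempotency alike), or the
    # planted run is too short to trigger the trimmer
    merged <- has_art & first(anchor) == art_base
    starts_artifact <- first(anchor) %in% spec$bases &
      leading_run(anchor) >= spec$min_run
    too_short <- has_art & art_len < spec$min_run
    data.frame(
      id = sprintf("read_%06d", seq_len(n)),
      seq = seq, qual = qual, clean = clean,
      artifact_base = art_base, artifact_len = art_len,
      recoverable = !(merged | starts_artifact | too_short),
      stringsAsFactors = FALSE
    )
  })

  if (!is.null(path)) {
    desc <- sprintf("clean=%s artifact=%s", reads$clean,
                    ifelse(reads$artifact_len > 0,
                           paste0(reads$artifact_base, reads$artifact_len),
                           "none"))
    write_fastq(data.frame(id = reads$id, desc = desc, seq = reads$seq,
                           qual = reads$qual, stringsAsFactors = FALSE),
                path)
    return(invisible(reads))
  }
  reads
}

reverse_chars <- function(x) {
  vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), "")
}

#' Simulate gene lists enriched for a planted regulatory category
#'
#' Draws gene sets that oversample members of chosen categories by a given
#' factor relative to the background frequency, emulating subcellular
#' compartment lists (axonal transcriptome, synaptic bouton proteome,
#' monosome/polysome fractions) used for enrichment analysis.
#' `enrichment_factor = 1` gives a uniform background sample; an empty
#' category degenerates to a background-only draw.
#'
#' @param truth truth table from [simulate_counts()] (or any data.frame with
#'   `gene_id` and `category`).
#' @param categories categories to build one list for each.
#' @param list_size genes per list; must not exceed the background size.
#' @param enrichment_factor sampling weight (>= 1) of in-category genes.
#' @param seed integer seed or `NULL`.
#' @param path optional GMT output path.
#'
#' @return A named list of gene sets (each `list(name, description, genes)`),
#'   written as GMT when `path` is given.
#' @export
simulate_gene_lists <- function(truth, categories = regulated_categories(),
                                list_size = 200, enrichment_factor = 1,
                                seed = NULL, path = NULL) {
  if (enrichment_factor < 1)
    stop_stage("simulate", "enrichment_factor must be >= 1")
  if (list_size > nrow(truth))
    stop_stage("simulate", "requested list larger than background")
  sets <- with_seed(seed, {
    lapply(categories, function(cat) {
      w <- ifelse(truth$category == cat, enrichment_factor, 1)
      list(name = paste0(cat, "_list"),
           description = sprintf("synthetic list, factor %g over %s",
                                 enrichment_factor, cat),
           genes = sample(truth$gene_id, list_size, prob = w))
    })
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  if (!is.null(path)) write_gmt(sets, path)
  sets
}
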