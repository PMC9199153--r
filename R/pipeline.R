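#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. All
#' analysis thresholds live here; the conventional defaults (twofold change,
#' FDR 0.01, count >= 1 in every library) are defaults, not constants.
#' A YAML file with the same keys can be passed straight to
#' [run_pipeline()].
#'
#' @param counts path to the count TSV.
#' @param samples path to the sample-sheet TSV.
#' @param outdir output directory (created if missing).
#' @param contrasts list of length-2 character vectors `c(cond_b, cond_a)`.
#' @param gmt optional GMT path for enrichment.
#' @param min_abs_log2fc,max_fdr classification thresholds.
#' @param min_count background-filter minimum raw count.
#' @param pseudocount TE pseudocount.
#' @param variance,prior_df variance mode of the shift tests.
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, outdir,
                            contrasts = list(c("Neuron", "NPC")),
                            gmt = NULL, min_abs_log2fc = 1, max_fdr = 0.01,
                            min_count = 1, pseudocount = 0.5,
                            variance = "quasi", prior_df = 4, seed = 1L) {
  if (!is.list(contrasts) || !all(vapply(contrasts, length, 0L) == 2))
    stop_stage("config", "contrasts must be a list of length-2 vectors")
  structure(list(counts = counts, samples = samples, outdir = outdir,
                 contrasts = contrasts, gmt = gmt,
                 min_abs_log2fc = min_abs_log2fc, max_fdr = max_fdr,
                 min_count = min_count, pseudocount = pseudocount,
                 variance = variance, prior_df = prior_df,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop_stage("config", "config must be a pipeline_config, list or YAML path")
  if (!is.null(config$contrasts))
    config$contrasts <- lapply(config$contrasts, unlist)
  do.call(pipeline_config, config)
}

log_msg <- function(log_con, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  message(line)
  if (!is.null(log_con)) writeLines(line, log_con)
}

#' Run the translational-control pipeline end to end
#'
#' Reads the count matrix and sample sheet, validates the configuration up
#' front, then per contrast: background filter, normalization, the three
#' shift tests, classification, per-condition TE, and (when a GMT file is
#' given) category enrichment. All tables are written as TSV under
#' `outdir`; a run manifest with input checksums and per-stage row counts
#' makes silent input drift detectable. Two runs with identical inputs and
#' configuration produce byte-identical tables.
#'
#' @param config a [pipeline_config()], a plain list of its arguments, or a
#'   path to a YAML file with the same keys.
#' @return Invisibly, a list with one [te_fit()] per contrast, the
#'   enrichment tables, and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- as_pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(cfg$outdir, "run.log"), "wt")
  on.exit(close(log_con))

  log_msg(log_con, "stage config: validating inputs")
  for (p in c(cfg$counts, cfg$samples, cfg$gmt))
    if (!file.exists(p)) stop_stage("config", paste("missing input file:", p))
  counts <- read_counts_tsv(cfg$counts)
  samples <- read_sample_sheet(cfg$samples)
  samples <- assert_sample_sheet(samples, counts, "config")
  for (ct in cfg$contrasts)
    if (!all(ct %in% samples$condition))
      stop_stage("config", paste("contrast names a missing condition:",
                                 paste(ct, collapse = " vs ")))
  gene_sets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
  thresholds <- te_thresholds(cfg$min_abs_log2fc, cfg$max_fdr)
  filter <- background_filter(cfg$min_count)

  stage_rows <- list(input_genes = nrow(counts))
  fits <- list()
  enrichments <- list()
  for (ct in cfg$contrasts) {
    label <- paste0(ct[1], "_vs_", ct[2])
    log_msg(log_con, "stage fit (%s): filter + normalize + test + classify",
            label)
    fit <- te_fit(counts, samples, contrast = ct, thresholds = thresholds,
                  filter = filter, pseudocount = cfg$pseudocount,
                  variance = cfg$variance, prior_df = cfg$prior_df)
    fits[[label]] <- fit
    stage_rows[[paste0("background_", label)]] <- fit$background_size

    log_msg(log_con, "stage export (%s)", label)
    write_tsv(fit$stats, file.path(cfg$outdir,
                                   paste0("classification_", label, ".tsv")))
    write_tsv(fit$category_counts,
              file.path(cfg$outdir, paste0("category_counts_", label, ".tsv")))
    export_fc_plane(fit, file.path(cfg$outdir,
                                   paste0("fc_plane_", label, ".tsv")))
    stage_rows[[paste0("classified_", label)]] <- nrow(fit$stats)

    if (!is.null(gene_sets)) {
      log_msg(log_con, "stage enrich (%s): %d gene sets", label,
              length(gene_sets))
      enr <- enrich_all(fit$stats, gene_sets)
      enrichments[[label]] <- enr
      write_tsv(enr, file.path(cfg$outdir, paste0("enrichment_", label,
                                                  ".tsv")))
      stage_rows[[paste0("enrichment_rows_", label)]] <- nrow(enr)
    }
  }

  log_msg(log_con, "stage export: TE heatmap matrix")
  export_te_heatmap(fits[[1]], file.path(cfg$outdir, "te_heatmap.tsv"))

  manifest <- run_manifest(cfg, stage_rows)
  yaml::write_yaml(manifest, file.path(cfg$outdir, "run_manifest.yaml"))
  log_msg(log_con, "done: %d contrast(s), outputs in %s",
          length(cfg$contrasts), cfg$outdir)
  invisible(list(fits = fits, enrichments = enrichments,
                 manifest = manifest))
}

# Manifest: tool version, config hash, input checksums, per-stage row
# counts, timestamp. Identical inputs give identical manifests up to the
# timestamp.
run_manifest <- function(cfg, stage_rows) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(cfg)), collapse = "\n"), tmp)
  inputs <- c(cfg$counts, cfg$samples, cfg$gmt)
  list(
    tool = "riboTE",
    version = as.character(packageVersion("riboTE")),
    config_hash = unname(tools::md5sum(tmp)),
    input_md5 = as.list(tools::md5sum(inputs)),
    stage_rows = stage_rows,
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Export the fold-change plane
#'
#' One row per background gene: mRNA log2FC, footprint log2FC and the
#' assigned category — the coordinates of the classification scatter.
#'
#' @param fit a [te_fit()] object (or a classified stats data.frame).
#' @param path optional TSV output path.
#' @return data.frame with `gene_id`, `log2fc_rna`, `log2fc_ribo`,
#'   `category`.
#' @export
export_fc_plane <- function(fit, path = NULL) {
  stats <- if (inherits(fit, "te_fit")) fit$stats else fit
  out <- data.frame(gene_id = stats$gene_id,
                    log2fc_rna = stats$log2fc_rna,
                    log2fc_ribo = stats$log2fc_ribo,
                    category = as.character(stats$category),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv(out, path)
  out
}

#' Export the log2-TE heatmap matrix
#'
#' Gene x condition matrix of `log2(TE)` values, columns in the configured
#' condition order — the matrix behind per-stage TE heatmaps.
#'
#' @param fit a [te_fit()] object, or a gene x condition TE matrix.
#' @param path optional TSV output path.
#' @param genes optional gene subset (default: all background genes).
#' @return data.frame with `gene_id` and one `log2_te_<condition>` column
#'   per condition.
#' @export
export_te_heatmap <- function(fit, path = NULL, genes = NULL) {
  te <- if (inherits(fit, "te_fit")) fit$te else fit
  if (!is.null(genes)) te <- te[genes, , drop = FALSE]
  out <- data.frame(gene_id = rownames(te), log2(te), check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("log2_te_", colnames(te))
  if (!is.null(path)) write_tsv(out, path)
  out
}
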