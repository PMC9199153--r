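#' Read and write gene x sample count matrices as TSV
#'
#' The on-disk format is a header line (`gene_id` followed by sample ids)
#' and one row per gene, tab-separated, UTF-8, '.' decimal separator.
#'
#' @param path file path.
#' @return `read_counts_tsv()`: an integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    stop_stage("io", "count TSV must start with a gene_id column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  assert_count_matrix(m, "io")
}

#' @rdname read_counts_tsv
#' @param counts gene x sample matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read and write the sample sheet
#'
#' Columns: `sample_id`, `assay` (`rna`/`ribo`), `condition`, `replicate`.
#'
#' @param path file path.
#' @return `read_sample_sheet()`: a data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_sample_sheet(df, stage = "io")
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  write_tsv(samples, path)
}

# All tabular output funnels through here: TSV, header, no quoting.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A named list of gene sets, each `list(name, description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2)
      stop_stage("io", "malformed GMT line (need name TAB description)")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("gene set '%s': duplicated members deduplicated", f[1]))
      genes <- unique(genes)
    }
    list(name = f[1], description = f[2], genes = genes)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write FASTQ files
#'
#' Plain 4-line-record FASTQ I/O, gzip-transparent, preserving the header
#' comment (everything after the first space) which the simulator uses to
#' carry per-read ground truth.
#'
#' @param path FASTQ path (`.gz` handled transparently).
#' @return `read_fastq()`: data.frame with `id`, `desc`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4 != 0)
    stop_stage("io", "FASTQ record count is not a multiple of 4")
  idx <- seq(1, length(lines), by = 4)
  header <- sub("^@", "", lines[idx])
  sp <- regexpr(" ", header, fixed = TRUE)
  id <- ifelse(sp > 0, substr(header, 1, sp - 1), header)
  desc <- ifelse(sp > 0, substr(header, sp + 1, nchar(header)), "")
  data.frame(id = id, desc = desc, seq = lines[idx + 1], qual = lines[idx + 3],
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame with `id`, `seq`, `qual` and optional `desc`.
#' @export
write_fastq <- function(reads, path) {
  desc <- if (!is.null(reads$desc)) reads$desc else ""
  header <- paste0("@", reads$id, ifelse(nzchar(desc), paste0(" ", desc), ""))
  lines <- as.vector(rbind(header, reads$seq, "+", reads$qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
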