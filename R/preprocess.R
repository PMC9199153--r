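#' Trimming specification for template-switch homopolymer artifacts
#'
#' Template-switching library chemistry can prepend non-templated
#' homopolymer bases (poly-C/poly-T) to reads; this spec describes what the
#' trimmer removes: a single maximal run of one artifact base at the chosen
#' read end, when the run is at least `min_run` long.
#'
#' @param bases artifact nucleotides, a subset of A/C/G/T.
#' @param end read end to trim, `"5prime"` (default) or `"3prime"`.
#' @param min_run minimum homopolymer run length that triggers trimming.
#' @param min_len_after reads shorter than this after trimming are flagged
#'   as discarded.
#' @return An object of class `trim_spec`.
#' @export
trim_spec <- function(bases = c("C", "T"), end = c("5prime", "3prime"),
                      min_run = 3L, min_len_after = 20L) {
  end <- match.arg(end)
  if (!length(bases) || !all(bases %in% c("A", "C", "G", "T")))
    stop_stage("trim", "bases must be a non-empty subset of A, C, G, T")
  if (min_run < 1 || min_run != round(min_run))
    stop_stage("trim", "min_run must be a positive integer")
  if (min_len_after < 0)
    stop_stage("trim", "min_len_after must be non-negative")
  structure(list(bases = bases, end = end, min_run = as.integer(min_run),
                 min_len_after = as.integer(min_len_after)),
            class = "trim_spec")
}

#' Trim homopolymer artifact runs from reads
#'
#' Removes, at most once per read, the maximal homopolymer run of an
#' artifact base at the end named by `spec`, together with the matching
#' quality values. Runs shorter than `spec$min_run` are left alone. Reads
#' containing characters outside A/C/G/T/N raise a warning and pass through
#' untrimmed. Reads shorter than `spec$min_len_after` after trimming are
#' flagged `discarded`.
#'
#' @param seq character vector of read sequences.
#' @param qual optional character vector of quality strings (same lengths).
#' @param spec a [trim_spec()].
#'
#' @return data.frame with `seq`, `qual` (if given), `trimmed` (bases
#'   removed) and `discarded`.
#' @examples
#' trim_artifacts("TTTTTACGTACGTACGTACGTACGT",
#'                spec = trim_spec(min_len_after = 10))$seq
#' @export
trim_artifacts <- function(seq, qual = NULL, spec = trim_spec()) {
  stopifnot(inherits(spec, "trim_spec"))
  if (!is.null(qual) && any(nchar(qual) != nchar(seq)))
    stop_stage("trim", "quality strings must match sequence lengths")

  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    warning(sprintf("%d read(s) contain non-ACGTN characters; passed through untrimmed",
                    sum(bad)))

  work <- if (spec$end == "3prime") reverse_chars(seq) else seq
  first <- substr(work, 1, 1)
  run <- nchar(work) - nchar(sub("^(.)\\1*", "", work))
  cut <- ifelse(!bad & first %in% spec$bases & run >= spec$min_run, run, 0L)

  keep_len <- nchar(seq) - cut
  out_seq <- if (spec$end == "3prime") substr(seq, 1, keep_len)
             else substr(seq, cut + 1, nchar(seq))
  res <- data.frame(seq = out_seq, trimmed = cut,
                    discarded = keep_len < spec$min_len_after,
                    stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    res$qual <- if (spec$end == "3prime") substr(qual, 1, keep_len)
                else substr(qual, cut + 1, nchar(qual))
    res <- res[, c("seq", "qual", "trimmed", "discarded")]
  }
  res
}

#' Trim a FASTQ file and write the surviving reads
#'
#' File-level wrapper around [trim_artifacts()]: reads `input`
#' (gzip-transparent), trims, drops reads flagged as discarded, writes the
#' remainder to `output` and returns a summary.
#'
#' @param input,output FASTQ paths (`.gz` supported).
#' @param spec a [trim_spec()].
#' @param summary_path optional TSV path for the one-row summary.
#' @return Invisibly, a data.frame with `reads_in`, `trimmed`, `discarded`,
#'   `reads_out`.
#' @export
trim_fastq <- function(input, output, spec = trim_spec(),
                       summary_path = NULL) {
  reads <- read_fastq(input)
  tr <- trim_artifacts(reads$seq, reads$qual, spec)
  out <- data.frame(id = reads$id, desc = reads$desc,
                    seq = tr$seq, qual = tr$qual, stringsAsFactors = FALSE)
  write_fastq(out[!tr$discarded, , drop = FALSE], output)
  summary <- data.frame(reads_in = nrow(reads),
                        trimmed = sum(tr$trimmed > 0),
                        discarded = sum(tr$discarded),
                        reads_out = sum(!tr$discarded))
  if (!is.null(summary_path)) write_tsv(summary, summary_path)
  invisible(summary)
}

#' Background filter specification
#'
#' The expression background is the gene universe used by every test and
#' enrichment: genes with at least `min_count` raw reads in every in-scope
#' sample (by default, all libraries of the experiment).
#'
#' @param min_count minimum raw count required in each in-scope sample.
#' @param scope optional character vector of sample ids the rule applies to;
#'   `NULL` means all samples.
#' @return An object of class `background_filter`.
#' @export
background_filter <- function(min_count = 1L, scope = NULL) {
  if (min_count < 0 || min_count != round(min_count))
    stop_stage("filter", "min_count must be a non-negative integer")
  structure(list(min_count = as.integer(min_count), scope = scope),
            class = "background_filter")
}

#' Restrict a count matrix to the expression background
#'
#' Keeps exactly the genes with raw count >= `filter$min_count` in every
#' in-scope sample, preserving row order. The realized background size is
#' attached as attribute `background_size`.
#'
#' @param counts gene x sample count matrix.
#' @param filter a [background_filter()].
#' @return The row-subset count matrix.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' filter_background(m, background_filter(min_count = 1))
#' @export
filter_background <- function(counts, filter = background_filter()) {
  assert_count_matrix(counts, "filter")
  stopifnot(inherits(filter, "background_filter"))
  scope <- filter$scope %||% colnames(counts)
  if (!length(scope) || !all(scope %in% colnames(counts)))
    stop_stage("filter", "filter scope must name at least one existing sample")
  keep <- rowSums(counts[, scope, drop = FALSE] >= filter$min_count) ==
    length(scope)
  out <- counts[keep, , drop = FALSE]
  attr(out, "background_size") <- sum(keep)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
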