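# Readers and writers for the pipeline's plain-text formats: TSV count
# matrices (gene_id column + one column per sample), TSV sample sheets,
# FASTA coding sequences with "gene|transcript|mrna_length" headers, and
# generic result tables.  All TSVs are UTF-8, tab-separated, '#' comments.

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids, a `gene_id` column, and numeric
#' (possibly fractional, per RSEM expected counts) non-negative values.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples, with dimnames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("count matrix must have a `gene_id` column", call. = FALSE)
  ids <- as.character(df$gene_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  m <- df[names(df) != "gene_id"]
  dupc <- unique(names(m)[duplicated(names(m))])
  if (length(dupc))
    stop("duplicate sample ids: ", paste(dupc, collapse = ", "), call. = FALSE)
  for (j in seq_along(m)) {
    v <- suppressWarnings(as.numeric(m[[j]]))
    bad <- which(is.na(v) & !is.na(m[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric count at row %d, column `%s`",
                   bad[1], names(m)[j]), call. = FALSE)
    m[[j]] <- v
  }
  m <- as.matrix(m)
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE))
    stop("negative counts are not allowed", call. = FALSE)
  m
}

#' Write a count matrix to TSV
#' @param counts gene-by-sample matrix.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Read a sample sheet from TSV
#'
#' Requires columns `sample`, `tissue`, `fraction`, `replicate`,
#' `experiment`.  The `fraction` field is matched case-insensitively to
#' `IP`/`input` and normalized.  The (tissue, fraction, replicate,
#' experiment) combinations must be unique.
#'
#' @param path file path.
#' @return data.frame with the five columns, fraction normalized.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "fraction", "replicate", "experiment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  dup <- unique(df$sample[duplicated(df$sample)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  fr <- c(ip = "IP", input = "input")[tolower(df$fraction)]
  if (anyNA(fr))
    stop("unknown fraction level(s): ",
         paste(unique(df$fraction[is.na(fr)]), collapse = ", "),
         " (expected IP or input)", call. = FALSE)
  df$fraction <- unname(fr)
  key <- do.call(paste, c(df[c("tissue", "fraction", "replicate",
                               "experiment")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (tissue, fraction, replicate, experiment) combinations",
         call. = FALSE)
  df
}

#' Write a sample sheet to TSV
#' @param samples sample sheet data.frame.
#' @param path file path.
#' @export
write_sample_sheet <- function(samples, path) write_table(samples, path)

#' Write a result table to TSV
#'
#' Tab-separated, UTF-8, no quoting, no row names; the column order of the
#' data.frame is preserved.
#'
#' @param table data.frame.
#' @param path file path.
#' @export
write_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read coding sequences from FASTA
#'
#' Headers must be `gene|transcript|mrna_length`.  Wrapped and unwrapped
#' sequence lines are accepted.  Sequences must be A/C/G/T and no longer
#' than their stated mRNA length.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `gene_id`, `transcript_id`, `cds`,
#'   `mrna_length` (one row per transcript).
#' @export
read_transcripts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("FASTA header not in gene|transcript|mrna_length form: ",
         names(seqs)[bad[1]], call. = FALSE)
  df <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                   transcript_id = vapply(parts, `[`, "", 2L),
                   cds = as.character(seqs),
                   mrna_length = as.integer(vapply(parts, `[`, "", 3L)),
                   stringsAsFactors = FALSE, row.names = NULL)
  dup <- unique(df$transcript_id[duplicated(df$transcript_id)])
  if (length(dup))
    stop("duplicate transcript ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(grepl("[^ACGT]", df$cds)))
    stop("CDS sequences must contain only A/C/G/T", call. = FALSE)
  if (any(df$mrna_length < nchar(df$cds)))
    stop("mrna_length must be at least the CDS length", call. = FALSE)
  df
}

#' Write coding sequences to FASTA
#'
#' Inverse of [read_transcripts()]: emits one record per row with a
#' `gene|transcript|mrna_length` header, 70-column wrapped.
#'
#' @param transcripts data.frame as returned by [read_transcripts()].
#' @param path output path.
#' @export
write_transcripts <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$cds)
  names(seqs) <- sprintf("%s|%s|%d", transcripts$gene_id,
                         transcripts$transcript_id, transcripts$mrna_length)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
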