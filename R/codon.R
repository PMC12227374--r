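# Codon usage analysis: representative transcript per gene (longest CDS,
# ties by longest mRNA), CDS validation, in-frame codon counting over gene
# sets, relative usage per amino acid, and percent-change / correlation
# summaries between translation classes.  The standard genetic code
# (Biostrings::GENETIC_CODE) is fixed; the three stop codons are grouped as
# one amino-acid class for relative-usage purposes.

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  data.frame(codon = names(gc), amino_acid = unname(gc),
             stringsAsFactors = FALSE)
}

#' Pick the representative transcript of a gene
#'
#' Rule 1: the transcript with the longest CDS.  Rule 2: among CDS-length
#' ties, the one with the longest mRNA.  A residual tie is broken by the
#' lexicographically smallest transcript id, so the choice is always
#' deterministic.
#'
#' @param records data.frame of the gene's transcripts (columns `gene_id`,
#'   `transcript_id`, `cds`, `mrna_length`).
#' @return the selected row (a one-row data.frame).
#' @export
select_representative_transcript <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame of transcripts",
         call. = FALSE)
  if (length(unique(records$gene_id)) != 1L)
    stop("all records must share one gene id", call. = FALSE)
  o <- order(-nchar(records$cds), -records$mrna_length,
             records$transcript_id)
  records[o[1L], , drop = FALSE]
}

#' Representative transcripts for every gene
#'
#' Applies [select_representative_transcript()]'s ordering to a whole
#' transcript table at once.
#'
#' @param transcripts data.frame as from [read_transcripts()].
#' @return data.frame with one row per gene.
#' @export
representative_transcripts <- function(transcripts) {
  o <- order(transcripts$gene_id, -nchar(transcripts$cds),
             -transcripts$mrna_length, transcripts$transcript_id)
  tx <- transcripts[o, , drop = FALSE]
  tx[!duplicated(tx$gene_id), , drop = FALSE]
}

#' Validate coding sequences
#'
#' A CDS is usable for codon counting iff its length is a multiple of 3,
#' it starts with ATG, and it ends with TAA, TAG or TGA.
#'
#' @param cds character vector of DNA strings (A/C/G/T only; anything else
#'   is an error).
#' @return logical vector with a `reasons` attribute giving, for each
#'   failure, which rule broke (`length`, `start`, `stop`); `"ok"` for
#'   passes.
#' @examples
#' validate_cds(c("ATGAAATAA", "ATGAAATA", "TTGAAATAA"))
#' @export
validate_cds <- function(cds) {
  if (any(grepl("[^ACGT]", cds)))
    stop("CDS contains characters outside A/C/G/T", call. = FALSE)
  n <- nchar(cds)
  ok_len <- n %% 3L == 0L & n >= 3L
  ok_start <- substr(cds, 1L, 3L) == "ATG"
  ok_stop <- substr(cds, n - 2L, n) %in% c("TAA", "TAG", "TGA")
  valid <- ok_len & ok_start & ok_stop
  reasons <- rep("ok", length(cds))
  reasons[!ok_stop] <- "stop"
  reasons[!ok_start] <- "start"
  reasons[!ok_len] <- "length"
  attr(valid, "reasons") <- reasons
  valid
}

#' Count codons over a gene set
#'
#' Aggregates in-frame codon counts across the representative CDSs of the
#' given genes and expresses each codon's usage as a percentage of all
#' codons encoding the same amino acid (stop codons form one class).
#' Transcripts failing [validate_cds()] and genes absent from the
#' transcript table are skipped and counted in attributes.
#'
#' @param gene_set character vector of gene ids.
#' @param transcripts transcript table; representative transcripts are
#'   selected per gene automatically.
#' @return a data.frame of class `codon_usage` with columns `codon`,
#'   `amino_acid`, `count`, `rel_usage` (percent within amino acid; `NaN`
#'   when the amino acid never occurs), and attributes `n_genes_used`,
#'   `n_skipped_invalid`, `n_missing`.
#' @export
count_codons <- function(gene_set, transcripts) {
  reps <- representative_transcripts(transcripts)
  hit <- reps[reps$gene_id %in% gene_set, , drop = FALSE]
  n_missing <- length(setdiff(gene_set, reps$gene_id))
  valid <- validate_cds(hit$cds)
  n_invalid <- sum(!valid)
  hit <- hit[valid, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("no usable CDS in the gene set (all missing or invalid)",
         call. = FALSE)
  counts <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(hit$cds), step = 3L))
  tab <- codon_table()
  tab$count <- as.integer(counts[tab$codon])
  aa_total <- tapply(tab$count, tab$amino_acid, sum)
  tab$rel_usage <- 100 * tab$count / aa_total[tab$amino_acid]
  structure(tab, class = c("codon_usage", "data.frame"),
            n_genes_used = nrow(hit), n_skipped_invalid = n_invalid,
            n_missing = n_missing)
}

#' Percent change of codon usage between two gene sets
#'
#' For each codon, the difference in relative usage (percentage points of
#' the codon's amino acid) between a "more translated" and a "less
#' translated" usage table.  Within each amino acid the changes sum to 0;
#' codons of an amino acid absent from either set are marked missing.
#'
#' @param more,less [count_codons()] tables.
#' @return data.frame with columns `codon`, `amino_acid`, `count_more`,
#'   `count_less`, `pct_more`, `pct_less`, `change`.
#' @export
percent_change <- function(more, less) {
  stopifnot(inherits(more, "codon_usage"), inherits(less, "codon_usage"))
  stopifnot(identical(more$codon, less$codon))
  out <- data.frame(codon = more$codon, amino_acid = more$amino_acid,
                    count_more = more$count, count_less = less$count,
                    pct_more = more$rel_usage, pct_less = less$rel_usage,
                    stringsAsFactors = FALSE)
  out$change <- out$pct_more - out$pct_less
  out$change[!is.finite(out$pct_more) | !is.finite(out$pct_less)] <- NA_real_
  out
}

#' Squared correlation of two codon-usage profiles
#'
#' Pearson r-squared over the codons shared by two usage vectors (or
#' tables, whose `rel_usage` is used), optionally excluding stop codons.
#'
#' @param table_a,table_b [count_codons()] tables or named numeric vectors
#'   keyed by codon.
#' @param exclude_stops drop TAA/TAG/TGA before correlating.
#' @return r-squared (single number).
#' @export
usage_correlation <- function(table_a, table_b, exclude_stops = FALSE) {
  as_vec <- function(x) {
    if (inherits(x, "codon_usage")) setNames(x$rel_usage, x$codon)
    else if (is.numeric(x) && !is.null(names(x))) x
    else stop("inputs must be codon_usage tables or named numeric vectors",
              call. = FALSE)
  }
  a <- as_vec(table_a); b <- as_vec(table_b)
  shared <- intersect(names(a), names(b))
  if (exclude_stops) shared <- setdiff(shared, c("TAA", "TAG", "TGA"))
  a <- a[shared]; b <- b[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L)
    stop("need at least 3 shared codons with finite usage", call. = FALSE)
  cor(a[ok], b[ok])^2
}

#' Partition genes into translation classes
#'
#' Splits an enrichment table (IP versus input of the whole-organism TRAP
#' experiment) into the "more highly translated" genes (log2 fold above the
#' threshold at BH-adjusted p below `alpha`) and the "less highly
#' translated" genes (log2 fold below the negated threshold, same
#' significance) — i.e. the `enriched` and `depleted` classes.
#'
#' @param enrichment a [trap_enrich()] table (or any data.frame with
#'   `gene_id`, `log2fc`, `p_adj`).
#' @param lfc_threshold,alpha thresholds (defaults 0.35, 0.05).
#' @return list with disjoint character vectors `more` and `less`.
#' @export
translation_partition <- function(enrichment, lfc_threshold = 0.35,
                                  alpha = 0.05) {
  tab <- classify_enrichment(as.data.frame(enrichment),
                             lfc_threshold = lfc_threshold, alpha = alpha)
  list(more = tab$gene_id[tab$class == "enriched"],
       less = tab$gene_id[tab$class == "depleted"])
}
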