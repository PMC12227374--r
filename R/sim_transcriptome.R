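# Synthetic transcriptomes with planted codon bias between translation
# classes, for validating the codon-usage pipeline end to end.

# codons grouped by amino acid under the standard code
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Default planted codon bias
#'
#' A weight map emulating the codon-optimality signal of highly translated
#' genes: within every amino acid, codons ending in C or G (high GC3, the
#' composition enriched among highly expressed zebrafish genes) receive
#' weight `strength` in the `high` class; the `low` class is uniform.
#'
#' @param strength relative weight of the favoured codons (default 3).
#' @return list of two named weight vectors (`high`, `low`) over all 64
#'   codons.
#' @export
default_codon_bias <- function(strength = 3) {
  gc <- Biostrings::GENETIC_CODE
  w_high <- setNames(rep(1, length(gc)), names(gc))
  gc3 <- substr(names(gc), 3L, 3L) %in% c("C", "G")
  w_high[gc3] <- strength
  list(high = w_high, low = setNames(rep(1, length(gc)), names(gc)))
}

check_weights <- function(weights, classes) {
  by_aa <- codons_by_aa()
  for (cl in classes) {
    w <- weights[[cl]]
    if (is.null(w))
      stop_param("biased_codons", paste0("no weight vector for class `",
                                         cl, "`"))
    if (any(w < 0, na.rm = TRUE))
      stop_param("biased_codons", "weights must be non-negative")
    for (aa in names(by_aa)) {
      tot <- sum(w[by_aa[[aa]]], na.rm = TRUE)
      if (!is.finite(tot) || tot <= 0)
        stop_param("biased_codons",
                   sprintf("weights for amino acid %s in class `%s` are not normalizable",
                           aa, cl))
    }
  }
  invisible(weights)
}

#' Simulate a transcriptome with planted codon bias
#'
#' Generates one or more transcripts per gene.  Every CDS starts with ATG,
#' ends with one of TAA/TAG/TGA and has length divisible by 3, so all
#' emitted CDSs pass [validate_cds()] by construction.  Each gene belongs
#' to one class; within an amino acid, internal codons are drawn with the
#' class's relative weights, so the planted between-class difference in
#' relative usage equals the difference of normalized weights.  Amino acids
#' themselves are drawn uniformly; the stop codon is drawn from the class's
#' stop weights.
#'
#' A fraction of genes receives a second transcript — half of them with a
#' shorter CDS (exercising the longest-CDS rule), half with an equal-length
#' CDS but different mRNA length (exercising the tie-break rule).
#'
#' @param n_genes number of genes.
#' @param class_fractions named proportions per class, summing to 1
#'   (default `c(high = 0.5, low = 0.5)`).
#' @param biased_codons list of per-class codon weight vectors
#'   (default [default_codon_bias()] for classes `high`/`low`; uniform for
#'   any other class name).
#' @param length_range range (in internal codons, excluding start and
#'   stop) of the uniform CDS length law.
#' @param multi_tx_prob probability a gene gets a second transcript.
#' @param seed integer seed.
#' @return list of class `sim_transcriptome` with `transcripts` (data.frame
#'   `gene_id`, `transcript_id`, `cds`, `mrna_length`) and `truth`
#'   (data.frame `gene_id`, `class`).
#' @examples
#' sim <- simulate_transcriptome(20, seed = 3)
#' all(validate_cds(sim$transcripts$cds))
#' @export
simulate_transcriptome <- function(n_genes,
                                   class_fractions = c(high = 0.5, low = 0.5),
                                   biased_codons = NULL,
                                   length_range = c(50, 300),
                                   multi_tx_prob = 0.2,
                                   seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  if (is.null(names(class_fractions)) ||
      abs(sum(class_fractions) - 1) > 1e-8 || any(class_fractions < 0))
    stop_param("class_fractions",
               "must be named non-negative proportions summing to 1")
  classes <- names(class_fractions)
  if (is.null(biased_codons)) {
    biased_codons <- default_codon_bias()
    uni <- setNames(rep(1, 64), names(Biostrings::GENETIC_CODE))
    for (cl in setdiff(classes, names(biased_codons)))
      biased_codons[[cl]] <- uni
  }
  check_weights(biased_codons, classes)
  check_prob(multi_tx_prob, "multi_tx_prob")
  if (length(length_range) != 2L || any(length_range < 1) ||
      diff(length_range) < 0)
    stop_param("length_range", "must be an increasing pair of codon counts")

  set.seed(seed)
  by_aa <- codons_by_aa()
  aas <- setdiff(names(by_aa), "*")
  gene_ids <- sprintf("sg%0*d", nchar(n_genes), seq_len(n_genes))
  class <- sample(classes, n_genes, replace = TRUE, prob = class_fractions)

  draw_cds <- function(n_codon, cl) {
    w <- biased_codons[[cl]]
    aa_seq <- sample(aas, n_codon, replace = TRUE)
    inner <- vapply(aa_seq, function(aa) {
      cod <- by_aa[[aa]]
      if (length(cod) == 1L) cod else sample(cod, 1L, prob = w[cod])
    }, character(1))
    stops <- by_aa[["*"]]
    stop_codon <- sample(stops, 1L, prob = w[stops])
    paste0("ATG", paste(inner, collapse = ""), stop_codon)
  }

  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    L <- sample(seq(length_range[1], length_range[2]), 1L)
    cds1 <- draw_cds(L, class[i])
    utr1 <- sample(100:1500, 1L)
    rec <- data.frame(gene_id = gene_ids[i],
                      transcript_id = paste0(gene_ids[i], ".t1"),
                      cds = cds1, mrna_length = nchar(cds1) + utr1,
                      stringsAsFactors = FALSE)
    if (runif(1) < multi_tx_prob) {
      if (runif(1) < 0.5 && L > length_range[1]) {
        L2 <- sample(seq(length_range[1], L - 1L), 1L)  # strictly shorter CDS
        cds2 <- draw_cds(L2, class[i])
      } else {
        cds2 <- draw_cds(L, class[i])                   # CDS-length tie
      }
      utr2 <- sample(100:1500, 1L)
      rec <- rbind(rec, data.frame(
        gene_id = gene_ids[i],
        transcript_id = paste0(gene_ids[i], ".t2"),
        cds = cds2, mrna_length = nchar(cds2) + utr2,
        stringsAsFactors = FALSE))
    }
    rows[[i]] <- rec
  }
  structure(list(transcripts = do.call(rbind, rows),
                 truth = data.frame(gene_id = gene_ids, class = class,
                                    stringsAsFactors = FALSE)),
            class = "sim_transcriptome")
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  tab <- table(x$truth$class)
  cat(sprintf("Simulated transcriptome: %d genes, %d transcripts (%s)\n",
              nrow(x$truth), nrow(x$transcripts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
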