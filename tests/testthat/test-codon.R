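tx_row <- function(gene, tx, cds, mrna) {
  data.frame(gene_id = gene, transcript_id = tx, cds = cds,
             mrna_length = mrna, stringsAsFactors = FALSE)
}

test_that("representative transcript follows the two rules and tie-break", {
  one <- tx_row("g1", "t1", "ATGAAATAA", 300)
  expect_equal(select_representative_transcript(one)$transcript_id, "t1")

  two <- rbind(tx_row("g1", "t1", strrep("ATGAAATAA", 1), 900),
               tx_row("g1", "t2", paste0("ATG", strrep("AAA", 148), "TAA"),
                      600))
  expect_equal(select_representative_transcript(two)$transcript_id, "t2")

  tie <- rbind(tx_row("g1", "t1", "ATGAAATAA", 900),
               tx_row("g1", "t2", "ATGCCCTAA", 1200))
  expect_equal(select_representative_transcript(tie)$transcript_id, "t2")

  # residual tie after both rules: lexicographically smallest transcript id
  full_tie <- rbind(tx_row("g1", "tB", "ATGAAATAA", 900),
                    tx_row("g1", "tA", "ATGCCCTAA", 900))
  expect_equal(select_representative_transcript(full_tie)$transcript_id, "tA")

  expect_error(select_representative_transcript(one[0, ]), "non-empty")
  expect_error(select_representative_transcript(
    rbind(tx_row("g1", "t1", "ATGAAATAA", 1),
          tx_row("g2", "t2", "ATGAAATAA", 1))), "one gene id")

  # the vectorized version agrees gene by gene
  tx <- rbind(two, tx_row("g2", "u1", "ATGTAA", 100),
              tx_row("g2", "u2", "ATGTAA", 200))
  reps <- representative_transcripts(tx)
  expect_equal(reps$transcript_id[reps$gene_id == "g1"], "t2")
  expect_equal(reps$transcript_id[reps$gene_id == "g2"], "u2")
})

test_that("CDS validation enforces length, start and stop rules", {
  v <- validate_cds(c("ATGAAATAA", "ATGAAATA", "TTGAAATAA", "ATGAAAAAA"))
  expect_equal(as.logical(v), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(v, "reasons"), c("ok", "length", "start", "stop"))
  expect_error(validate_cds("ATGNNNTAA"), "A/C/G/T")
})

test_that("codon counting: single CDS arithmetic and doubling", {
  tx <- tx_row("g1", "t1", "ATGAAATAA", 100)
  u <- count_codons("g1", tx)
  expect_s3_class(u, "codon_usage")
  cnt <- setNames(u$count, u$codon)
  expect_equal(unname(cnt[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(cnt), 3L)
  rel <- setNames(u$rel_usage, u$codon)
  expect_equal(unname(rel["AAA"]), 100)
  expect_equal(unname(rel["AAG"]), 0)

  tx2 <- rbind(tx, tx_row("g2", "t2", "ATGAAATAA", 100))
  u2 <- count_codons(c("g1", "g2"), tx2)
  expect_equal(u2$count, 2L * u$count)
  expect_equal(u2$rel_usage, u$rel_usage)
})

test_that("codon counting equals the brute-force oracle on random sets", {
  set.seed(11)
  sim <- simulate_transcriptome(50, seed = 12)
  reps <- representative_transcripts(sim$transcripts)
  u <- count_codons(sim$truth$gene_id, sim$transcripts)
  ora <- oracle_codon_counts(reps$cds)
  expect_equal(setNames(u$count, u$codon)[names(ora)], ora)
})

test_that("counting is additive over disjoint gene sets", {
  sim <- simulate_transcriptome(40, seed = 13)
  g <- sim$truth$gene_id
  a <- count_codons(g[1:20], sim$transcripts)
  b <- count_codons(g[21:40], sim$transcripts)
  both <- count_codons(g, sim$transcripts)
  expect_equal(both$count, a$count + b$count)
})

test_that("invalid and missing genes are skipped with counts", {
  tx <- rbind(tx_row("g1", "t1", "ATGAAATAA", 100),
              tx_row("g2", "t2", "ATGAAAT", 100))   # invalid length
  u <- count_codons(c("g1", "g2", "g3"), tx)
  expect_equal(attr(u, "n_genes_used"), 1L)
  expect_equal(attr(u, "n_skipped_invalid"), 1L)
  expect_equal(attr(u, "n_missing"), 1L)
  expect_error(count_codons("g9", tx), "no usable CDS")
})

test_that("relative usage sums to 100 per amino acid and changes to 0", {
  sim <- simulate_transcriptome(60, seed = 14)
  more <- sim$truth$gene_id[sim$truth$class == "high"]
  less <- sim$truth$gene_id[sim$truth$class == "low"]
  um <- count_codons(more, sim$transcripts)
  ul <- count_codons(less, sim$transcripts)
  for (u in list(um, ul)) {
    sums <- tapply(u$rel_usage, u$amino_acid, sum)
    tot <- tapply(u$count, u$amino_acid, sum)
    expect_true(all(abs(sums[tot > 0] - 100) < 1e-9))
  }
  chg <- percent_change(um, ul)
  by_aa <- tapply(chg$change, chg$amino_acid, sum)
  expect_true(all(abs(by_aa[!is.na(by_aa)]) < 1e-9))
  # single-codon amino acids never change
  expect_equal(chg$change[chg$codon == "ATG"], 0)
  expect_equal(chg$change[chg$codon == "TGG"], 0)
})

test_that("percent change: identity, hand case, and planted-bias recovery", {
  sim <- simulate_transcriptome(30, seed = 15)
  u <- count_codons(sim$truth$gene_id, sim$transcripts)
  same <- percent_change(u, u)
  expect_true(all(same$change[!is.na(same$change)] == 0))

  # hand case: Lys usage 80/20 vs 50/50 -> +30 / -30
  mk <- function(aaa, aag) {
    tx <- rbind(
      tx_row("h1", "x1", paste0("ATG", strrep("AAA", aaa),
                                strrep("AAG", aag), "TAA"), 1000))
    count_codons("h1", tx)
  }
  chg <- percent_change(mk(8, 2), mk(5, 5))
  expect_equal(chg$change[chg$codon == "AAA"], 30)
  expect_equal(chg$change[chg$codon == "AAG"], -30)

  # planted bias: class high prefers AAA for Lys 3:1, class low uniform
  w_high <- setNames(rep(1, 64), names(Biostrings::GENETIC_CODE))
  w_high["AAA"] <- 3
  bias <- list(high = w_high,
               low = setNames(rep(1, 64), names(Biostrings::GENETIC_CODE)))
  sim2 <- simulate_transcriptome(300, biased_codons = bias,
                                 length_range = c(100, 200), seed = 16)
  more <- sim2$truth$gene_id[sim2$truth$class == "high"]
  less <- sim2$truth$gene_id[sim2$truth$class == "low"]
  chg2 <- percent_change(count_codons(more, sim2$transcripts),
                         count_codons(less, sim2$transcripts))
  # planted: 75% vs 50% usage of AAA -> +25 percentage points
  expect_equal(chg2$change[chg2$codon == "AAA"], 25, tolerance = 2.5)
  expect_equal(chg2$change[chg2$codon == "AAG"], -25, tolerance = 2.5)
})

test_that("extreme planted bias gives the closed-form 100-point change", {
  w_high <- setNames(rep(1, 64), names(Biostrings::GENETIC_CODE))
  w_low <- w_high
  w_high["AAG"] <- 0   # class high uses only AAA for Lys
  w_low["AAA"] <- 0    # class low uses only AAG
  sim <- simulate_transcriptome(60, biased_codons = list(high = w_high,
                                                         low = w_low),
                                seed = 17)
  more <- sim$truth$gene_id[sim$truth$class == "high"]
  less <- sim$truth$gene_id[sim$truth$class == "low"]
  chg <- percent_change(count_codons(more, sim$transcripts),
                        count_codons(less, sim$transcripts))
  expect_equal(chg$change[chg$codon == "AAA"], 100)
  expect_equal(chg$change[chg$codon == "AAG"], -100)
})

test_that("uniform weights give near-zero changes everywhere", {
  uni <- setNames(rep(1, 64), names(Biostrings::GENETIC_CODE))
  sim <- simulate_transcriptome(400, biased_codons = list(high = uni,
                                                          low = uni),
                                length_range = c(100, 200), seed = 18)
  more <- sim$truth$gene_id[sim$truth$class == "high"]
  less <- sim$truth$gene_id[sim$truth$class == "low"]
  chg <- percent_change(count_codons(more, sim$transcripts),
                        count_codons(less, sim$transcripts))
  # MC error: ~1.5k codons per amino acid and class, so per-codon usage has
  # a ~1.3 percentage-point standard error; the difference stays within a
  # few points and averages near zero
  expect_lt(max(abs(chg$change), na.rm = TRUE), 8)
  expect_equal(mean(abs(chg$change), na.rm = TRUE), 0, tolerance = 2)
})

test_that("usage correlation: identity, sign-invariance, hand Pearson", {
  sim <- simulate_transcriptome(30, seed = 19)
  u <- count_codons(sim$truth$gene_id, sim$transcripts)
  expect_equal(usage_correlation(u, u), 1)
  v <- setNames(u$rel_usage, u$codon)
  expect_equal(usage_correlation(v, -v), 1)
  x <- c(AAA = 1, AAG = 4, GGG = 2, GGA = 7, TTT = 3)
  y <- c(AAA = 2, AAG = 3, GGG = 5, GGA = 6, TTT = 1)
  expect_equal(usage_correlation(x, y), oracle_r2(x, y), tolerance = 1e-12)
  expect_error(usage_correlation(x[1:2], y[1:2]), "at least 3")
  # excluding stops drops them from the shared set
  x2 <- c(x, TAA = 100); y2 <- c(y, TAA = -100)
  expect_equal(usage_correlation(x2, y2, exclude_stops = TRUE),
               oracle_r2(x, y), tolerance = 1e-12)
})

test_that("translation partition mirrors the enrichment classes", {
  tab <- data.frame(gene_id = paste0("g", 1:4),
                    log2fc = c(1, -1, 0.2, 0.5),
                    p_adj = c(0.01, 0.01, 0.01, 0.5))
  part <- translation_partition(tab)
  expect_equal(part$more, "g1")
  expect_equal(part$less, "g2")
  expect_length(intersect(part$more, part$less), 0)
})

test_that("simulated transcriptomes are constructively valid and deterministic", {
  a <- simulate_transcriptome(50, multi_tx_prob = 0.5, seed = 20)
  b <- simulate_transcriptome(50, multi_tx_prob = 0.5, seed = 20)
  expect_identical(a, b)
  expect_true(all(validate_cds(a$transcripts$cds)))
  expect_true(all(a$transcripts$mrna_length >= nchar(a$transcripts$cds)))
  expect_true(any(duplicated(a$transcripts$gene_id)))  # multi-transcript genes
  expect_error(simulate_transcriptome(10, class_fractions = c(h = 0.7)),
               "class_fractions")
  bad <- list(high = setNames(rep(0, 64), names(Biostrings::GENETIC_CODE)))
  expect_error(simulate_transcriptome(10,
                                      class_fractions = c(high = 1),
                                      biased_codons = bad),
               "not normalizable")
})
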