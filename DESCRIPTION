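Package: trapseq
Title: TRAP-RNAseq Translatome Enrichment, Tissue-Specific Gene Selection,
    and Sequence Feature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for translating ribosome affinity purification
    (TRAP) RNA-seq experiments that profile a cell type's translatome by
    comparing immunoprecipitated (IP) polysomal mRNA against matched total
    lysate (input).  Provides negative-binomial GLM enrichment testing
    (median-of-ratios size factors, trended empirical-Bayes dispersion
    estimation, two- and one-sided Wald tests, a likelihood-ratio test for
    the interaction "ratio of ratios" design), a multi-dimensional
    pairwise-comparison selection procedure (per-gene Holm correction with
    across-gene false discovery rate control) for shared and organ-unique
    endothelial genes, codon usage bias analysis of highly versus lowly
    translated gene sets, CRISPR deletion allele characterization from
    wild-type/mutant sequence pairs, and a negative-binomial count simulator
    so the whole pipeline runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
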