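---
title: "Models and methods behind trapseq"
author: "trapseq authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Translating ribosome affinity purification (TRAP) profiles the mRNAs a cell
type is actively translating: ribosomes carrying an epitope-tagged Rpl10a
are immunoprecipitated from a tissue homogenate, and the co-purified mRNA
(the **IP** library) is sequenced alongside the matched total-lysate mRNA
(the **input** library).  A gene enriched in IP over input is being
translated in the tagged cell population — in the motivating application,
the endothelium of zebrafish larvae and of dissected adult organs, with a
whole-animal TRAP as control.

`trapseq` implements the complete downstream analysis: negative-binomial
enrichment testing of IP versus input, the multi-dimensional
multiple-testing procedure that selects endothelial genes shared across all
organs or unique to one organ, codon-usage analysis of highly versus lowly
translated gene sets, and characterization of CRISPR deletion alleles.  A
negative-binomial simulator generates data with the same structure, so the
whole pipeline is testable without any external download.

# Enrichment model

Counts for gene $g$ in library $j$ are modelled as negative binomial,

$$K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
  \mu_{gj} = s_j \exp(x_j^\top \beta_g), \qquad
  \mathrm{Var}(K_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2,$$

with per-library size factors $s_j$ (median-of-ratios: the median across
genes of the ratio of a library's counts to the gene's geometric mean,
rescaled to geometric mean 1) and a log-linear design.  Two designs are
built in:

* `condition`: `~ fraction` — one IP-versus-input contrast; the enrichment
  coefficient is reported in log2 units and tested with a Wald statistic
  $z = \hat\beta/\widehat{se}$ against a standard-normal reference,
  two-sided or one-sided (IP greater).
* `interaction`: `~ experiment + fraction + experiment:fraction` — the
  interaction coefficient is the log "ratio of ratios", i.e. the difference
  in IP/input enrichment between two experiments (endothelial versus
  whole-animal TRAP).  It is tested by a likelihood-ratio test against the
  reduced model without the interaction, $2(\ell_{full}-\ell_{red})$ on one
  chi-square degree of freedom.

All genes share the design matrix, so the per-gene IRLS normal equations
are solved for the whole matrix at once — genome-scale fitting in pure R
takes well under a second for 2000 genes.

Genes are classified **enriched** when $\log_2 FC > 0.35$ with
BH-adjusted $p < 0.05$, **depleted** below $-0.35$ at the same
significance (both inequalities strict), and unclassified otherwise.  The
same partition defines the "more highly translated" and "less highly
translated" gene sets of the codon-usage analysis.

## Dispersion estimation

With triplicate libraries a gene contributes only ~4 residual degrees of
freedom, far too few to estimate its own dispersion: plugging gene-wise
estimates into the Wald statistic makes it behave like a t variable read
off a normal table, and null p-values stop being uniform.  The default
estimator therefore borrows strength across genes, in three steps:

1. **Pooled trend.** Genes are binned by mean normalized count (about 50
   genes per bin) and one dispersion per bin is estimated by maximizing the
   bin's *summed* Cox–Reid-adjusted profile log-likelihood on a log-spaced
   grid.  Pooling gives the trend hundreds of degrees of freedom per bin,
   which avoids two biases we measured for per-gene-MLE trends: the
   downward bias of averaging log-scale MLEs
   ($\psi((n-p)/2) - \log((n-p)/2) \approx -0.27$ at 4 df) and the upward
   bias from discarding boundary-zero estimates at low means.  The bin
   estimates are smoothed by lowess.
2. **Prior width.** The spread of true dispersions around the trend is
   estimated as
   $\max(\mathrm{mad}^2(\log\hat\alpha_g - \log\alpha_{tr}) -
   \psi_1((n-p)/2),\ 0.01)$ over well-measured genes — the observed scatter
   minus the known sampling noise of a log-dispersion estimate.
3. **Posterior mean.** Each gene's final $\alpha_g$ is the posterior mean
   of its Cox–Reid likelihood under a log-normal prior centred on the
   trend with that width.

Under null simulations at 3 versus 3 this keeps the normal-reference Wald
test calibrated (Kolmogorov–Smirnov uniformity holds in essentially every
run at 2000 genes; rejection at nominal 5% stays within 3–7%).  Two
simpler estimators remain available: `"moments"` (per-gene chi-square
matching, the textbook method-of-moments with a $10^{-8}$ floor) and
`"ml"` (per-gene Cox–Reid maximum without shrinkage); both are useful for
method comparisons but are *not* calibrated at triplicate scale.  Exact
replication of any external tool's shrinkage (fit types, outlier
handling, independent filtering, fold-change shrinkage) is out of scope by
design; classifications use the raw maximum-likelihood log2 fold changes.

## Numerical conventions

* Expected counts may be fractional (RSEM convention); they enter the IRLS
  moment equations unchanged and are rounded half-to-even only inside the
  log-likelihood, which is defined on integers.
* Linear predictors are clamped to $\pm 30$ on the natural-log scale;
  non-converged genes are flagged and their p-values left missing.
  Missing p-values are replaced by 1 only inside the selection stage,
  where an absent comparison is treated as uninformative.
* Genes with zero counts in every sample are removed from the gene
  universe (and logged); genes all-zero in one condition keep their GLM
  test but report a log2 fold change computed from group means with a 0.5
  pseudo-count, since the GLM coefficient runs to the boundary.
* The internal fit is on the natural-log scale; every reported fold change
  and standard error is converted to log2 by a fixed $1/\log 2$ factor.

# Multi-dimensional selection

To find genes enriched in *every* tissue (shared endothelial genes), raw
one-sided p-values are arranged as a genes × comparisons grid and passed
through:

1. missing values → 1; Holm step-down correction across comparisons
   *within* each gene;
2. across genes, BH FDR on the gene-wise *minimal* Holm-corrected p;
3. $R$ = fraction of genes with FDR < 0.1;
4. each comparison selects genes with Holm-corrected $p < 0.1 \times R$
   and FDR < 0.1;
5. the shared set is the intersection across comparisons.

The constant 0.1 plays both roles (the FDR level and the scale of the
per-comparison cut), as a single configurable `fdr_level`.  If $R = 0$ the
cut is 0 and every selection is empty; the function warns rather than
inventing a fallback.  A display-strength filter retains, from the
intersection, genes with $\log_2 FC \ge 1.2$ (inclusive) and per-comparison
BH $p < 0.05$ in every tissue.

**Organ-unique genes** are found in two steps.  The pre-screen runs the
same machinery independently on two grids — tissue IP over its own input,
and tissue IP over the whole-organism control IP — and intersects the two
selections per tissue.  The dominance screen then keeps a candidate for
tissue $T$ only if (1) it was pre-screened for $T$; (2) it passes the
omnibus FDR < 0.1 over all ordered pairwise IP-versus-IP comparisons
(minimum within-gene Holm p, BH across genes); (3) every "$T$ above other"
comparison has Holm-corrected $p < 0.1 \times R$; and (4) the *minimum*
of $T$'s IP replicates exceeds, strictly, every IP replicate of every
other tissue on size-factor-normalized counts.  Pairwise IP tests reuse
the one-sided Wald machinery with dispersions estimated once across all IP
samples under the tissue cell-means design, so every pair sees the same
gene-wise dispersion.

Finally three fold filters act on mean normalized expression: IP at least
1.5-fold above the tissue's own input; IP at least 2-fold above the
next-highest tissue's IP; and the IP difference to that next tissue at
least twice their input difference.  All bounds are inclusive.  Two
genuinely open choices are exposed rather than resolved: the filters'
scale (`fold`, the default, or `log2`, since the two descriptions of these
thresholds circulate in both units — on the log2 scale the same constants
act on log2 differences of pseudo-counted means), and the meaning of
"difference" in the third filter, implemented as the difference on the
configured scale with per-gene diagnostics emitted so the filter can be
audited.  A gene whose IP expression ties exactly with another tissue's is
assigned to neither tissue — uniqueness cannot be claimed on a tie.

# Codon usage

One representative transcript per gene: the longest CDS, ties broken by
the longest mRNA, residual ties by the lexicographically smallest
transcript id (deterministic; the last rule is this package's own
tie-break).  A CDS is usable iff its length is a multiple of three, it
starts with ATG and ends with TAA/TAG/TGA; unusable CDSs and genes missing
from the transcript table are skipped and counted.  Codons are counted in
frame across the gene set, and each codon's **relative usage** is its
share (in %) of all codons encoding the same amino acid; the three stop
codons are grouped as one class, and single-codon amino acids (Met, Trp)
are included — their usage is 100% and their change identically 0.  The
percent change between the "more" and "less" translated sets is the
difference of relative usages, which sums to 0 within each amino acid;
profile similarity is summarized by Pearson $r^2$, optionally excluding
stops.

# Deletion characterization

Printed exon coordinates are 1-based inclusive, so a span's length is
$end - start + 1$ and the span-based deletion length is the difference of
the two span lengths.  Independently, the wild-type/mutant pair is aligned:
if the mutant is exactly the wild type minus one contiguous block, the
block is found by prefix/suffix matching and placed at its **leftmost**
equivalent position (standard indel normalization); otherwise a global
affine-gap alignment (which prefers one contiguous gap) reports the net
length difference and mismatch count.  Span- and alignment-based lengths
are reported side by side and any disagreement is flagged — the bundled
published sequence pairs themselves contain one such inconsistency (a
wild-type string one base short of its printed span), which the package
surfaces rather than repairs.  Truncated protein length counts amino acids
*before* the first in-frame stop ("truncated after 77 amino acids" ↔ 77
residues); a trailing partial codon, routine in frameshifted alleles, is
ignored.

# The synthetic data generator

`simulate_counts()` emulates the structure the analyses assume: several
tissues plus a whole-organism control, paired IP/input libraries in
triplicate, gene baselines log-uniform on $[5, 5000]$, multiplicative
library-size factors uniform on $[0.5, 2]$, and gene-wise NB dispersions.
Planted classes carry the signal: tissue-`enriched` genes (log2 fold 2 in
one tissue's IP), `shared` genes (enriched in every tissue, optionally
with tissue-specific folds — that is how an interaction signal is
planted), and organ-`unique` genes (log2 fold 3, i.e. the eight-fold
dominance the unique screen targets).  A truth table records every gene's
class and planted fold per tissue.  One RNG is seeded per call; identical
designs give bit-identical output.

Dispersions default to log-normal with median 0.05 and log-scale spread
0.25.  The median matches the moderate biological variability expected
when every replicate pools many animals (triplicates of pooled larvae;
several adult fish per replicate), and 0.25 is the canonical prior width
assumed for log-dispersion scatter around the trend in bulk RNA-seq
practice; it is also the regime in which a trended plug-in estimator can
keep a normal-reference Wald test calibrated at triplicate scale — with a
much wider scatter no estimator can, since a gene's own dispersion is then
unknowable from 4 residual degrees of freedom.

`simulate_transcriptome()` plants codon bias: within each amino acid,
codons are drawn with class-specific weights (default: codons ending C/G
up-weighted 3:1 in the "high" class, mirroring the GC3 preference of
highly expressed zebrafish genes), every CDS is constructively valid, and
a fraction of genes receives a second transcript to exercise the
representative-transcript rules.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: sample outliers and batch effects, correlated
genes and co-regulated modules, rRNA or cross-tissue contamination, the
stress-response transcription induced by cell dissociation, and
zero-inflation beyond the NB.  One real-data effect it *does* reproduce is
composition bias: with a large one-sided planted fraction, median-of-ratios
normalization absorbs part of the signal (the recovered interaction
coefficient of 1.0 reads ≈ 0.90 with 20% of genes planted), exactly as in
real global shifts of translation.

# Validation problem sizes

The shipped checks run at the scale the methods are meant for while
staying quick: null calibration on 200 simulations of 2000 genes at 3
versus 3; fold-change recovery at 6 versus 6 with dispersion 0.05;
interaction recovery on 1500 genes; the organ-unique screen on 2000 genes
across five organs plus control; oracle equivalence of Holm, BH,
median-of-ratios, codon counting, Pearson $r^2$ and translate-and-scan on
100 random instances each.  `scripts/acceptance.R` recomputes all of these
from scratch.

# Known limitations

* No outlier detection (Cook's-style), no independent filtering, no
  fold-change shrinkage: the package reports raw MLE folds, and single
  aberrant replicates will propagate.
* The Wald/LRT normal and chi-square references are asymptotic; at very
  low counts (means below ~5) p-values become conservative.
* The dominance screen's replicate-minimum criterion is intentionally
  strict and loses sensitivity quickly as replicate noise grows.
* Gene-level headline counts from the motivating study depend on its
  deposited real data and are not reproduced here; the package validates
  the *methods* on synthetic data with known truth.
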