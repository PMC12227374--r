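#' Benjamini-Hochberg adjustment with missing values
#'
#' Standard step-up BH adjustment across the non-missing entries; missing
#' p-values are left missing (non-converged genes keep their flag until the
#' selection stage, which is where missing comparisons are treated as 1).
#'
#' @param p numeric vector of raw p-values in \[0, 1\], `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Classify genes by enrichment
#'
#' Labels each gene `enriched` if its log2 fold change exceeds the
#' threshold and its adjusted p-value is below `alpha`, `depleted` if the
#' fold change is below the negated threshold at the same significance, and
#' `unclassified` otherwise.  Both inequalities are strict, so a gene
#' sitting exactly on the fold threshold is not classified.
#'
#' @param table data.frame with columns `log2fc` and `p_adj`.
#' @param lfc_threshold positive log2 fold-change threshold (default 0.35).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return `table` with a `class` factor column added (or replaced).
#' @export
classify_enrichment <- function(table, lfc_threshold = 0.35, alpha = 0.05) {
  stopifnot(is.data.frame(table), all(c("log2fc", "p_adj") %in% names(table)))
  cls <- rep("unclassified", nrow(table))
  sig <- !is.na(table$p_adj) & table$p_adj < alpha
  cls[sig & table$log2fc > lfc_threshold] <- "enriched"
  cls[sig & table$log2fc < -lfc_threshold] <- "depleted"
  table$class <- factor(cls, levels = c("enriched", "depleted", "unclassified"))
  table
}

#' Test IP versus input enrichment gene by gene
#'
#' The central enrichment analysis: per-gene negative-binomial GLMs relate
#' expected counts to the sample factors, and each gene's IP/input log2
#' fold change is tested by a Wald test (`design = "condition"`) or, for
#' the two-experiment contrast, by a likelihood-ratio test on the
#' interaction coefficient (`design = "interaction"`, the "ratio of
#' ratios": does TRAP enrichment differ between the two experiments?).
#'
#' Size factors default to median-of-ratios on the supplied matrix;
#' dispersions default to the trended empirical-Bayes estimator
#' ([estimate_dispersion()]).  Genes with zero counts in every sample are
#' removed before testing (and listed in `attr(x, "removed_genes")`).
#' P-values are BH-adjusted and genes classified at the given thresholds.
#'
#' For genes where one condition is all zeros the GLM coefficient runs to
#' the boundary; the reported `log2fc` for such genes is computed from
#' normalized group means with a 0.5 pseudo-count (testing still uses the
#' GLM).
#'
#' @param counts gene-by-sample count matrix.
#' @param samples sample sheet data.frame (columns `sample`, `tissue`,
#'   `fraction`, `replicate`, `experiment`); rows are matched to the count
#'   columns by `sample`.
#' @param design `"condition"` for a single IP-vs-input comparison, or
#'   `"interaction"` for the ratio-of-ratios contrast between two
#'   experiments.
#' @param tissue for `design = "condition"`: restrict to one tissue
#'   (defaults to all samples provided, which must then form one
#'   IP/input pair set).
#' @param experiments for `design = "interaction"`: character vector of the
#'   two experiment labels to contrast (defaults to the two levels present).
#' @param sided `"two"` or `"greater"` (one-sided Wald, IP above input);
#'   ignored for the likelihood-ratio test.
#' @param lfc_threshold,alpha classification thresholds (see
#'   [classify_enrichment()]).
#' @param size_factors optional per-sample factors; estimated when `NULL`.
#' @param dispersion_method passed to [estimate_dispersion()].
#' @return a data.frame of class `trap_enrichment` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `p_raw`, `p_adj`, `class`, and
#'   attributes `design`, `size_factors`, `dispersions`, `removed_genes`.
#' @examples
#' sim <- simulate_counts(sim_design(n_genes = 200, tissues = "fish",
#'   control = "fish", frac_enriched = 0.1, lfc_enriched = 2, seed = 42))
#' res <- trap_enrich(sim$counts, sim$samples)
#' summary(res)
#' @export
trap_enrich <- function(counts, samples,
                        design = c("condition", "interaction"),
                        tissue = NULL, experiments = NULL,
                        sided = c("two", "greater"),
                        lfc_threshold = 0.35, alpha = 0.05,
                        size_factors = NULL,
                        dispersion_method = "shrink") {
  design <- match.arg(design)
  sided <- match.arg(sided)
  samples <- check_counts_samples(counts, samples)

  if (design == "condition") {
    if (!is.null(tissue)) {
      keep <- samples$tissue %in% tissue
      counts <- counts[, keep, drop = FALSE]
      samples <- samples[keep, , drop = FALSE]
    }
    frac <- factor(samples$fraction, levels = c("input", "IP"))
    if (nlevels(droplevels(frac)) != 2L)
      stop("condition design needs both IP and input samples", call. = FALSE)
    X <- cbind(`(Intercept)` = 1, fractionIP = as.numeric(frac == "IP"))
  } else {
    if (is.null(experiments)) experiments <- unique(samples$experiment)
    if (length(experiments) != 2L)
      stop("interaction design needs exactly two experiments", call. = FALSE)
    keep <- samples$experiment %in% experiments
    counts <- counts[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
    expB <- as.numeric(samples$experiment == experiments[2])
    ip <- as.numeric(samples$fraction == "IP")
    X <- cbind(`(Intercept)` = 1, experiment = expB, fractionIP = ip,
               `experiment:fractionIP` = expB * ip)
  }

  allzero <- rowSums(counts) == 0
  removed <- rownames(counts)[allzero]
  if (length(removed))
    message(sprintf("removed %d all-zero gene(s) before testing",
                    length(removed)))
  K <- counts[!allzero, , drop = FALSE]

  if (is.null(size_factors)) size_factors <- estimate_size_factors(K)
  disp <- estimate_dispersion(K, size_factors, X, method = dispersion_method)

  fit <- fit_nb_glm(K, X, size_factors, disp)
  test_coef <- ncol(X)  # enrichment (or interaction) coefficient is last
  if (design == "condition") {
    w <- wald_test(fit, test_coef, sided = sided)
    stat <- w$statistic; p_raw <- w$p
  } else {
    Xr <- X[, -test_coef, drop = FALSE]
    fit_r <- fit_nb_glm(K, Xr, size_factors, disp)
    lrt <- lrt_interaction(fit, fit_r)
    stat <- lrt$statistic; p_raw <- lrt$p
  }

  norm <- sweep(K, 2L, size_factors, "/")
  log2fc <- fit$log2fc[, test_coef]
  se <- fit$se[, test_coef] / log(2)
  # boundary genes: one level of the tested contrast entirely zero
  contrast_grp <- X[, test_coef] > 0
  z1 <- rowSums(K[, contrast_grp, drop = FALSE]) == 0
  z0 <- rowSums(K[, !contrast_grp, drop = FALSE]) == 0
  bnd <- xor(z1, z0)
  if (any(bnd)) {
    m1 <- rowMeans(norm[bnd, contrast_grp, drop = FALSE]) + 0.5
    m0 <- rowMeans(norm[bnd, !contrast_grp, drop = FALSE]) + 0.5
    log2fc[bnd] <- log2(m1 / m0)
  }

  out <- data.frame(gene_id = rownames(K),
                    base_mean = rowMeans(norm),
                    log2fc = log2fc, se = se, stat = stat,
                    p_raw = p_raw, p_adj = adjust_bh(p_raw),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- classify_enrichment(out, lfc_threshold = lfc_threshold, alpha = alpha)
  structure(out,
            class = c("trap_enrichment", "data.frame"),
            design = design, sided = sided,
            lfc_threshold = lfc_threshold, alpha = alpha,
            size_factors = size_factors, dispersions = disp,
            removed_genes = removed)
}

#' @export
print.trap_enrichment <- function(x, n = 6L, ...) {
  cat(sprintf("TRAP enrichment table: %d genes (design: %s%s)\n",
              nrow(x), attr(x, "design"),
              if (attr(x, "design") == "condition")
                paste0(", ", attr(x, "sided"), "-sided Wald")
              else ", likelihood-ratio test"))
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more genes\n", nrow(x) - n))
  invisible(x)
}

#' @export
summary.trap_enrichment <- function(object, ...) {
  tab <- table(object$class)
  cat(sprintf("TRAP enrichment of %d genes at |log2FC| > %g, BH p < %g:\n",
              nrow(object), attr(object, "lfc_threshold"),
              attr(object, "alpha")))
  cat(sprintf("  enriched: %d   depleted: %d   unclassified: %d\n",
              tab[["enriched"]], tab[["depleted"]], tab[["unclassified"]]))
  n_na <- sum(is.na(object$p_raw))
  if (n_na) cat(sprintf("  %d gene(s) with missing p (non-converged fits)\n",
                        n_na))
  rm <- attr(object, "removed_genes")
  if (length(rm)) cat(sprintf("  %d all-zero gene(s) removed before testing\n",
                              length(rm)))
  invisible(tab)
}
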