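# Builders for comparison grids: genes x named comparisons matrices of raw
# one-sided p-values and matching log2 fold changes, the input to the
# Holm/FDR selection machinery.  All grids built from the same counts share
# one set of median-of-ratios size factors so that normalized expression is
# comparable across comparisons.

#' Construct a comparison grid
#'
#' @param p genes x comparisons matrix of raw p-values (`NA` allowed).
#' @param lfc matching matrix of log2 fold changes (optional).
#' @param comparisons comparison names (defaults to `colnames(p)`).
#' @return object of class `comparison_grid`.
#' @export
comparison_grid <- function(p, lfc = NULL, comparisons = colnames(p)) {
  p <- as.matrix(p)
  if (is.null(comparisons))
    stop("comparisons must be named", call. = FALSE)
  if (anyDuplicated(comparisons))
    stop("comparison names must be unique", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  colnames(p) <- comparisons
  if (!is.null(lfc)) {
    lfc <- as.matrix(lfc)
    stopifnot(all(dim(lfc) == dim(p)))
    colnames(lfc) <- comparisons
  }
  structure(list(p = p, lfc = lfc, comparisons = comparisons,
                 gene_ids = rownames(p)),
            class = "comparison_grid")
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat(sprintf("Comparison grid: %d genes x %d comparisons (%s)\n",
              nrow(x$p), length(x$comparisons),
              paste(x$comparisons, collapse = ", ")))
  invisible(x)
}

# shared preparation: validate, drop all-zero genes, size factors, norm counts
grid_context <- function(counts, samples, size_factors = NULL) {
  samples <- check_counts_samples(counts, samples)
  allzero <- rowSums(counts) == 0
  if (any(allzero))
    message(sprintf("removed %d all-zero gene(s) from the gene universe",
                    sum(allzero)))
  counts <- counts[!allzero, , drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  list(counts = counts, samples = samples, size_factors = size_factors,
       norm = sweep(counts, 2L, size_factors, "/"))
}

# one-sided Wald p and lfc for a two-group contrast defined by sample masks
pairwise_wald <- function(ctx, grp_hi, grp_lo, dispersions) {
  keep <- grp_hi | grp_lo
  X <- cbind(1, as.numeric(grp_hi[keep]))
  fit <- fit_nb_glm(ctx$counts[, keep, drop = FALSE], X,
                    ctx$size_factors[keep], dispersions)
  w <- wald_test(fit, 2L, sided = "greater")
  list(p = w$p, lfc = fit$log2fc[, 2L])
}

#' Per-tissue IP-above-input comparison grid
#'
#' One one-sided Wald comparison per tissue, testing whether a gene is more
#' abundant in the tissue's TRAP pulldown (IP) than in its matched lysate
#' (input).  Dispersions are estimated once from all samples under the
#' tissue-by-fraction cell-means design and reused in every comparison.
#'
#' @param counts gene-by-sample count matrix.
#' @param samples sample sheet.
#' @param tissues tissues to compare (default: all in the sheet).
#' @param size_factors optional shared size factors.
#' @param dispersion_method passed to [estimate_dispersion()].
#' @return a [comparison_grid()] with comparisons named
#'   `<tissue>:IP>input`, plus attributes `norm` (normalized counts),
#'   `samples` and `size_factors` for the downstream screens.
#' @export
ip_input_grid <- function(counts, samples, tissues = NULL,
                          size_factors = NULL,
                          dispersion_method = "shrink") {
  ctx <- grid_context(counts, samples, size_factors)
  if (is.null(tissues)) tissues <- unique(ctx$samples$tissue)
  cell <- factor(paste(ctx$samples$tissue, ctx$samples$fraction))
  Xc <- stats::model.matrix(~ 0 + cell)
  disp <- estimate_dispersion(ctx$counts, ctx$size_factors, Xc,
                              method = dispersion_method)
  cols <- lapply(tissues, function(t) {
    pairwise_wald(ctx,
                  grp_hi = ctx$samples$tissue == t & ctx$samples$fraction == "IP",
                  grp_lo = ctx$samples$tissue == t & ctx$samples$fraction == "input",
                  dispersions = disp)
  })
  g <- comparison_grid(
    p = do.call(cbind, lapply(cols, `[[`, "p")),
    lfc = do.call(cbind, lapply(cols, `[[`, "lfc")),
    comparisons = paste0(tissues, ":IP>input"))
  attr(g, "tissues") <- tissues
  attr(g, "norm") <- ctx$norm
  attr(g, "samples") <- ctx$samples
  attr(g, "size_factors") <- ctx$size_factors
  g
}

#' Tissue-IP above control-IP comparison grid
#'
#' One one-sided comparison per non-control tissue, testing whether a
#' gene's TRAP pulldown in that tissue exceeds the whole-organism control
#' pulldown.  Dispersions are estimated once across all IP samples under
#' the tissue cell-means design.
#'
#' @inheritParams ip_input_grid
#' @param control name of the whole-organism control tissue.
#' @return a [comparison_grid()] with comparisons named
#'   `<tissue>:IP>control`.
#' @export
ip_control_grid <- function(counts, samples, control,
                            size_factors = NULL,
                            dispersion_method = "shrink") {
  ctx <- grid_context(counts, samples, size_factors)
  if (!control %in% ctx$samples$tissue)
    stop("control tissue `", control, "` has no samples", call. = FALSE)
  tissues <- setdiff(unique(ctx$samples$tissue), control)
  ip <- ctx$samples$fraction == "IP"
  cell <- factor(ctx$samples$tissue[ip])
  Xc <- stats::model.matrix(~ 0 + cell)
  disp <- estimate_dispersion(ctx$counts[, ip, drop = FALSE],
                              ctx$size_factors[ip], Xc,
                              method = dispersion_method)
  cols <- lapply(tissues, function(t) {
    pairwise_wald(ctx,
                  grp_hi = ctx$samples$tissue == t & ip,
                  grp_lo = ctx$samples$tissue == control & ip,
                  dispersions = disp)
  })
  g <- comparison_grid(
    p = do.call(cbind, lapply(cols, `[[`, "p")),
    lfc = do.call(cbind, lapply(cols, `[[`, "lfc")),
    comparisons = paste0(tissues, ":IP>control"))
  attr(g, "tissues") <- tissues
  g
}

#' All ordered pairwise IP-versus-IP comparisons
#'
#' One one-sided comparison for every ordered pair of non-control tissues,
#' testing greater TRAP expression in the first tissue of the pair.  The
#' grid feeds the omnibus and cross-IP criteria of the organ-unique screen.
#' Dispersions are estimated once across all IP samples.
#'
#' @inheritParams ip_control_grid
#' @return a [comparison_grid()] with comparisons named `<t1>><t2>`.
#' @export
ip_pairwise_grid <- function(counts, samples, control = NULL,
                             size_factors = NULL,
                             dispersion_method = "shrink") {
  ctx <- grid_context(counts, samples, size_factors)
  tissues <- setdiff(unique(ctx$samples$tissue), control)
  if (length(tissues) < 2L)
    stop("pairwise IP comparisons need at least 2 tissues", call. = FALSE)
  ip <- ctx$samples$fraction == "IP"
  cell <- factor(ctx$samples$tissue[ip])
  Xc <- stats::model.matrix(~ 0 + cell)
  disp <- estimate_dispersion(ctx$counts[, ip, drop = FALSE],
                              ctx$size_factors[ip], Xc,
                              method = dispersion_method)
  pairs <- expand.grid(t2 = tissues, t1 = tissues,
                       stringsAsFactors = FALSE)[, c("t1", "t2")]
  pairs <- pairs[pairs$t1 != pairs$t2, ]
  cols <- lapply(seq_len(nrow(pairs)), function(i) {
    pairwise_wald(ctx,
                  grp_hi = ctx$samples$tissue == pairs$t1[i] & ip,
                  grp_lo = ctx$samples$tissue == pairs$t2[i] & ip,
                  dispersions = disp)
  })
  g <- comparison_grid(
    p = do.call(cbind, lapply(cols, `[[`, "p")),
    lfc = do.call(cbind, lapply(cols, `[[`, "lfc")),
    comparisons = paste0(pairs$t1, ">", pairs$t2))
  attr(g, "tissues") <- tissues
  attr(g, "pairs") <- pairs
  g
}

#' Mean normalized expression per tissue and fraction
#'
#' @param counts gene-by-sample count matrix.
#' @param samples sample sheet.
#' @param size_factors optional; estimated when `NULL`.
#' @return list with matrices `ip` and `input` (genes x tissues) of mean
#'   normalized counts.
#' @export
tissue_means <- function(counts, samples, size_factors = NULL) {
  ctx <- grid_context(counts, samples, size_factors)
  tissues <- unique(ctx$samples$tissue)
  mk <- function(frac) {
    m <- vapply(tissues, function(t) {
      sel <- ctx$samples$tissue == t & ctx$samples$fraction == frac
      rowMeans(ctx$norm[, sel, drop = FALSE])
    }, numeric(nrow(ctx$norm)))
    colnames(m) <- tissues
    m
  }
  list(ip = mk("IP"), input = mk("input"))
}
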