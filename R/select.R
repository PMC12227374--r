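# The multi-dimensional pairwise-comparison selection machinery: a Holm
# step-down correction across comparisons within each gene, an FDR computed
# across genes from the gene-wise minimal Holm-corrected p-values, and a
# per-comparison cut at fdr_level * R (R being the fraction of genes whose
# FDR clears the level).  Shared genes come from intersecting per-comparison
# selections; organ-unique genes from a two-grid pre-screen followed by a
# dominance screen and fold filters.

#' Holm correction across comparisons within one gene
#'
#' Missing p-values count as 1 (an absent comparison is uninformative, not
#' favourable) and then the standard Holm step-down adjustment is applied
#' across the full set, capped at 1.
#'
#' @param p_row vector of raw p-values in \[0, 1\], `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @examples
#' holm_within_gene(c(0.01, 0.04))   # 0.02, 0.04
#' holm_within_gene(c(0.02, NA))     # 0.04, 1
#' @export
holm_within_gene <- function(p_row) {
  if (any(p_row > 1 | p_row < 0, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p_row[is.na(p_row)] <- 1
  p.adjust(p_row, method = "holm")
}

# row-wise Holm over a genes x comparisons matrix (NA -> 1 first)
holm_matrix <- function(p) {
  p[is.na(p)] <- 1
  m <- ncol(p)
  if (m == 1L) return(p)
  ord <- t(apply(p, 1L, order))
  sorted <- matrix(p[cbind(rep(seq_len(nrow(p)), m), as.vector(ord))],
                   nrow(p), m)
  mult <- matrix(m:1, nrow(p), m, byrow = TRUE)
  adj <- pmin(sorted * mult, 1)
  adj <- t(apply(adj, 1L, cummax))
  out <- p
  for (j in seq_len(m)) out[cbind(seq_len(nrow(p)), ord[, j])] <- adj[, j]
  out
}

#' Select genes shared across all comparisons
#'
#' Implements the multi-dimensional multiple-testing procedure on a
#' comparison grid: (1) missing p-values become 1 and a Holm correction is
#' applied across comparisons within each gene; (2) the FDR is computed
#' across genes by BH on the gene-wise minimal Holm-corrected p-values;
#' (3) `R` is the fraction of genes with FDR below `fdr_level`; (4) each
#' comparison selects the genes whose within-gene Holm p is below
#' `fdr_level * R` and whose gene-wise FDR is below `fdr_level`; (5) the
#' shared set is the intersection of the per-comparison selections.
#'
#' @param grid a [comparison_grid()].
#' @param fdr_level the FDR level, which also scales the per-comparison
#'   Holm cut (default 0.1; the same constant plays both roles).
#' @return object of class `shared_selection`: list with `per_comparison`
#'   (named list of gene-id vectors), `intersection`, `holm` (adjusted
#'   matrix), `min_holm`, `fdr`, `R`, `fdr_level`.
#' @export
select_shared <- function(grid, fdr_level = 0.1) {
  stopifnot(inherits(grid, "comparison_grid"))
  p <- grid$p
  if (nrow(p) < 2L) stop("need at least 2 genes", call. = FALSE)
  genes <- grid$gene_ids %||% as.character(seq_len(nrow(p)))
  holm <- holm_matrix(p)
  min_holm <- row_min(holm)
  fdr <- adjust_bh(min_holm)
  R <- mean(fdr < fdr_level)
  if (R == 0)
    warning("no gene clears the across-gene FDR level; the per-comparison ",
            "cut fdr_level * R is 0 and every selection is empty",
            call. = FALSE)
  pass_fdr <- fdr < fdr_level
  per_comparison <- lapply(seq_len(ncol(holm)), function(j) {
    genes[pass_fdr & holm[, j] < fdr_level * R]
  })
  names(per_comparison) <- grid$comparisons
  structure(list(per_comparison = per_comparison,
                 intersection = Reduce(intersect, per_comparison),
                 holm = holm, min_holm = min_holm, fdr = fdr, R = R,
                 fdr_level = fdr_level, gene_ids = genes),
            class = "shared_selection")
}

#' @export
print.shared_selection <- function(x, ...) {
  cat(sprintf("Shared-gene selection over %d comparisons (FDR level %g, R = %.3f)\n",
              length(x$per_comparison), x$fdr_level, x$R))
  for (nm in names(x$per_comparison))
    cat(sprintf("  %-24s %d genes\n", nm, length(x$per_comparison[[nm]])))
  cat(sprintf("  intersection: %d genes\n", length(x$intersection)))
  invisible(x)
}

#' Filter shared genes for display strength
#'
#' Retains, from a shared selection, the genes whose IP/input log2 fold
#' change is at least `lfc_min` (inclusive) with a BH-adjusted p-value
#' below `alpha` in every comparison of the grid — the criterion used to
#' pick genes strong enough to display in a heatmap.
#'
#' @param result a [select_shared()] result.
#' @param grid the [comparison_grid()] the selection came from (must carry
#'   `lfc`).
#' @param lfc_min inclusive log2 fold-change bound (default 1.2).
#' @param alpha BH-adjusted significance level per comparison (default 0.05).
#' @return character vector of retained gene ids.
#' @export
heatmap_filter <- function(result, grid, lfc_min = 1.2, alpha = 0.05) {
  stopifnot(inherits(result, "shared_selection"),
            inherits(grid, "comparison_grid"))
  if (is.null(grid$lfc))
    stop("grid carries no log2 fold changes", call. = FALSE)
  genes <- result$intersection
  if (!length(genes)) return(character())
  ix <- match(genes, result$gene_ids)
  p_adj <- apply(grid$p, 2L, adjust_bh)
  keep <- rowSums(grid$lfc[ix, , drop = FALSE] >= lfc_min &
                    !is.na(p_adj[ix, , drop = FALSE]) &
                    p_adj[ix, , drop = FALSE] < alpha) == ncol(grid$p)
  genes[keep]
}

#' Pre-screen candidate organ-unique genes
#'
#' For each tissue, a gene is a candidate if it is selected both in the
#' tissue's IP-above-input comparison and, independently, in the tissue's
#' IP-above-control-IP comparison, each selection made by the same
#' Holm/FDR machinery as [select_shared()] applied to its own grid; the
#' per-tissue candidate set is the intersection of the two.
#'
#' @param grid_input an [ip_input_grid()] restricted to the non-control
#'   tissues (comparisons named `<tissue>:...`).
#' @param grid_control an [ip_control_grid()] over the same gene universe.
#' @param fdr_level FDR level for both selections (default 0.1).
#' @return object of class `unique_prescreen`: list with `candidates`
#'   (named list per tissue), `union_size`, and the two selections.
#' @export
prescreen_unique <- function(grid_input, grid_control, fdr_level = 0.1) {
  stopifnot(inherits(grid_input, "comparison_grid"),
            inherits(grid_control, "comparison_grid"))
  if (!setequal(grid_input$gene_ids, grid_control$gene_ids))
    stop("the two grids must share one gene universe", call. = FALSE)
  t1 <- sub(":.*$", "", grid_input$comparisons)
  t2 <- sub(":.*$", "", grid_control$comparisons)
  tissues <- intersect(t1, t2)
  if (!length(tissues))
    stop("no tissue appears in both grids; is the whole-organism control ",
         "configured?", call. = FALSE)
  sel1 <- select_shared(grid_input, fdr_level)
  sel2 <- select_shared(grid_control, fdr_level)
  candidates <- lapply(tissues, function(t) {
    intersect(sel1$per_comparison[[match(t, t1)]],
              sel2$per_comparison[[match(t, t2)]])
  })
  names(candidates) <- tissues
  structure(list(candidates = candidates,
                 union_size = length(unique(unlist(candidates))),
                 sel_input = sel1, sel_control = sel2,
                 fdr_level = fdr_level),
            class = "unique_prescreen")
}

#' Dominance screen for organ-unique genes
#'
#' Keeps a candidate gene for tissue T only if all four criteria hold:
#' (1) it was pre-screened for T; (2) it passes the omnibus test of any
#' expression change across tissue IPs — across-gene FDR below `fdr_level`
#' computed from the gene's minimal Holm-corrected p over all ordered
#' pairwise IP-versus-IP comparisons; (3) every comparison "T above other"
#' has a within-gene Holm-corrected p below `fdr_level * R`, with R the
#' fraction of genes passing the omnibus test; (4) the minimum of T's IP
#' replicates (normalized counts) lies strictly above every IP replicate of
#' every other tissue.
#'
#' @param prescreen a [prescreen_unique()] result (or a named list of
#'   candidate gene-id vectors per tissue).
#' @param pairwise_grid an [ip_pairwise_grid()] over the same genes.
#' @param norm_counts genes x samples matrix of normalized counts.
#' @param samples sample sheet matching `norm_counts`.
#' @param fdr_level FDR level (default 0.1).
#' @param control optional control tissue excluded from criterion (4).
#' @return object of class `unique_screen`: list with `unique` (named list
#'   of gene ids per tissue, pairwise disjoint), `diagnostics` (per
#'   gene-tissue data.frame of the four criteria), `R`, `fdr`.
#' @export
dominance_screen <- function(prescreen, pairwise_grid, norm_counts, samples,
                             fdr_level = 0.1, control = NULL) {
  candidates <- if (inherits(prescreen, "unique_prescreen"))
    prescreen$candidates else prescreen
  stopifnot(inherits(pairwise_grid, "comparison_grid"))
  tissues <- attr(pairwise_grid, "tissues")
  if (length(tissues) < 2L)
    stop("dominance screen needs at least 2 tissues", call. = FALSE)
  genes <- pairwise_grid$gene_ids
  holm <- holm_matrix(pairwise_grid$p)
  fdr <- adjust_bh(row_min(holm))
  pass_omnibus <- fdr < fdr_level
  R <- mean(pass_omnibus)

  ip_cols <- lapply(tissues, function(t) {
    which(samples$tissue == t & samples$fraction == "IP")
  })
  names(ip_cols) <- tissues

  pair_t1 <- sub(">.*$", "", pairwise_grid$comparisons)
  unique_sets <- list()
  diags <- list()
  for (t in intersect(names(candidates), tissues)) {
    cand <- candidates[[t]]
    if (!length(cand)) { unique_sets[[t]] <- character(); next }
    ix <- match(cand, genes)
    own <- which(pair_t1 == t)
    crit2 <- pass_omnibus[ix]
    crit3 <- rowSums(holm[ix, own, drop = FALSE] < fdr_level * R) ==
      length(own)
    mins <- apply(norm_counts[cand, ip_cols[[t]], drop = FALSE], 1L, min)
    others <- unlist(ip_cols[setdiff(tissues, c(t, control))])
    maxs <- apply(norm_counts[cand, others, drop = FALSE], 1L, max)
    crit4 <- mins > maxs
    keep <- crit2 & crit3 & crit4
    unique_sets[[t]] <- cand[keep]
    diags[[t]] <- data.frame(gene_id = cand, tissue = t,
                             prescreened = TRUE, omnibus = crit2,
                             cross_ip = crit3, replicate_min = crit4,
                             kept = keep, stringsAsFactors = FALSE)
  }
  structure(list(unique = unique_sets,
                 diagnostics = do.call(rbind, c(diags,
                                                make.row.names = FALSE)),
                 R = R, fdr = setNames(fdr, genes),
                 fdr_level = fdr_level, tissues = tissues),
            class = "unique_screen")
}

#' @export
print.unique_screen <- function(x, ...) {
  cat(sprintf("Organ-unique dominance screen (omnibus R = %.3f, FDR level %g)\n",
              x$R, x$fdr_level))
  for (t in names(x$unique))
    cat(sprintf("  %-12s %d genes\n", t, length(x$unique[[t]])))
  invisible(x)
}

#' Fold-change filters on organ-unique genes
#'
#' Applies the three expression-strength filters to a dominance screen, on
#' the configured scale:
#' (1) the tissue's endothelial (IP) expression is at least
#' `filters[1]`-fold above its own lysate (input); (2) the tissue's IP
#' expression is at least `filters[2]`-fold above the next-highest tissue's
#' IP expression; (3) the IP difference between the tissue and that
#' next-highest tissue is at least `filters[3]` times their input
#' difference.  All bounds are inclusive.  A gene whose IP expression ties
#' exactly with another tissue's is assigned to neither (uniqueness cannot
#' be claimed).
#'
#' With `scale = "fold"` expressions are mean normalized counts and filters
#' are ratios; with `scale = "log2"` expressions are log2 mean normalized
#' counts (0.5 pseudo-count) and the same constants act on log2 differences.
#'
#' @param screen a [dominance_screen()] result (or named list of gene ids).
#' @param means a [tissue_means()] list (`ip`, `input` matrices).
#' @param filters numeric triple, default `c(1.5, 2, 2)`.
#' @param scale `"fold"` or `"log2"`.
#' @param control optional control tissue excluded from the comparison set.
#' @return object of class `unique_result`: list with `unique` (filtered
#'   per-tissue gene lists) and `diagnostics` (per gene the three filter
#'   quantities and verdicts).
#' @export
fold_filters <- function(screen, means, filters = c(1.5, 2, 2),
                         scale = c("fold", "log2"), control = NULL) {
  scale <- match.arg(scale)
  sets <- if (inherits(screen, "unique_screen")) screen$unique else screen
  stopifnot(length(filters) == 3L, all(filters > 0))
  ip <- means$ip; input <- means$input
  tissues <- setdiff(colnames(ip), control)
  if (scale == "log2") {
    ip <- log2(ip + 0.5); input <- log2(input + 0.5)
  }
  cmp <- function(hi, lo, f) {
    if (scale == "fold") hi >= f * lo else (hi - lo) >= f
  }
  out <- list(); diags <- list()
  for (t in intersect(names(sets), tissues)) {
    g <- sets[[t]]
    if (!length(g)) { out[[t]] <- character(); next }
    others <- setdiff(tissues, t)
    ip_t <- ip[g, t]; in_t <- input[g, t]
    next_ix <- apply(ip[g, others, drop = FALSE], 1L, which.max)
    next_tissue <- others[next_ix]
    ip_n <- ip[cbind(g, next_tissue)]
    in_n <- input[cbind(g, next_tissue)]
    tie <- vapply(seq_along(g), function(i) {
      sum(ip[g[i], others] == ip_t[i]) > 0
    }, logical(1))
    f1 <- cmp(ip_t, in_t, filters[1])
    f2 <- cmp(ip_t, ip_n, filters[2]) & !tie
    f3 <- (ip_t - ip_n) >= filters[3] * (in_t - in_n)
    keep <- f1 & f2 & f3
    out[[t]] <- g[keep]
    diags[[t]] <- data.frame(
      gene_id = g, tissue = t, next_tissue = next_tissue,
      ip = ip_t, input = in_t, ip_next = ip_n, input_next = in_n,
      pass_input_fold = f1, pass_next_fold = f2, pass_diff = f3,
      tied = tie, kept = keep, stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(unique = out,
                 diagnostics = do.call(rbind, c(diags,
                                                make.row.names = FALSE)),
                 filters = filters, scale = scale),
            class = "unique_result")
}

#' @export
print.unique_result <- function(x, ...) {
  cat(sprintf("Organ-unique genes after fold filters (%s scale, %s)\n",
              x$scale, paste(x$filters, collapse = "/")))
  for (t in names(x$unique))
    cat(sprintf("  %-12s %d genes\n", t, length(x$unique[[t]])))
  invisible(x)
}
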