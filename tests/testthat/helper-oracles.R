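# Independent brute-force oracles.  These re-derive, from first principles
# and without touching the package's implementation paths, the quantities
# the implementation is supposed to produce.

# median-of-ratios size factors, literal transcription of the definition
oracle_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  ref <- exp(rowMeans(log(m[keep, , drop = FALSE])))
  sf <- apply(m[keep, , drop = FALSE], 2, function(col) median(col / ref))
  sf / exp(mean(log(sf)))
}

# Holm step-down, element by element from the definition
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    v <- min((m - i + 1) * p[o[i]], 1)
    running <- max(running, v)
    adj[o[i]] <- running
  }
  adj
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- 1
  for (i in seq_along(o)) {
    rank <- m - i + 1
    running <- min(running, p[o[i]] * m / rank)
    adj[o[i]] <- running
  }
  adj
}

# codon counts of one in-frame CDS by direct substring extraction
oracle_codon_counts <- function(cds_vec) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  counts <- setNames(integer(64), all_codons)
  for (cds in cds_vec) {
    n <- nchar(cds) %/% 3
    for (i in seq_len(n)) {
      codon <- substr(cds, 3 * i - 2, 3 * i)
      counts[codon] <- counts[codon] + 1L
    }
  }
  counts
}

# Pearson r^2 from its closed form
oracle_r2 <- function(x, y) {
  sx <- x - mean(x); sy <- y - mean(y)
  (sum(sx * sy))^2 / (sum(sx^2) * sum(sy^2))
}

# translate and scan for the first stop, independent of the implementation
oracle_truncation <- function(cds) {
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, 3 * (nchar(cds) %/% 3))),
    if.fuzzy.codon = "X")), "")[[1]]
  stop_at <- which(aa == "*")
  if (length(stop_at)) stop_at[1] - 1L else length(aa)
}

# leftmost single-deletion placement by exhaustive enumeration
oracle_leftmost_deletion <- function(wt, mut) {
  d <- nchar(wt) - nchar(mut)
  for (i in seq_len(nchar(mut) + 1)) {
    cand <- paste0(substr(wt, 1, i - 1), substr(wt, i + d, nchar(wt)))
    if (cand == mut) return(list(length = d, position = i))
  }
  NULL
}

# the shared-gene selection pipeline, step by literal step
oracle_select_shared <- function(p, fdr_level = 0.1) {
  p[is.na(p)] <- 1
  holm <- t(apply(p, 1, oracle_holm))
  minp <- apply(holm, 1, min)
  fdr <- oracle_bh(minp)
  R <- mean(fdr < fdr_level)
  sets <- lapply(seq_len(ncol(p)), function(j) {
    which(holm[, j] < fdr_level * R & fdr < fdr_level)
  })
  list(sets = sets, intersection = Reduce(intersect, sets), R = R,
       fdr = fdr)
}

# small NB count matrix with a two-group design
make_two_group_counts <- function(n_genes, n_per_group, mu1, mu2, alpha,
                                  sf = NULL, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  if (is.null(sf)) sf <- rep(1, n)
  mu <- cbind(matrix(mu1, n_genes, n_per_group),
              matrix(mu2, n_genes, n_per_group))
  mu <- sweep(mu, 2, sf, "*")
  k <- matrix(rnbinom(n_genes * n, mu = mu, size = 1 / max(alpha, 1e-12)),
              n_genes)
  if (alpha == 0) k <- matrix(rpois(n_genes * n, lambda = mu), n_genes)
  rownames(k) <- sprintf("g%03d", seq_len(n_genes))
  colnames(k) <- sprintf("s%02d", seq_len(n))
  k
}

two_group_design <- function(n_per_group) {
  cbind(1, rep(c(0, 1), each = n_per_group))
}
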