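#' Describe a simulated TRAP-RNAseq experiment
#'
#' Collects the parameters of the negative-binomial count simulator into a
#' validated design object.  The defaults emulate the structure of an adult
#' multi-organ TRAP experiment: five organs plus a whole-organism control,
#' paired IP/input libraries in triplicate, gene baseline means log-uniform
#' over \[5, 5000\], gene-wise dispersions log-normal around 0.05, and
#' multiplicative library-size factors uniform over \[0.5, 2\].
#'
#' Three planted gene classes carry true effects, recorded in the emitted
#' truth table:
#' * `enriched:<tissue>` — IP-enriched in one tissue only
#'   (`frac_enriched` of genes per tissue, effect `lfc_enriched`);
#' * `shared` — IP-enriched in every tissue including the control
#'   (`n_shared` genes, effect `lfc_shared`), the "pan-endothelial" class;
#' * `unique:<tissue>` — IP-enriched in exactly one non-control tissue
#'   (`n_unique` genes per tissue, effect `lfc_unique`; the default of 3
#'   log2 units corresponds to the eight-fold dominance the organ-unique
#'   screen is designed to detect).
#'
#' @param n_genes number of genes.
#' @param tissues character vector of tissue names; must include `control`.
#' @param control name of the whole-organism control tissue.
#' @param n_replicates replicates per tissue and fraction.
#' @param frac_enriched proportion of genes planted as IP-enriched per tissue.
#' @param lfc_enriched planted log2 IP/input fold change for enriched genes.
#' @param n_shared number of genes planted as shared (enriched everywhere).
#' @param lfc_shared planted log2 fold for shared genes: a scalar applied in
#'   every tissue, or a named vector giving a tissue-specific fold (this is
#'   how an interaction — a gene whose IP/input enrichment differs between
#'   experiments — is planted).
#' @param n_unique number of organ-unique genes planted per non-control tissue.
#' @param lfc_unique planted log2 fold for organ-unique genes.
#' @param dispersion_meanlog,dispersion_sdlog location and scale of the
#'   log-normal gene-wise dispersion law (variance = mu + alpha * mu^2).
#' @param baseline_range range of the log-uniform gene baseline mean law.
#' @param libsize_range range of the uniform library-size factor law.
#' @param seed integer seed; all draws flow from one RNG seeded once.
#' @return an object of class `sim_design` (a validated list).
#' @seealso [simulate_counts()]
#' @export
sim_design <- function(n_genes = 2000,
                       tissues = c("brain", "heart", "liver", "muscle", "skin",
                                   "wholefish"),
                       control = "wholefish",
                       n_replicates = 3,
                       frac_enriched = 0.1,
                       lfc_enriched = 2,
                       n_shared = 0,
                       lfc_shared = 2,
                       n_unique = 0,
                       lfc_unique = 3,
                       dispersion_meanlog = log(0.05),
                       dispersion_sdlog = 0.25,
                       baseline_range = c(5, 5000),
                       libsize_range = c(0.5, 2),
                       seed = 1) {
  d <- list(
    n_genes = check_count(n_genes, "n_genes"),
    tissues = tissues, control = control,
    n_replicates = check_count(n_replicates, "n_replicates"),
    frac_enriched = check_prob(frac_enriched, "frac_enriched"),
    lfc_enriched = lfc_enriched,
    n_shared = as.integer(n_shared), lfc_shared = lfc_shared,
    n_unique = as.integer(n_unique), lfc_unique = lfc_unique,
    dispersion_meanlog = dispersion_meanlog,
    dispersion_sdlog = dispersion_sdlog,
    baseline_range = baseline_range,
    libsize_range = libsize_range,
    seed = seed
  )
  if (!is.character(tissues) || length(tissues) < 1L || anyDuplicated(tissues))
    stop_param("tissues", "must be a character vector of unique tissue names")
  if (!control %in% tissues)
    stop_param("control", "must be one of `tissues`")
  if (d$n_shared < 0) stop_param("n_shared", "must be non-negative")
  if (length(d$lfc_shared) > 1L &&
      !setequal(names(d$lfc_shared), tissues))
    stop_param("lfc_shared",
               "a vector lfc_shared must be named by the tissues")
  if (d$n_unique < 0) stop_param("n_unique", "must be non-negative")
  if (!is.numeric(d$dispersion_sdlog) || d$dispersion_sdlog < 0)
    stop_param("dispersion_sdlog", "must be non-negative")
  if (length(baseline_range) != 2L || any(baseline_range <= 0) ||
      diff(baseline_range) < 0)
    stop_param("baseline_range", "must be an increasing positive pair")
  if (length(libsize_range) != 2L || any(libsize_range <= 0) ||
      diff(libsize_range) < 0)
    stop_param("libsize_range", "must be an increasing positive pair")
  n_target <- length(tissues) - 1L
  planted <- d$n_shared + d$n_unique * n_target +
    round(d$frac_enriched * d$n_genes) * length(tissues)
  if (planted > d$n_genes)
    stop_param("frac_enriched",
               "planted classes exceed n_genes; reduce fractions or counts")
  structure(d, class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat("TRAP-RNAseq simulation design\n")
  cat(sprintf("  %d genes; tissues: %s (control: %s); %d replicates per IP/input\n",
              x$n_genes, paste(x$tissues, collapse = ", "), x$control,
              x$n_replicates))
  cat(sprintf("  planted per tissue: %.0f enriched (lfc %.2f); %d shared (lfc %.2f); %d unique (lfc %.2f)\n",
              round(x$frac_enriched * x$n_genes), x$lfc_enriched,
              x$n_shared, x$lfc_shared, x$n_unique, x$lfc_unique))
  cat(sprintf("  dispersion ~ lognormal(%.3f, %.3f); baseline [%g, %g]; libsize [%g, %g]; seed %s\n",
              x$dispersion_meanlog, x$dispersion_sdlog,
              x$baseline_range[1], x$baseline_range[2],
              x$libsize_range[1], x$libsize_range[2], format(x$seed)))
  invisible(x)
}

#' Simulate a TRAP-RNAseq count matrix
#'
#' Draws a gene-by-sample matrix of negative-binomial counts following a
#' [sim_design()].  Counts for gene g in sample j have mean
#' `baseline_g * libsize_j * 2^lfc` where the planted log2 fold `lfc` is
#' non-zero only when sample j is an IP library of a tissue affected by the
#' gene's class, and variance `mu + alpha_g * mu^2` with gene-wise
#' dispersion `alpha_g`.  Output is bit-identical for a given design
#' (including its seed).
#'
#' @param design a [sim_design()] object.
#' @return a list of class `trap_sim` with elements
#'   `counts` (integer matrix, genes x samples),
#'   `samples` (data.frame: sample, tissue, fraction, replicate, experiment),
#'   `truth` (data.frame: gene_id, class, and one `lfc_<tissue>` column per
#'   tissue giving the planted log2 IP/input fold in that tissue), and
#'   `dispersions`, `baselines`, `size_factors` (the drawn gene and library
#'   parameters).
#' @examples
#' sim <- simulate_counts(sim_design(n_genes = 100, n_replicates = 2, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$class)
#' @export
simulate_counts <- function(design) {
  if (!inherits(design, "sim_design"))
    stop("`design` must be created by sim_design()", call. = FALSE)
  d <- design
  set.seed(d$seed)
  G <- d$n_genes
  tissues <- d$tissues
  n_t <- length(tissues)

  samples <- expand.grid(replicate = seq_len(d$n_replicates),
                         fraction = c("IP", "input"),
                         tissue = tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("tissue", "fraction", "replicate")]
  samples$experiment <- samples$tissue
  samples$sample <- sprintf("%s_%s_%d", samples$tissue, samples$fraction,
                            samples$replicate)
  samples <- samples[, c("sample", "tissue", "fraction", "replicate",
                         "experiment")]
  n_s <- nrow(samples)
  gene_ids <- sprintf("g%0*d", nchar(G), seq_len(G))

  baselines <- exp(runif(G, log(d$baseline_range[1]), log(d$baseline_range[2])))
  dispersions <- rlnorm(G, d$dispersion_meanlog, d$dispersion_sdlog)
  libsize <- runif(n_s, d$libsize_range[1], d$libsize_range[2])

  # planted classes: assign disjoint gene sets in a fixed order
  class <- rep("null", G)
  pool <- sample.int(G)   # random but seed-determined placement
  take <- function(n) {
    ix <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    ix
  }
  lfc <- matrix(0, G, n_t, dimnames = list(gene_ids, tissues))
  if (d$n_shared > 0) {
    ix <- take(d$n_shared)
    class[ix] <- "shared"
    shared_lfc <- if (length(d$lfc_shared) > 1L)
      d$lfc_shared[tissues] else rep(d$lfc_shared, n_t)
    lfc[ix, ] <- matrix(shared_lfc, length(ix), n_t, byrow = TRUE)
  }
  for (t in setdiff(tissues, d$control)) {
    if (d$n_unique > 0) {
      ix <- take(d$n_unique)
      class[ix] <- paste0("unique:", t)
      lfc[ix, t] <- d$lfc_unique
    }
  }
  n_enr <- round(d$frac_enriched * G)
  for (t in tissues) {
    if (n_enr > 0) {
      ix <- take(n_enr)
      class[ix] <- paste0("enriched:", t)
      lfc[ix, t] <- d$lfc_enriched
    }
  }

  is_ip <- samples$fraction == "IP"
  tissue_col <- match(samples$tissue, tissues)
  mu <- outer(baselines, libsize)
  for (j in seq_len(n_s)) {
    if (is_ip[j]) mu[, j] <- mu[, j] * 2^lfc[, tissue_col[j]]
  }
  size <- 1 / pmax(dispersions, 1e-12)
  counts <- matrix(rnbinom(G * n_s, mu = mu, size = rep(size, n_s)),
                   nrow = G, dimnames = list(gene_ids, samples$sample))

  truth <- data.frame(gene_id = gene_ids, class = class,
                      stringsAsFactors = FALSE)
  for (t in tissues) truth[[paste0("lfc_", t)]] <- lfc[, t]

  structure(list(counts = counts, samples = samples, truth = truth,
                 dispersions = setNames(dispersions, gene_ids),
                 baselines = setNames(baselines, gene_ids),
                 size_factors = setNames(libsize, samples$sample),
                 design = d),
            class = "trap_sim")
}

#' @export
print.trap_sim <- function(x, ...) {
  cat(sprintf("Simulated TRAP-RNAseq data: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$tissue), collapse = ", ")))
  tab <- table(sub(":.*", "", x$truth$class))
  cat("  planted classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
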