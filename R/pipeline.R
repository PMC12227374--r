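# End-to-end orchestration: simulate -> enrich -> select-shared ->
# select-unique -> codon-usage -> indel, from one config, with a
# machine-readable manifest.  Reruns with an identical config are
# bit-identical; each stochastic stage draws from a seed derived from the
# master seed and the stage name, so stages stay decoupled.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the pipeline's thresholds
#' (enrichment log2 fold 0.35 at BH p < 0.05; selection FDR level 0.1;
#' heatmap fold 1.2; unique-gene fold filters 1.5/2/2 on the fold scale),
#' the simulation design parameters, and stage toggles.  Any element can be
#' overridden through `...` or by a YAML config file in [run_pipeline()].
#'
#' @param seed master seed.
#' @param ... overrides of top-level config elements.
#' @return named list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    stages = c("simulate", "enrich", "shared", "unique", "codon", "indel"),
    sim = list(n_genes = 2000, n_replicates = 3,
               tissues = c("brain", "heart", "liver", "muscle", "skin",
                           "wholefish"),
               control = "wholefish",
               frac_enriched = 0.05, lfc_enriched = 2,
               n_shared = 20, lfc_shared = 2,
               n_unique = 5, lfc_unique = 3),
    transcriptome = list(n_genes = 150, bias_strength = 3),
    lfc_threshold = 0.35, alpha = 0.05,
    fdr_level = 0.1, heatmap_lfc = 1.2,
    filters = c(1.5, 2, 2), scale = "fold"
  )
  modifyList(cfg, list(...))
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

#' Run the whole TRAP-RNAseq analysis pipeline
#'
#' Executes the enabled stages on simulated data and writes every stage's
#' tables plus a `manifest.json` (package version, seed, config, and
#' per-stage row counts) to `out_dir`.  With the same config the run is
#' bit-identical.  On a stage failure the error propagates after a
#' `FAILED` marker file is written, so partial outputs remain inspectable.
#'
#' @param config a [pipeline_config()] list (or `NULL` for defaults).
#' @param out_dir output directory (created if needed).
#' @param config_file optional YAML file whose top-level keys override the
#'   defaults.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir, config_file = NULL) {
  cfg <- pipeline_config()
  if (!is.null(config_file))
    cfg <- modifyList(cfg, yaml::read_yaml(config_file))
  if (!is.null(config)) cfg <- modifyList(cfg, config)
  if (any(c(cfg$lfc_threshold, cfg$alpha, cfg$fdr_level, cfg$heatmap_lfc,
            cfg$filters) <= 0))
    stop("all thresholds must be positive", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "trapseq",
                   version = as.character(packageVersion("trapseq")),
                   seed = cfg$seed, config = cfg, stages = list())
  current_stage <- NA_character_

  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    current_stage <<- name
    rows <- tryCatch(fun(), error = function(e) {
      writeLines(c(current_stage, conditionMessage(e)),
                 stage_file(out_dir, "FAILED"))
      stop(sprintf("stage `%s` failed: %s", current_stage,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- rows
    message(sprintf("[%s] done (%s)", name,
                    paste(sprintf("%s=%s", names(rows), rows),
                          collapse = ", ")))
  }

  sim <- NULL
  run_stage("simulate", function() {
    design <- do.call(sim_design,
                      c(cfg$sim, list(seed = derive_seed(cfg$seed,
                                                         "simulate"))))
    sim <<- simulate_counts(design)
    write_counts(sim$counts, stage_file(out_dir, "counts.tsv"))
    write_sample_sheet(sim$samples, stage_file(out_dir, "samples.tsv"))
    write_table(sim$truth, stage_file(out_dir, "truth.tsv"))
    list(genes = nrow(sim$counts), samples = ncol(sim$counts))
  })
  if (is.null(sim) && any(c("enrich", "shared", "unique") %in% cfg$stages)) {
    counts <- read_counts(stage_file(out_dir, "counts.tsv"))
    samples <- read_sample_sheet(stage_file(out_dir, "samples.tsv"))
    sim <- list(counts = counts, samples = samples)
  }

  enrich_tabs <- list()
  run_stage("enrich", function() {
    tissues <- unique(sim$samples$tissue)
    n_cls <- integer(0)
    for (t in tissues) {
      res <- trap_enrich(sim$counts, sim$samples, design = "condition",
                         tissue = t, lfc_threshold = cfg$lfc_threshold,
                         alpha = cfg$alpha)
      enrich_tabs[[t]] <<- res
      write_table(as.data.frame(res),
                  stage_file(out_dir, sprintf("enrichment_%s.tsv", t)))
      n_cls[t] <- sum(res$class == "enriched")
    }
    as.list(n_cls)
  })

  control <- cfg$sim$control
  run_stage("shared", function() {
    grid <- ip_input_grid(sim$counts, sim$samples)
    sel <- select_shared(grid, fdr_level = cfg$fdr_level)
    strong <- heatmap_filter(sel, grid, lfc_min = cfg$heatmap_lfc,
                             alpha = cfg$alpha)
    write_table(data.frame(gene_id = sel$intersection),
                stage_file(out_dir, "shared_genes.tsv"))
    write_table(data.frame(gene_id = strong),
                stage_file(out_dir, "shared_heatmap_genes.tsv"))
    list(shared = length(sel$intersection), heatmap = length(strong),
         R = sel$R)
  })

  run_stage("unique", function() {
    target <- setdiff(unique(sim$samples$tissue), control)
    sf <- estimate_size_factors(sim$counts[rowSums(sim$counts) > 0, ,
                                           drop = FALSE])
    g_in <- ip_input_grid(sim$counts, sim$samples, tissues = target,
                          size_factors = sf)
    g_ctl <- ip_control_grid(sim$counts, sim$samples, control = control,
                             size_factors = sf)
    g_pw <- ip_pairwise_grid(sim$counts, sim$samples, control = control,
                             size_factors = sf)
    pre <- prescreen_unique(g_in, g_ctl, fdr_level = cfg$fdr_level)
    screen <- dominance_screen(pre, g_pw, attr(g_in, "norm"),
                               attr(g_in, "samples"),
                               fdr_level = cfg$fdr_level, control = control)
    means <- tissue_means(sim$counts, sim$samples, size_factors = sf)
    final <- fold_filters(screen, means, filters = cfg$filters,
                          scale = cfg$scale, control = control)
    lists <- data.frame(
      gene_id = unlist(final$unique, use.names = FALSE),
      tissue = rep(names(final$unique), lengths(final$unique)))
    write_table(lists, stage_file(out_dir, "unique_genes.tsv"))
    if (!is.null(final$diagnostics))
      write_table(final$diagnostics,
                  stage_file(out_dir, "unique_diagnostics.tsv"))
    c(list(prescreen_union = pre$union_size),
      as.list(setNames(lengths(final$unique),
                       paste0("unique_", names(final$unique)))))
  })

  run_stage("codon", function() {
    tcfg <- cfg$transcriptome
    tsim <- simulate_transcriptome(
      n_genes = tcfg$n_genes,
      biased_codons = default_codon_bias(tcfg$bias_strength),
      seed = derive_seed(cfg$seed, "codon"))
    write_transcripts(tsim$transcripts, stage_file(out_dir, "cds.fa"))
    more <- tsim$truth$gene_id[tsim$truth$class == "high"]
    less <- tsim$truth$gene_id[tsim$truth$class == "low"]
    usage_more <- count_codons(more, tsim$transcripts)
    usage_less <- count_codons(less, tsim$transcripts)
    chg <- percent_change(usage_more, usage_less)
    write_table(chg, stage_file(out_dir, "codon_usage.tsv"))
    list(codons = nrow(chg),
         r2_more_vs_less = usage_correlation(usage_more, usage_less))
  })

  run_stage("indel", function() {
    fx <- deletion_fixtures()
    rows <- lapply(names(fx), function(nm) {
      f <- fx[[nm]]
      rep <- suppressWarnings(
        characterize_deletion(f$wt, f$mut, f$wt_span, f$mut_span))
      data.frame(allele = nm, gene_id = f$gene_id,
                 span_deletion = rep$span_length,
                 aligned_deletion = rep$alignment$length,
                 position = rep$alignment$position,
                 frameshift = rep$alignment$frameshift,
                 consistent = rep$agree, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    write_table(tab, stage_file(out_dir, "deletion_report.tsv"))
    setNames(as.list(tab$span_deletion), paste0(tab$allele, "_bp"))
  })

  jsonlite::write_json(manifest, stage_file(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
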