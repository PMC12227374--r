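# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param(field, "must be a single proportion in [0, 1]")
  x
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_param(field, "must be a single positive integer")
  as.integer(x)
}

# deterministic per-stage seed derived from a master seed and a stage name;
# keeps stages decoupled while reproducible (kept below 2^31 - 1)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# row-wise minimum that returns NA only when the whole row is NA
row_min <- function(m) {
  out <- suppressWarnings(apply(m, 1L, min, na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !is.null(rownames(x)) && !is.null(colnames(x))
}

check_counts_samples <- function(counts, samples) {
  if (!is_count_matrix(counts))
    stop("`counts` must be a numeric matrix with gene rownames and sample colnames",
         call. = FALSE)
  if (any(counts < 0)) stop("count matrix has negative entries", call. = FALSE)
  missing <- setdiff(colnames(counts), samples$sample)
  extra <- setdiff(samples$sample, colnames(counts))
  if (length(missing) || length(extra))
    stop("count matrix columns and sample sheet disagree: ",
         if (length(missing)) paste0("columns without sheet rows: ",
                                     paste(missing, collapse = ", "), "; "),
         if (length(extra)) paste0("sheet rows without columns: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  samples[match(colnames(counts), samples$sample), , drop = FALSE]
}
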