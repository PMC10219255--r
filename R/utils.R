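# Internal helpers shared across modules.

# Convert a wide count tibble (gene_id + one column per sample) to a numeric
# matrix with gene_id rownames. Validates non-negativity and id uniqueness.
count_matrix <- function(counts, what = "counts") {
  if (!"gene_id" %in% names(counts)) {
    abort(paste0(what, " must have a 'gene_id' column"))
  }
  if (anyDuplicated(counts$gene_id) > 0) {
    abort(paste0(what, ": gene_id values must be unique"))
  }
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (!is.numeric(m)) abort(paste0(what, ": sample columns must be numeric"))
  if (anyNA(m)) abort(paste0(what, ": missing values are not allowed"))
  if (any(m < 0)) abort(paste0(what, ": negative counts are not allowed"))
  rownames(m) <- counts$gene_id
  m
}

# Inverse of count_matrix().
as_count_tbl <- function(m) {
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

# Restrict and order count columns to the samples in a sample sheet.
align_counts <- function(counts, samples) {
  missing <- setdiff(samples$sample_id, names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts are missing sample columns: ",
                 paste(missing, collapse = ", ")))
  }
  counts[, c("gene_id", samples$sample_id)]
}

check_sample_sheet <- function(samples, need = "sample_id") {
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id) > 0) abort("sample_id values must be unique")
  invisible(samples)
}

check_probability <- function(p, what = "p") {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort(paste0(what, " values must lie in [0, 1]"))
  }
  invisible(p)
}
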