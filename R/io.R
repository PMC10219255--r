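# Readers and writers for the plain-text interchange formats the pipeline
# consumes: counts TSV (gene_id + one column per sample), sample sheet CSV,
# annotation TSV (gene_id, length_nt), lifespans CSV (group, lifespan_days),
# long-format Ct CSV, and GMT gene-set collections.

#' Read / write a wide count table (TSV)
#' @param path File path.
#' @return Tibble with `gene_id` and one numeric column per sample.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  count_matrix(x) # validates
  x
}

#' @rdname read_counts
#' @param counts Wide count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a sample sheet (CSV)
#' @param path File path; needs at least a `sample_id` column.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  check_sample_sheet(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a gene annotation table (TSV with gene_id, length_nt)
#' @param path File path.
#' @return Tibble.
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "length_nt") %in% names(x))) {
    abort("annotation needs columns gene_id and length_nt")
  }
  if (any(x$length_nt <= 0)) abort("transcript lengths must be positive")
  x
}

#' Read a lifespan table (CSV with group, lifespan_days)
#' @param path File path.
#' @return Tibble.
#' @export
read_lifespans <- function(path) {
  check_lifespans(readr::read_csv(path, show_col_types = FALSE))
}

#' Read a long-format qPCR Ct table (CSV)
#' @param path File path.
#' @return Tibble with sample_id, group, gene_id, technical_rep, ct.
#' @export
read_ct_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "group", "gene_id", "ct")
  if (!all(need %in% names(x))) {
    abort(paste("Ct table needs columns", paste(need, collapse = ", ")))
  }
  x
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   then member genes).
#' @return Tibble with columns `set_name`, `gene_id`.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  imap(sets, ~ tibble(set_name = .y, gene_id = .x)) |> list_rbind()
}
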