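#' Per-sample delta-Ct values
#'
#' Technical replicates are averaged first; then, per biological sample,
#' `dCt = Ct(reference) - Ct(target)` for each reference gene, combined
#' across references by their arithmetic mean. Samples missing the target
#' or any reference are dropped with a warning. Any per-sample plate
#' offset common to all genes cancels exactly.
#'
#' @param ct_table Long Ct tibble with columns `sample_id`, `group`,
#'   `gene_id`, `technical_rep`, `ct` (as from [simulate_qpcr()] or
#'   [read_ct_table()]); extra metadata columns (sex, age_weeks, ...) are
#'   carried through.
#' @param target Target gene name.
#' @param references Character vector of reference gene names.
#' @param per_reference If `TRUE`, return one row per sample x reference
#'   instead of the across-reference mean.
#' @return Tibble with one row per sample (`delta_ct`), or per sample and
#'   reference when `per_reference = TRUE`.
#' @export
delta_ct <- function(ct_table, target, references, per_reference = FALSE) {
  need <- c("sample_id", "group", "gene_id", "ct")
  if (!all(need %in% names(ct_table))) {
    abort("ct_table needs columns sample_id, group, gene_id, ct")
  }
  if (any(ct_table$ct <= 0)) abort("Ct values must be positive")
  genes <- c(references, target)
  meta_cols <- intersect(c("group", "sex", "age_weeks"), names(ct_table))
  averaged <- ct_table |>
    filter(.data$gene_id %in% genes) |>
    group_by(.data$sample_id, across(all_of(meta_cols)), .data$gene_id) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  complete <- averaged |>
    count(.data$sample_id) |>
    filter(.data$n == length(genes)) |>
    pull(.data$sample_id)
  dropped <- setdiff(unique(averaged$sample_id), complete)
  if (length(dropped) > 0) {
    warn(paste0("dropping sample(s) missing target or reference Ct: ",
                paste(dropped, collapse = ", ")))
  }
  wide <- averaged |>
    filter(.data$sample_id %in% complete) |>
    pivot_wider(names_from = "gene_id", values_from = "ct")
  if (nrow(wide) == 0) abort("no samples with complete Ct measurements")
  long <- wide |>
    pivot_longer(all_of(references), names_to = "reference",
                 values_to = "ct_reference") |>
    mutate(delta_ct = .data$ct_reference - .data[[target]]) |>
    select("sample_id", all_of(meta_cols), "reference", "delta_ct")
  if (per_reference) return(long)
  long |>
    group_by(.data$sample_id, across(all_of(meta_cols))) |>
    summarise(delta_ct = mean(.data$delta_ct), .groups = "drop")
}

#' Minus delta-delta-Ct between treatment and control
#'
#' `-ddCt = mean dCt(test) - mean dCt(ref)`, the qPCR analogue of the
#' RNA-seq log2 fold change under amplification efficiency 2; computed
#' within each combination of `by` columns when given.
#'
#' @param delta_cts Output of [delta_ct()].
#' @param test,ref Group labels (treatment and control).
#' @param by Optional extra grouping columns (e.g. `c("sex", "age_weeks")`).
#' @return Tibble with the `by` columns and `neg_ddct`.
#' @export
neg_delta_delta_ct <- function(delta_cts, test = "torin", ref = "control",
                               by = NULL) {
  if (!"group" %in% names(delta_cts)) abort("delta_cts needs a group column")
  out <- delta_cts |>
    filter(.data$group %in% c(test, ref)) |>
    group_by(across(all_of(by))) |>
    summarise(
      neg_ddct = {
        a <- .data$delta_ct[.data$group == test]
        b <- .data$delta_ct[.data$group == ref]
        if (length(a) == 0 || length(b) == 0) {
          abort("both groups must be represented")
        }
        mean(a) - mean(b)
      },
      .groups = "drop")
  out
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' Joins per-group `-ddCt` values with RNA-seq log2 fold changes on the
#' given keys and reports their difference and whether the signs agree.
#' A zero on either side counts as agreement (no sign conflict), so
#' "decreased or unchanged" profiles are concordant.
#'
#' @param qpcr Tibble with key columns and `neg_ddct` (from
#'   [neg_delta_delta_ct()]).
#' @param rnaseq Tibble with the same key columns and `log2fc`.
#' @param by Key columns to join on.
#' @return Tibble with the keys, both estimates, `difference`
#'   (`neg_ddct - log2fc`) and `sign_agreement`.
#' @export
concordance <- function(qpcr, rnaseq, by = c("sex", "age_weeks")) {
  if (!"neg_ddct" %in% names(qpcr)) abort("qpcr needs a neg_ddct column")
  if (!"log2fc" %in% names(rnaseq)) abort("rnaseq needs a log2fc column")
  if (!setequal(do.call(paste, qpcr[by]), do.call(paste, rnaseq[by]))) {
    abort("qpcr and rnaseq must cover the same groups")
  }
  inner_join(qpcr, rnaseq, by = by) |>
    mutate(difference = .data$neg_ddct - .data$log2fc,
           sign_agreement = sign(.data$neg_ddct) * sign(.data$log2fc) >= 0)
}
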