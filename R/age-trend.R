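#' Mean log2 CPM trajectories over the three ages
#'
#' Summarises expression as `log2(CPM + 0.5)` averaged over replicates per
#' age, within each combination of `group_vars` (by default sex and diet).
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet with `age_weeks` and the grouping columns.
#' @param group_vars Sample sheet columns defining the trajectory groups.
#' @return Tibble with `gene_id`, the grouping columns and one
#'   `log2cpm_<age>` column per age.
#' @export
age_trajectories <- function(counts, samples, group_vars = c("sex", "diet")) {
  check_sample_sheet(samples, c("sample_id", "age_weeks", group_vars))
  counts <- align_counts(counts, samples)
  cpm(counts) |>
    pivot_longer(-"gene_id", names_to = "sample_id", values_to = "cpm") |>
    left_join(samples, by = "sample_id") |>
    group_by(.data$gene_id, across(all_of(group_vars)), .data$age_weeks) |>
    summarise(log2cpm = mean(log2(.data$cpm + 0.5)), .groups = "drop") |>
    pivot_wider(names_from = "age_weeks", values_from = "log2cpm",
                names_prefix = "log2cpm_")
}

#' Age-associated fold change from the 3-point slope
#'
#' Fits an ordinary least-squares line to log2 expression at the three
#' ages (coded 0, 1, 2 for 2, 4 and 6 weeks) and reports `2^(2b)`, the
#' fitted old-vs-young expression ratio: it is 4 when expression in old
#' individuals is 4x that of young ones and 2x that of middle-aged ones,
#' and 1 for a flat trajectory.
#'
#' @param traj Trajectory tibble with three `log2cpm_<age>` columns (as
#'   from [age_trajectories()]); all values must be finite.
#' @return `traj` with added `age_slope` (log2 per timepoint) and
#'   `aa_fold_change` (linear scale).
#' @examples
#' traj <- tibble::tibble(gene_id = "g1", log2cpm_2 = log2(1),
#'                        log2cpm_4 = log2(2), log2cpm_6 = log2(4))
#' aa_fold_change(traj)$aa_fold_change # 4
#' @export
aa_fold_change <- function(traj) {
  cols <- grep("^log2cpm_", names(traj), value = TRUE)
  if (length(cols) != 3) abort("trajectories must have exactly 3 age columns")
  cols <- cols[order(as.numeric(sub("^log2cpm_", "", cols)))]
  y <- as.matrix(traj[cols])
  if (anyNA(y) || any(!is.finite(y))) abort("trajectory values must be finite")
  # OLS slope on x = 0, 1, 2 reduces to (y3 - y1) / 2
  b <- (y[, 3] - y[, 1]) / 2
  traj |> mutate(age_slope = unname(b), aa_fold_change = 2^(2 * unname(b)))
}

#' Classify genes as age-associated
#'
#' A gene is called up (down) with age iff its test p-value passes
#' `p_threshold` and the log2 age-associated fold change strictly exceeds
#' `logfc_threshold` in magnitude, with the matching sign; otherwise
#' `none`. The p-value is taken from the young-vs-old consensus contrast.
#'
#' @param de_table Consensus result for the young-vs-old contrast
#'   (columns `gene_id` and `consensus_p`, or any table with a `p_value`
#'   column).
#' @param aa_table Output of [aa_fold_change()] over the same gene set.
#' @param p_threshold,logfc_threshold Decision thresholds (strict
#'   inequalities: p < 0.05, |log2 aa FC| > 0.3 by default).
#' @return Tibble with `gene_id`, `aa_fold_change`, `p_value`,
#'   `direction` in `up`/`down`/`none`.
#' @export
classify_age_associated <- function(de_table, aa_table,
                                    p_threshold = 0.05,
                                    logfc_threshold = 0.3) {
  if (!setequal(de_table$gene_id, aa_table$gene_id)) {
    abort("de_table and aa_table must cover the same genes")
  }
  pcol <- if ("consensus_p" %in% names(de_table)) "consensus_p" else "p_value"
  joined <- aa_table |>
    select("gene_id", "aa_fold_change") |>
    left_join(de_table |> select("gene_id", p_value = all_of(pcol)),
              by = "gene_id")
  joined |>
    mutate(direction = case_when(
      .data$p_value < p_threshold &
        log2(.data$aa_fold_change) > logfc_threshold ~ "up",
      .data$p_value < p_threshold &
        log2(.data$aa_fold_change) < -logfc_threshold ~ "down",
      TRUE ~ "none"))
}

#' Group-exclusive (Venn) partition of age-associated gene sets
#'
#' Partitions the union of age-associated genes into every non-empty
#' region of the inclusion-exclusion lattice over groups, separately for
#' up- and downregulated genes. A gene lands in exactly one region per
#' direction: the set of groups in which it was called.
#'
#' @param associations Tibble with columns `group`, `gene_id`,
#'   `direction` (stacked [classify_age_associated()] outputs, one group
#'   label per input).
#' @return Tibble with `direction`, `region` (group names joined by
#'   `"&"`), `n_groups` and `gene_id`.
#' @export
exclusive_sets <- function(associations) {
  need <- c("group", "gene_id", "direction")
  if (!all(need %in% names(associations))) {
    abort("associations needs columns group, gene_id, direction")
  }
  if (length(unique(associations$group)) < 2) {
    abort("at least two groups are required")
  }
  associations |>
    filter(.data$direction %in% c("up", "down")) |>
    distinct(.data$group, .data$gene_id, .data$direction) |>
    group_by(.data$direction, .data$gene_id) |>
    summarise(region = paste(sort(unique(.data$group)), collapse = "&"),
              n_groups = n_distinct(.data$group), .groups = "drop") |>
    select("direction", "region", "n_groups", "gene_id") |>
    arrange(.data$direction, .data$region, .data$gene_id)
}

#' Hypergeometric overrepresentation analysis over GMT gene sets
#'
#' One-sided upper-tail hypergeometric test of each gene set's overlap
#' with the selection, against a user-supplied universe; gene sets are
#' intersected with the universe first, and Benjamini-Hochberg FDR is
#' computed across sets.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param universe Character vector of all testable genes.
#' @param gene_sets Tibble with columns `set_name`, `gene_id` (as from
#'   [read_gmt()]), or a named list of gene id vectors.
#' @return Tibble with `set_name`, `set_size` (within universe),
#'   `overlap`, `p_value`, `fdr`, ordered by p-value.
#' @examples
#' ora(selected = letters[1:5], universe = letters[1:10],
#'     gene_sets = list(s1 = letters[1:5]))
#' @export
ora <- function(selected, universe, gene_sets) {
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- imap(gene_sets,
                      ~ tibble(set_name = .y, gene_id = .x)) |> list_rbind()
  }
  selected <- unique(selected); universe <- unique(universe)
  if (!all(selected %in% universe)) {
    abort("selected genes must be a subset of the universe")
  }
  if (length(selected) == 0) warn("empty selection: all p-values are 1")
  n_univ <- length(universe)
  n_sel <- length(selected)
  gene_sets |>
    filter(.data$gene_id %in% universe) |>
    group_by(.data$set_name) |>
    summarise(set_size = n_distinct(.data$gene_id),
              overlap = n_distinct(intersect(.data$gene_id, selected)),
              .groups = "drop") |>
    mutate(p_value = phyper(.data$overlap - 1, .data$set_size,
                            n_univ - .data$set_size, n_sel,
                            lower.tail = FALSE),
           fdr = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value)
}
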