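#' Correction method 1: 3'-window counting
#'
#' Runs the full DE pipeline (CPM filter, TMM, dispersion, exact test) on
#' counts restricted to the 3'-terminal `min(length, window)` nucleotides
#' of each transcript. Because the 3' window is covered (nearly) uniformly
#' regardless of the decay scale, group differences in 3'-bias cancel out
#' of the windowed counts up to a per-sample factor absorbed by
#' normalization.
#'
#' @param windowed_counts Wide tibble of counts restricted to the 3'
#'   window (e.g. `sim$windowed_counts`, or derived from per-read
#'   coordinates upstream).
#' @param annotation Tibble with `gene_id` and `length_nt`.
#' @param samples,group_var,test,ref,... Passed to [run_de()].
#' @param window Window width in nt (recorded as effective gene length).
#' @return Method result tibble: `gene_id`, `log_fc`, `p_value`, `fdr`,
#'   `mean_cpm`, `effective_length`, `method = "threeprime"`.
#' @export
method1_threeprime <- function(windowed_counts, annotation, samples,
                               group_var = "diet", test = "torin",
                               ref = "control", window = 1000, ...) {
  need <- setdiff(windowed_counts$gene_id, annotation$gene_id)
  if (length(need) > 0) abort("annotation is missing transcript lengths")
  fit <- run_de(windowed_counts, samples, group_var = group_var,
                test = test, ref = ref, ...)
  fit$table |>
    left_join(annotation, by = "gene_id") |>
    mutate(effective_length = pmin(.data$length_nt, window),
           method = "threeprime") |>
    select(-"length_nt")
}

# Assign genes to equal-count bins on log10 length, ties broken by gene_id.
length_bins <- function(annotation, n_bins, min_bin = 5) {
  ord <- order(log10(annotation$length_nt), annotation$gene_id)
  n <- nrow(annotation)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) * n_bins / n)
  # merge undersized bins into their lower neighbour
  repeat {
    sizes <- table(bin)
    small <- names(sizes)[sizes < min_bin]
    if (length(small) == 0 || length(sizes) == 1) break
    warn("length bin with fewer than 5 genes merged with its neighbour")
    b <- as.integer(small[1])
    ids <- sort(unique(bin))
    nb <- if (b == min(ids)) ids[ids > b][1] else max(ids[ids < b])
    bin[bin == b] <- nb
  }
  tibble(gene_id = annotation$gene_id, bin = bin)
}

#' Correction method 2: length-binned TMM renormalization
#'
#' After the CPM filter, genes are split into `n_bins` equal-count bins on
#' log10 transcript length (ties broken by gene id); TMM factors are
#' computed within each bin and applied as per-sample, per-bin effective
#' scalings before the exact test. The resulting fold changes are then
#' passed through the length-slope alignment of [method3_slope_align()].
#'
#' @param counts Wide tibble of full-length counts.
#' @param annotation Tibble with `gene_id`, `length_nt`.
#' @param samples,group_var,test,ref Contrast definition, as in [run_de()].
#' @param n_bins Number of length bins (bins with < 5 genes are merged
#'   with a neighbour, with a warning).
#' @param cpm_threshold,min_fraction Passed to [filter_by_cpm()].
#' @param dispersion Optional fixed dispersion; estimated globally if NULL.
#' @return Method result tibble with `method = "binned_tmm"`.
#' @export
method2_binned_tmm <- function(counts, annotation, samples,
                               group_var = "diet", test = "torin",
                               ref = "control", n_bins = 10,
                               cpm_threshold = 1, min_fraction = 0.5,
                               dispersion = NULL) {
  check_sample_sheet(samples, c("sample_id", group_var))
  samples <- samples[samples[[group_var]] %in% c(test, ref), , drop = FALSE]
  counts <- align_counts(counts, samples)
  filt <- filter_by_cpm(counts, samples, group_vars = group_var,
                        threshold = cpm_threshold, min_fraction = min_fraction)
  if (nrow(filt) < 3) abort("too few genes after filtering for binned TMM")
  if (!all(filt$gene_id %in% annotation$gene_id)) {
    abort("annotation is missing transcript lengths")
  }
  ann <- annotation[match(filt$gene_id, annotation$gene_id), ]
  groups <- factor(samples[[group_var]], levels = c(ref, test))
  m <- count_matrix(filt)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(filt, groups)
  bins <- length_bins(ann, n_bins)
  adj <- m
  for (b in unique(bins$bin)) {
    idx <- bins$bin == b
    fb <- tmm_core(m[idx, , drop = FALSE])
    adj[idx, ] <- adjust_counts(m[idx, , drop = FALSE], fb)
  }
  tab <- exact_test_core(adj, groups, dispersion)
  tab$log_fc <- slope_align(tab$log_fc, log10(ann$length_nt))
  tab |> mutate(method = "binned_tmm")
}

# Remove the OLS trend of a fold-change vector on log10 length, preserving
# the mean exactly. Degenerate inputs are returned unchanged with a warning.
slope_align <- function(log_fc, log10_length) {
  ok <- is.finite(log_fc) & is.finite(log10_length)
  if (sum(ok) < 3) abort("slope alignment needs >= 3 genes with finite values")
  x <- log10_length[ok]
  if (var(x) == 0) {
    warn("all transcript lengths equal: slope undefined, fold changes unchanged")
    return(log_fc)
  }
  b <- sum((x - mean(x)) * (log_fc[ok] - mean(log_fc[ok]))) / sum((x - mean(x))^2)
  out <- log_fc
  out[ok] <- log_fc[ok] - b * (x - mean(x))
  out
}

#' Correction method 3: length-slope alignment of fold changes
#'
#' Fits `log_fc ~ log10(length)` by ordinary least squares across genes and
#' subtracts the fitted trend, leaving the mean fold change unchanged; the
#' aligned vector has exactly zero residual slope against log10 length.
#' P-values are untouched.
#'
#' @param de_table DE result tibble with `gene_id` and `log_fc` (e.g.
#'   `tidy(run_de(...))`).
#' @param annotation Tibble with `gene_id`, `length_nt`.
#' @return Method result tibble with aligned `log_fc` and
#'   `method = "slope_only"`; the removed slope is in attribute
#'   `"alignment_slope"`.
#' @examples
#' tab <- tibble::tibble(gene_id = c("a", "b", "c"), log_fc = c(2, 4, 6))
#' ann <- tibble::tibble(gene_id = c("a", "b", "c"), length_nt = 10^(1:3))
#' method3_slope_align(tab, ann)$log_fc # 4 4 4
#' @export
method3_slope_align <- function(de_table, annotation) {
  if (!all(de_table$gene_id %in% annotation$gene_id)) {
    abort("annotation is missing transcript lengths")
  }
  x <- log10(annotation$length_nt[match(de_table$gene_id, annotation$gene_id)])
  before <- de_table$log_fc
  aligned <- slope_align(before, x)
  slope <- if (var(x) == 0) 0 else {
    sum((x - mean(x)) * (before - mean(before))) / sum((x - mean(x))^2)
  }
  out <- de_table |> mutate(log_fc = aligned, method = "slope_only")
  attr(out, "alignment_slope") <- slope
  out
}

#' Conservative per-gene consensus over the three correction methods
#'
#' For each gene: if the three fold-change estimates do not share one sign
#' (strict sign conflict, zeros agree with either sign), the gene is
#' zeroed (`consensus_log_fc = 0`, `consensus_p = 1`,
#' `chosen_method = "zeroed"`); otherwise the estimate with the minimum
#' absolute value wins and carries its method's p-value (ties go to the
#' first method in argument order). FDR is recomputed by
#' Benjamini-Hochberg on the consensus p-values.
#'
#' @param m1,m2,m3 Method result tibbles over an identical gene set, with
#'   columns `gene_id`, `log_fc`, `p_value` (and optionally `method`).
#' @return Tibble with `gene_id`, `consensus_log_fc`, `chosen_method`,
#'   `consensus_p`, `consensus_fdr`.
#' @examples
#' g <- function(lfc) tibble::tibble(gene_id = "x", log_fc = lfc, p_value = 0.5)
#' consensus(g(0.5), g(0.8), g(-0.2))$consensus_log_fc # 0: sign conflict
#' @export
consensus <- function(m1, m2, m3) {
  ms <- list(m1, m2, m3)
  ids <- m1$gene_id
  if (!identical(sort(ids), sort(m2$gene_id)) ||
      !identical(sort(ids), sort(m3$gene_id))) {
    abort("the three methods must cover identical gene sets")
  }
  method_ids <- vapply(seq_along(ms), function(i) {
    if ("method" %in% names(ms[[i]])) ms[[i]]$method[1] else paste0("method", i)
  }, character(1))
  lfc <- vapply(ms, function(m) m$log_fc[match(ids, m$gene_id)],
                numeric(length(ids)))
  pv <- vapply(ms, function(m) m$p_value[match(ids, m$gene_id)],
               numeric(length(ids)))
  lfc <- matrix(lfc, ncol = 3); pv <- matrix(pv, ncol = 3)
  conflict <- row_min(lfc) * row_max(lfc) < 0
  pick <- max.col(-abs(lfc), ties.method = "first")
  sel <- cbind(seq_along(ids), pick)
  out <- tibble(
    gene_id = ids,
    consensus_log_fc = ifelse(conflict, 0, lfc[sel]),
    chosen_method = ifelse(conflict, "zeroed", method_ids[pick]),
    consensus_p = ifelse(conflict, 1, pv[sel])
  )
  out$consensus_fdr <- p.adjust(out$consensus_p, method = "BH")
  out
}

# Row-wise min/max, returning plain vectors.
row_min <- function(m) do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
row_max <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

#' Length-vs-fold-change diagnostic
#'
#' Pearson correlation and OLS line of `log_fc` against log10 transcript
#' length; under differential 3'-bias between groups this scatter shows a
#' strong trend, and the corrections should flatten it.
#'
#' @param de_table Tibble with `gene_id`, `log_fc`.
#' @param annotation Tibble with `gene_id`, `length_nt`.
#' @return One-row tibble: `n`, `pearson_r`, `slope`, `intercept`,
#'   `degenerate` (TRUE when a correlation is undefined and reported as 0).
#' @export
length_logfc_diagnostic <- function(de_table, annotation) {
  if (nrow(de_table) < 3) abort("diagnostic needs >= 3 genes")
  x <- log10(annotation$length_nt[match(de_table$gene_id, annotation$gene_id)])
  y <- de_table$log_fc
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  degenerate <- var(x) == 0 || var(y) == 0
  if (var(x) == 0) {
    slope <- 0; intercept <- mean(y)
  } else {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    intercept <- mean(y) - slope * mean(x)
  }
  r <- if (degenerate) 0 else cor(x, y)
  tibble(n = sum(ok), pearson_r = r, slope = slope,
         intercept = intercept, degenerate = degenerate)
}

#' Consensus 3'-bias-corrected differential expression
#'
#' End-to-end driver: runs the uncorrected pipeline, the three correction
#' methods (3'-window counting; length-binned TMM with slope alignment;
#' slope alignment alone) for one two-group contrast, restricts all
#' methods to the genes every route retained, and fuses them with the
#' conservative [consensus()] rule. Dispersion is estimated once on the
#' filtered full counts (the 3'-window route estimates its own).
#'
#' @param counts,windowed_counts,annotation,samples Experiment components,
#'   as produced by [simulate_counts()] or read from files.
#' @param group_var,test,ref Contrast definition.
#' @param n_bins Length bins for method 2.
#' @param window 3' window width (nt) used for method 1's effective length.
#' @param cpm_threshold,min_fraction CPM filter parameters.
#' @return A `consensus_de` object: list with `uncorrected` (`de_fit`),
#'   `methods` (named list of method tibbles), `consensus`, `diagnostics`
#'   (length-trend before/after per route), `dispersion`, `contrast`,
#'   `annotation`. `tidy()` returns the consensus table.
#' @examples
#' \donttest{
#' sim <- simulate_counts(sim_config(n_genes = 300, seed = 1,
#'   design = dplyr::filter(default_design(), sex == "male", age_weeks == 2)))
#' fit <- consensus_de(sim$counts, sim$windowed_counts, sim$annotation,
#'                     sim$samples)
#' glance(fit)
#' }
#' @export
consensus_de <- function(counts, windowed_counts, annotation, samples,
                         group_var = "diet", test = "torin", ref = "control",
                         n_bins = 10, window = 1000,
                         cpm_threshold = 1, min_fraction = 0.5) {
  uncor <- run_de(counts, samples, group_var = group_var, test = test,
                  ref = ref, cpm_threshold = cpm_threshold,
                  min_fraction = min_fraction)
  m1 <- method1_threeprime(windowed_counts, annotation, samples,
                           group_var = group_var, test = test, ref = ref,
                           window = window, cpm_threshold = cpm_threshold,
                           min_fraction = min_fraction)
  m2 <- method2_binned_tmm(counts, annotation, samples,
                           group_var = group_var, test = test, ref = ref,
                           n_bins = n_bins, cpm_threshold = cpm_threshold,
                           min_fraction = min_fraction,
                           dispersion = uncor$dispersion)
  m3 <- method3_slope_align(uncor$table, annotation)
  common <- Reduce(intersect, list(m1$gene_id, m2$gene_id, m3$gene_id))
  if (length(common) == 0) abort("no genes shared by all three methods")
  keep <- function(m) m[m$gene_id %in% common, , drop = FALSE]
  m1 <- keep(m1); m2 <- keep(m2); m3 <- keep(m3)
  cons <- consensus(m1, m2, m3)
  diag_tbl <- bind_rows(
    mutate(length_logfc_diagnostic(keep(uncor$table), annotation),
           route = "uncorrected"),
    mutate(length_logfc_diagnostic(m1, annotation), route = "threeprime"),
    mutate(length_logfc_diagnostic(m2, annotation), route = "binned_tmm"),
    mutate(length_logfc_diagnostic(m3, annotation), route = "slope_only"),
    mutate(length_logfc_diagnostic(
      tibble(gene_id = cons$gene_id, log_fc = cons$consensus_log_fc),
      annotation), route = "consensus")
  ) |> select("route", everything())
  structure(
    list(uncorrected = uncor,
         methods = list(threeprime = m1, binned_tmm = m2, slope_only = m3),
         consensus = cons,
         diagnostics = diag_tbl,
         dispersion = uncor$dispersion,
         contrast = uncor$contrast,
         annotation = annotation),
    class = "consensus_de")
}

#' @export
print.consensus_de <- function(x, ...) {
  cat("Consensus 3'-bias-corrected DE:", x$contrast$test, "vs",
      x$contrast$ref, "\n")
  cat("  genes in consensus:", nrow(x$consensus), "\n")
  cat("  zeroed (sign conflict):",
      sum(x$consensus$chosen_method == "zeroed"), "\n")
  cat("  FDR < 0.05: consensus", sum(x$consensus$consensus_fdr < 0.05),
      "| uncorrected", sum(x$uncorrected$table$fdr < 0.05), "\n")
  invisible(x)
}
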