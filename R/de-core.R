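#' Counts per million
#'
#' @param counts Wide count tibble (`gene_id` + one column per sample).
#' @return Tibble of the same shape with CPM values; every sample column
#'   sums to 1e6.
#' @examples
#' cpm(tibble::tibble(gene_id = c("a", "b"), s1 = c(1, 3), s2 = c(2, 2)))
#' @export
cpm <- function(counts) {
  m <- count_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("zero library size in sample(s): ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  as_count_tbl(sweep(m, 2, 1e6 / lib, "*"))
}

#' Filter genes by expression level
#'
#' Keeps a gene iff its CPM is strictly greater than `threshold` in at
#' least `ceiling(min_fraction * n)` samples, where `n` is the size of the
#' smallest group defined by `group_vars` in the sample sheet.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet with `sample_id` and the grouping columns.
#' @param group_vars Columns of `samples` defining the groups whose
#'   smallest size sets the required sample count.
#' @param threshold CPM threshold (strict inequality).
#' @param min_fraction Fraction of the smallest group that must exceed it.
#' @return Filtered count tibble (possibly zero rows, with a warning).
#' @export
filter_by_cpm <- function(counts, samples, group_vars = "diet",
                          threshold = 1, min_fraction = 0.5) {
  check_sample_sheet(samples)
  miss <- setdiff(group_vars, names(samples))
  if (length(miss) > 0) {
    abort(paste0("grouping columns absent from sample sheet: ",
                 paste(miss, collapse = ", ")))
  }
  counts <- align_counts(counts, samples)
  sizes <- samples |> count(across(all_of(group_vars))) |> pull(.data$n)
  if (length(sizes) == 0 || any(sizes == 0)) abort("empty groups")
  required <- ceiling(min_fraction * min(sizes))
  if (sum(count_matrix(counts)) == 0) {
    warn("no genes pass the CPM filter")
    return(counts[0, , drop = FALSE])
  }
  cpm_m <- count_matrix(cpm(counts), "cpm")
  keep <- rowSums(cpm_m > threshold) >= required
  if (!any(keep)) warn("no genes pass the CPM filter")
  counts[keep, , drop = FALSE]
}

# Core trimmed-mean-of-M-values computation on a count matrix. M-values are
# raw log2 count ratios against the reference sample, so the returned
# factors absorb both sequencing depth and composition (size-factor
# convention, geometric mean 1); dividing counts by the factor equalises
# samples. With equal library sizes this coincides with the classic
# library-size-normalised TMM factors.
tmm_core <- function(m, m_trim = 0.30, a_trim = 0.05) {
  ns <- ncol(m)
  if (ns < 2) abort("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    warn("sample(s) with zero total count: TMM factors set to 1")
    return(rep(1, ns))
  }
  cpm_m <- sweep(m, 2, 1e6 / lib, "*")
  f75 <- apply(cpm_m, 2, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(k) {
    if (k == ref) return(1)
    yk <- m[, k]; yr <- m[, ref]
    ok <- yk > 0 & yr > 0
    if (!any(ok)) {
      warn("no genes shared with the reference sample; TMM factor set to 1")
      return(1)
    }
    yk <- yk[ok]; yr <- yr[ok]
    mv <- log2(yk) - log2(yr)
    av <- 0.5 * (log2(yk) + log2(yr))
    w <- (lib[k] - yk) / (lib[k] * yk) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(mv)
    lo_m <- floor(n * m_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * a_trim) + 1; hi_a <- n + 1 - lo_a
    r_m <- rank(mv); r_a <- rank(av)
    keep <- r_m >= lo_m & r_m <= hi_m & r_a >= lo_a & r_a <= hi_a
    if (!any(keep)) {
      warn("no genes survive TMM trimming; factor set to 1")
      return(1)
    }
    2^(sum(w[keep] * mv[keep]) / sum(w[keep]))
  }
  f <- vapply(seq_len(ns), one_factor, numeric(1))
  f / exp(mean(log(f)))
}

#' Trimmed mean of M-values normalization factors
#'
#' Per-sample scaling factors from variance-weighted, doubly trimmed log2
#' count ratios against a reference sample (the sample whose upper-quartile
#' CPM is closest to the mean upper quartile). Factors are size-factor
#' style: they absorb depth and composition, are rescaled to geometric
#' mean 1, and `counts / factor` puts all samples on a common scale.
#'
#' @param counts Wide count tibble (>= 2 samples).
#' @param m_trim Two-sided trim fraction on M-values.
#' @param a_trim Two-sided trim fraction on A-values (average abundance).
#' @return Tibble with columns `sample_id` and `tmm_factor`.
#' @examples
#' x <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                     a = c(10, 20, 30, 40), b = c(20, 40, 60, 80))
#' tmm_factors(x) # (1/sqrt(2), sqrt(2))
#' @export
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  m <- count_matrix(counts)
  tibble(sample_id = colnames(m), tmm_factor = tmm_core(m, m_trim, a_trim))
}

# Rescale counts to a common scale: proportional rescaling + rounding as a
# fast stand-in for exact quantile adjustment.
adjust_counts <- function(m, factors) {
  round(sweep(m, 2, factors, "/"))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Counts are put on a common scale with TMM factors, then the common
#' dispersion phi maximises the negative-binomial likelihood conditional on
#' each gene's within-group total (summed over genes and groups). The
#' estimate is clipped at 0; Poisson data return (numerically) 0.
#'
#' @param counts Wide count tibble.
#' @param groups Factor (or vector) of group labels, one per sample column,
#'   in column order. At least one group needs >= 2 replicates.
#' @return Single dispersion value phi >= 0.
#' @export
estimate_dispersion <- function(counts, groups) {
  m <- count_matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) abort("groups must match the sample columns")
  if (sum(m) == 0) abort("all-zero count matrix")
  if (max(table(groups)) < 2) {
    abort("dispersion is unidentifiable without replicates (need >= 2 samples in a group)")
  }
  adj <- adjust_counts(m, tmm_core(m))
  group_mats <- lapply(levels(groups)[table(groups) >= 2], function(g) {
    adj[, groups == g, drop = FALSE]
  })
  cll <- function(phi) {
    r <- 1 / phi
    tot <- 0
    for (sub in group_mats) {
      n <- ncol(sub)
      z <- rowSums(sub)
      tot <- tot + sum(lgamma(sub + r)) - nrow(sub) * n * lgamma(r) +
        sum(lgamma(n * r) - lgamma(z + n * r))
    }
    tot
  }
  opt <- optimize(function(d) cll(d / (1 - d)),
                  interval = c(1e-8, 0.98), maximum = TRUE)
  phi <- opt$maximum / (1 - opt$maximum)
  if (phi < 1e-6) phi <- 0
  phi
}

# Two-sided conditional exact test p-value for one gene: enumerate all
# splits j + (t - j) of the total t between the two groups and sum the
# probabilities of splits no more likely than the observed one.
exact_test_p <- function(y1, t, n1, n2, phi) {
  if (t == 0) return(1)
  j <- 0:t
  if (phi <= 0) {
    lf <- dbinom(j, t, n1 / (n1 + n2), log = TRUE)
  } else {
    mu_per_sample <- t / (n1 + n2)
    lf <- dnbinom(j, size = n1 / phi, mu = n1 * mu_per_sample, log = TRUE) +
      dnbinom(t - j, size = n2 / phi, mu = n2 * mu_per_sample, log = TRUE)
  }
  lf <- lf - max(lf)
  f <- exp(lf)
  sum(f[lf <= lf[y1 + 1] + 1e-10]) / sum(f)
}

# Exact test on an already-normalised (integer) matrix.
exact_test_core <- function(adj, groups, dispersion, prior_count = 0.125) {
  lev <- levels(groups)
  i1 <- groups == lev[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  y1 <- rowSums(adj[, i1, drop = FALSE])
  y2 <- rowSums(adj[, !i1, drop = FALSE])
  t <- y1 + y2
  p <- vapply(seq_along(t), function(g) {
    exact_test_p(y1[g], t[g], n1, n2, dispersion)
  }, numeric(1))
  log_fc <- log2((y2 / n2 + prior_count) / (y1 / n1 + prior_count))
  lib <- colSums(adj)
  mean_cpm <- if (all(lib > 0)) {
    rowMeans(sweep(adj, 2, 1e6 / lib, "*"))
  } else {
    rep(NA_real_, nrow(adj))
  }
  tibble(gene_id = rownames(adj), log_fc = log_fc, p_value = p,
         fdr = p.adjust(p, method = "BH"), mean_cpm = mean_cpm)
}

#' Negative-binomial exact test for a two-group contrast
#'
#' Counts are rescaled to a common scale with the normalization factors,
#' then each gene's split of its total between the two groups is compared
#' with its conditional negative-binomial distribution under equal means;
#' the two-sided p-value sums the probabilities of all splits no more
#' likely than the observed one. The log2 fold change compares normalized
#' group means (second factor level vs first) with a prior count of 0.125
#' guarding against zeros.
#'
#' @param counts Wide count tibble.
#' @param groups Factor with exactly two levels, one value per sample
#'   column in order; the contrast is `levels[2]` vs `levels[1]`.
#' @param dispersion Common NB dispersion phi (0 = Poisson).
#' @param factors Optional per-sample normalization factors (defaults to
#'   [tmm_factors()] of `counts`).
#' @param prior_count Prior count for the fold-change ratio.
#' @return Tibble with `gene_id`, `log_fc`, `p_value`, `fdr` (BH across
#'   genes), `mean_cpm`.
#' @export
exact_test <- function(counts, groups, dispersion, factors = NULL,
                       prior_count = 0.125) {
  m <- count_matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("exact_test needs exactly two groups")
  if (length(groups) != ncol(m)) abort("groups must match the sample columns")
  lib_by_group <- tapply(colSums(m), groups, sum)
  if (any(lib_by_group == 0)) abort("a group has zero total library size")
  if (is.null(factors)) factors <- tmm_core(m)
  exact_test_core(adjust_counts(m, factors), groups, dispersion, prior_count)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment with monotonicity enforcement; order-preserving under
#' permutation of the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted FDR values in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p_values) {
  check_probability(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Run the uncorrected differential-expression pipeline
#'
#' CPM filter, TMM factors, common dispersion (unless supplied) and the
#' conditional exact test, for one two-group contrast defined on a sample
#' sheet column.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet; only rows whose `group_var` is `test` or
#'   `ref` are used.
#' @param group_var Sample sheet column defining the contrast.
#' @param test,ref Levels of `group_var` to compare (`test` vs `ref`).
#' @param cpm_threshold,min_fraction Passed to [filter_by_cpm()].
#' @param dispersion Optional fixed dispersion; estimated if `NULL`.
#' @return A `de_fit` object; `tidy()` extracts the per-gene table.
#' @export
run_de <- function(counts, samples, group_var = "diet",
                   test = "torin", ref = "control",
                   cpm_threshold = 1, min_fraction = 0.5,
                   dispersion = NULL) {
  check_sample_sheet(samples, c("sample_id", group_var))
  samples <- samples[samples[[group_var]] %in% c(test, ref), , drop = FALSE]
  if (!all(c(test, ref) %in% samples[[group_var]])) {
    abort("both contrast levels must be present in the sample sheet")
  }
  counts <- align_counts(counts, samples)
  filt <- filter_by_cpm(counts, samples, group_vars = group_var,
                        threshold = cpm_threshold, min_fraction = min_fraction)
  groups <- factor(samples[[group_var]], levels = c(ref, test))
  if (nrow(filt) == 0) {
    warn("no genes left after filtering; empty result")
    tab <- tibble(gene_id = character(), log_fc = numeric(),
                  p_value = numeric(), fdr = numeric(), mean_cpm = numeric())
    fac <- tibble(sample_id = samples$sample_id,
                  tmm_factor = rep(1, nrow(samples)))
    disp <- dispersion %||% NA_real_
  } else {
    fac <- tmm_factors(filt)
    disp <- dispersion %||% estimate_dispersion(filt, groups)
    tab <- exact_test(filt, groups, disp, factors = fac$tmm_factor)
  }
  structure(list(table = tab, factors = fac, dispersion = disp,
                 contrast = list(var = group_var, test = test, ref = ref),
                 samples = samples),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat("Exact-test DE fit:", x$contrast$test, "vs", x$contrast$ref,
      "(", x$contrast$var, ")\n")
  cat("  genes tested:", nrow(x$table),
      "| samples:", nrow(x$samples),
      "| dispersion:", signif(x$dispersion, 3), "\n")
  cat("  genes at FDR < 0.05:", sum(x$table$fdr < 0.05), "\n")
  invisible(x)
}
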