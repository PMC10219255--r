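#' Empirical survival curve for uncensored lifespan data
#'
#' With every death observed, the Kaplan-Meier estimator reduces to the
#' empirical survival function S(t) = fraction of individuals alive after
#' day t; the curve starts at 1 and reaches 0 at the last death.
#'
#' @param cohort Tibble with `group` and `lifespan_days` (positive
#'   integers).
#' @return Tibble with `group`, `day` (0..max) and `survival`.
#' @export
km_curve <- function(cohort) {
  check_lifespans(cohort)
  cohort |>
    group_by(.data$group) |>
    reframe({
      ls <- .data$lifespan_days
      days <- 0:max(ls)
      tibble(day = days,
             survival = vapply(days, function(d) mean(ls > d), numeric(1)))
    })
}

check_lifespans <- function(cohort, n_groups = NULL) {
  if (!all(c("group", "lifespan_days") %in% names(cohort))) {
    abort("lifespan data needs columns group and lifespan_days")
  }
  if (nrow(cohort) == 0) abort("empty cohort")
  if (any(cohort$lifespan_days < 1)) abort("lifespans must be >= 1 day")
  k <- length(unique(cohort$group))
  if (!is.null(n_groups) && k != n_groups) {
    abort(paste("expected", n_groups, "groups, found", k))
  }
  invisible(cohort)
}

#' Log-rank test between lifespan cohorts
#'
#' Standard log-rank statistic with hypergeometric variance at each
#' distinct death day (so heavy ties from daily collection are handled),
#' computed via [survival::survdiff()] on the complete (uncensored) data;
#' the p-value is from the chi-square reference with `k - 1` df.
#'
#' @param cohort Tibble with `group` and `lifespan_days` (2 or more
#'   groups, each non-empty).
#' @return One-row tibble with `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(cohort) {
  check_lifespans(cohort)
  if (length(unique(cohort$group)) < 2) abort("need at least two groups")
  fit <- survival::survdiff(
    survival::Surv(cohort$lifespan_days, rep(1, nrow(cohort))) ~ cohort$group)
  df <- length(fit$n) - 1
  tibble(chisq = unname(fit$chisq), df = df,
         p_value = pchisq(unname(fit$chisq), df, lower.tail = FALSE))
}

# Shared 2x2 dichotomisation test: group x (lifespan > threshold).
threshold_fisher <- function(cohort, threshold) {
  grp <- factor(cohort$group)
  above <- factor(cohort$lifespan_days > threshold, levels = c(FALSE, TRUE))
  tab <- table(grp, above)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  list(table = tab, p_value = p, degenerate = degenerate)
}

#' Fisher exact test on median lifespan
#'
#' Dichotomises every individual at the pooled median lifespan and tests
#' the resulting 2x2 table (group x above/below) with the two-sided
#' Fisher exact test; ties sit in the "<= median" cell. Group medians are
#' reported alongside.
#'
#' @param cohort Tibble with `group` and `lifespan_days`; exactly two
#'   groups.
#' @return One-row tibble with the group labels and medians, the pooled
#'   median, `p_value`, and `degenerate` (TRUE when a zero margin forces
#'   p = 1).
#' @export
median_fisher <- function(cohort) {
  check_lifespans(cohort, n_groups = 2)
  m <- median(cohort$lifespan_days)
  ft <- threshold_fisher(cohort, m)
  groups <- levels(factor(cohort$group))
  med <- tapply(cohort$lifespan_days, factor(cohort$group), median)
  tibble(group_1 = groups[1], group_2 = groups[2],
         median_1 = unname(med[1]), median_2 = unname(med[2]),
         pooled_median = m, p_value = ft$p_value,
         degenerate = ft$degenerate)
}

#' Wang-Allison test on maximum lifespan
#'
#' Dichotomises at the pooled `quantile` lifespan (90th percentile by
#' default) and applies the two-sided Fisher exact test to the 2x2 table
#' of group x above/below; ties count as "<= threshold". With
#' `quantile = 0.5` this reduces to [median_fisher()].
#'
#' @param cohort Tibble with `group` and `lifespan_days`; exactly two
#'   groups.
#' @param quantile Pooled quantile defining "maximum lifespan".
#' @return One-row tibble with the group labels, the per-group `quantile`
#'   lifespans, the pooled `threshold`, `p_value` and `degenerate`.
#' @export
wang_allison <- function(cohort, quantile = 0.9) {
  check_lifespans(cohort, n_groups = 2)
  thr <- stats::quantile(cohort$lifespan_days, quantile, names = FALSE)
  ft <- threshold_fisher(cohort, thr)
  groups <- levels(factor(cohort$group))
  q <- tapply(cohort$lifespan_days, factor(cohort$group),
              stats::quantile, probs = quantile, names = FALSE)
  tibble(group_1 = groups[1], group_2 = groups[2],
         quantile_1 = unname(q[1]), quantile_2 = unname(q[2]),
         threshold = thr, p_value = ft$p_value, degenerate = ft$degenerate)
}

#' Bonferroni adjustment
#'
#' @param p_values P-values in \[0, 1\].
#' @param m Number of comparisons; must be at least `length(p_values)`.
#' @return `pmin(1, m * p)`.
#' @export
adjust_bonferroni <- function(p_values, m = length(p_values)) {
  check_probability(p_values, "p_values")
  if (m < length(p_values)) abort("m must be >= the number of p-values")
  pmin(1, m * p_values)
}

#' Full lifespan comparison battery against a control group
#'
#' For each treated group vs the control: log-rank test on the survival
#' curves, Fisher exact test on median lifespan, and Wang-Allison test on
#' maximum lifespan, with Bonferroni adjustment across comparisons within
#' each test family.
#'
#' @param cohort Tibble with `group` and `lifespan_days`.
#' @param control Label of the control group.
#' @param quantile Wang-Allison quantile.
#' @param bonferroni_m Number of comparisons for the Bonferroni
#'   adjustment; defaults to the number of treated groups.
#' @return Tibble, one row per treated group, with the three raw and
#'   adjusted p-values and per-group summaries.
#' @export
compare_survival <- function(cohort, control = "control", quantile = 0.9,
                             bonferroni_m = NULL) {
  check_lifespans(cohort)
  if (!control %in% cohort$group) abort("control group not found")
  treated <- setdiff(unique(cohort$group), control)
  if (length(treated) == 0) abort("no treated groups to compare")
  m <- bonferroni_m %||% length(treated)
  rows <- map(treated, function(g) {
    sub <- cohort[cohort$group %in% c(control, g), , drop = FALSE]
    lr <- logrank_test(sub)
    mf <- median_fisher(sub)
    wa <- wang_allison(sub, quantile = quantile)
    ctrl_first <- mf$group_1 == control
    tibble(group = g,
           n = sum(sub$group == g),
           median = if (ctrl_first) mf$median_2 else mf$median_1,
           median_control = if (ctrl_first) mf$median_1 else mf$median_2,
           max_quantile = if (ctrl_first) wa$quantile_2 else wa$quantile_1,
           logrank_chisq = lr$chisq, logrank_p = lr$p_value,
           median_fisher_p = mf$p_value, wang_allison_p = wa$p_value)
  }) |> list_rbind()
  rows |>
    mutate(logrank_p_adj = adjust_bonferroni(.data$logrank_p, m),
           median_fisher_p_adj = adjust_bonferroni(.data$median_fisher_p, m),
           wang_allison_p_adj = adjust_bonferroni(.data$wang_allison_p, m))
}
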