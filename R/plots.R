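# ggplot2 displays for the main result types.

#' @describeIn run_de MA plot (mean CPM vs log2 fold change) of a `de_fit`.
#' @param object A fitted object.
#' @param fdr_threshold Significance highlight threshold.
#' @exportS3Method ggplot2::autoplot
autoplot.de_fit <- function(object, fdr_threshold = 0.05, ...) {
  tab <- object$table |>
    mutate(significant = .data$fdr < fdr_threshold)
  ggplot2::ggplot(tab, ggplot2::aes(x = log10(.data$mean_cpm + 0.5),
                                    y = .data$log_fc,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log10 mean CPM", y = "log2 fold change",
                  colour = paste0("FDR < ", fdr_threshold),
                  title = paste(object$contrast$test, "vs",
                                object$contrast$ref))
}

#' @describeIn consensus_de Length vs fold-change scatter for every route
#'   (uncorrected, the three methods and the consensus), with the OLS
#'   trend line whose flattening the corrections target.
#' @param object A fitted object.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_de <- function(object, ...) {
  routes <- bind_rows(
    object$uncorrected$table |> select("gene_id", "log_fc") |>
      mutate(route = "uncorrected"),
    map(object$methods, ~ select(.x, "gene_id", "log_fc")) |>
      list_rbind(names_to = "route"),
    object$consensus |>
      transmute(gene_id = .data$gene_id, log_fc = .data$consensus_log_fc,
                route = "consensus")
  ) |>
    left_join(object$annotation, by = "gene_id") |>
    mutate(route = factor(.data$route,
                          levels = c("uncorrected", "threeprime",
                                     "binned_tmm", "slope_only",
                                     "consensus")))
  ggplot2::ggplot(routes, ggplot2::aes(x = log10(.data$length_nt),
                                       y = .data$log_fc)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~route) +
    ggplot2::labs(x = "log10 transcript length (nt)",
                  y = "log2 fold change")
}

#' Survival curves by group
#'
#' @param cohort Tibble with `group` and `lifespan_days`.
#' @return A ggplot of the empirical survival step functions.
#' @export
plot_survival <- function(cohort) {
  ggplot2::ggplot(km_curve(cohort),
                  ggplot2::aes(x = .data$day, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "day", y = "fraction surviving", colour = NULL)
}

#' qPCR vs RNA-seq fold-change concordance plot
#'
#' @param conc Output of [concordance()].
#' @return A ggplot comparing `-ddCt` with the RNA-seq log2 fold change
#'   per group; points on the diagonal agree perfectly.
#' @export
plot_concordance <- function(conc) {
  ggplot2::ggplot(conc, ggplot2::aes(x = .data$log2fc, y = .data$neg_ddct,
                                     colour = .data$sign_agreement)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "RNA-seq log2 fold change", y = "qPCR -ddCt",
                  colour = "signs agree")
}
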