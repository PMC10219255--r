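# broom-style tidiers for the fitted objects.

#' @describeIn run_de Per-gene result table of a `de_fit`.
#' @param x A `de_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.de_fit <- function(x, ...) x$table

#' @describeIn run_de One-row summary of a `de_fit`.
#' @exportS3Method generics::glance
glance.de_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$table),
         n_samples = nrow(x$samples),
         dispersion = x$dispersion,
         n_fdr_05 = sum(x$table$fdr < 0.05),
         contrast = paste(x$contrast$test, "vs", x$contrast$ref))
}

#' @describeIn consensus_de Consensus table of a `consensus_de` fit.
#' @param x A `consensus_de` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.consensus_de <- function(x, ...) x$consensus

#' @describeIn consensus_de One-row summary of a `consensus_de` fit.
#' @exportS3Method generics::glance
glance.consensus_de <- function(x, ...) {
  tibble(n_genes = nrow(x$consensus),
         n_zeroed = sum(x$consensus$chosen_method == "zeroed"),
         n_fdr_05_consensus = sum(x$consensus$consensus_fdr < 0.05),
         n_fdr_05_uncorrected = sum(x$uncorrected$table$fdr < 0.05),
         dispersion = x$dispersion,
         contrast = paste(x$contrast$test, "vs", x$contrast$ref))
}
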