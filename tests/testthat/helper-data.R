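# Small deterministic fixtures built in code.

male_young_design <- function() {
  dplyr::filter(default_design(), sex == "male", age_weeks == 2)
}

# A tiny hand-sized count table with its sample sheet.
tiny_counts <- function() {
  counts <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    a1 = c(10, 100, 1000, 5),
    a2 = c(12, 110, 900, 6),
    b1 = c(11, 95, 1100, 4),
    b2 = c(9, 105, 950, 7))
  samples <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    diet = c("control", "control", "torin", "torin"))
  list(counts = counts, samples = samples)
}

# One-gene method-result builder for consensus rule tests.
method_row <- function(lfc, p = 0.5, id = "x", method = NULL) {
  out <- tibble::tibble(gene_id = id, log_fc = lfc, p_value = p)
  if (!is.null(method)) out$method <- method
  out
}
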