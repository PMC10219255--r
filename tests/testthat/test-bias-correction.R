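test_that("slope alignment matches closed-form OLS and is idempotent", {
  tab <- tibble::tibble(gene_id = c("a", "b", "c"), log_fc = c(2, 4, 6))
  ann <- tibble::tibble(gene_id = c("a", "b", "c"), length_nt = 10^(1:3))
  out <- method3_slope_align(tab, ann)
  expect_equal(out$log_fc, c(4, 4, 4))
  expect_equal(attr(out, "alignment_slope"), 2)
  expect_equal(mean(out$log_fc), mean(tab$log_fc)) # mean preserved exactly
  # uncorrelated input passes through unchanged
  flat <- tibble::tibble(gene_id = c("a", "b", "c"), log_fc = c(1, 5, 1))
  ann2 <- tibble::tibble(gene_id = c("a", "b", "c"), length_nt = c(10, 100, 1000))
  # symmetric y around the centre x -> slope 0
  expect_equal(method3_slope_align(flat, ann2)$log_fc, flat$log_fc)
  # idempotence and zero residual slope on random input
  set.seed(1)
  big <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                        log_fc = rnorm(200) + 0.5 * log10(1:200))
  bann <- tibble::tibble(gene_id = big$gene_id,
                         length_nt = round(10^runif(200, 2.5, 4.5)))
  once <- method3_slope_align(big, bann)
  twice <- method3_slope_align(once, bann)
  expect_equal(once$log_fc, twice$log_fc, tolerance = 1e-12)
  resid <- length_logfc_diagnostic(once, bann)
  expect_lt(abs(resid$slope), 1e-9)
  # degenerate: all lengths equal
  same_len <- tibble::tibble(gene_id = c("a", "b", "c"), length_nt = c(5, 5, 5))
  expect_warning(unchanged <- method3_slope_align(tab, same_len), "undefined")
  expect_equal(unchanged$log_fc, tab$log_fc)
  expect_error(method3_slope_align(tab[1:2, ], ann), "3 genes")
})

test_that("consensus applies the minimum-magnitude and sign-conflict rules", {
  cons <- function(l1, l2, l3, p = c(0.5, 0.5, 0.5)) {
    consensus(method_row(l1, p[1], method = "threeprime"),
              method_row(l2, p[2], method = "binned_tmm"),
              method_row(l3, p[3], method = "slope_only"))
  }
  conflicted <- cons(0.5, 0.8, -0.2)
  expect_equal(conflicted$consensus_log_fc, 0)
  expect_equal(conflicted$chosen_method, "zeroed")
  expect_equal(conflicted$consensus_p, 1)
  agreed <- cons(1.2, 0.7, 0.9, p = c(0.01, 0.02, 0.03))
  expect_equal(agreed$consensus_log_fc, 0.7)
  expect_equal(agreed$chosen_method, "binned_tmm")
  expect_equal(agreed$consensus_p, 0.02)
  negative <- cons(-1.2, -0.7, -0.9, p = c(0.01, 0.02, 0.03))
  expect_equal(negative$consensus_log_fc, -0.7)
  # all-zero estimates agree, not a conflict
  zeroes <- cons(0, 0, 0)
  expect_equal(zeroes$consensus_log_fc, 0)
  expect_false(zeroes$chosen_method == "zeroed")
  # zeros agree with either sign
  with_zero <- cons(0, 0.5, 0.8)
  expect_false(with_zero$chosen_method == "zeroed")
  expect_equal(with_zero$consensus_log_fc, 0)
  expect_error(consensus(method_row(1), method_row(1, id = "y"),
                         method_row(1)), "identical gene sets")
})

test_that("consensus is conservative and sign-safe on random method triples", {
  set.seed(99)
  n <- 500
  ids <- sprintf("g%03d", 1:n)
  mk <- function() tibble::tibble(gene_id = ids, log_fc = rnorm(n),
                                  p_value = runif(n))
  m1 <- mk(); m2 <- mk(); m3 <- mk()
  out <- consensus(m1, m2, m3)
  lfc <- cbind(m1$log_fc, m2$log_fc, m3$log_fc)
  min_abs <- apply(abs(lfc), 1, min)
  expect_true(all(abs(out$consensus_log_fc) <= min_abs + 1e-12))
  # never opposite in sign to any contributing method
  expect_true(all(out$consensus_log_fc * lfc >= 0 |
                    abs(out$consensus_log_fc) < 1e-12))
  # BH recomputed over consensus p-values
  expect_equal(out$consensus_fdr, bh_fdr(out$consensus_p))
})

test_that("length diagnostic reports exact trends and flags degeneracy", {
  ann <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        length_nt = c(10, 100, 1000, 10000))
  exact <- tibble::tibble(gene_id = ann$gene_id,
                          log_fc = 2 * log10(ann$length_nt))
  d <- length_logfc_diagnostic(exact, ann)
  expect_equal(d$pearson_r, 1)
  expect_equal(d$slope, 2)
  expect_equal(d$intercept, 0)
  flat <- tibble::tibble(gene_id = ann$gene_id, log_fc = rep(1.5, 4))
  d2 <- length_logfc_diagnostic(flat, ann)
  expect_equal(d2$slope, 0)
  expect_equal(d2$pearson_r, 0)
  expect_true(d2$degenerate)
})

test_that("3'-window counting neutralises differential bias; equal-length binning degenerates to the global pipeline", {
  cfg <- sim_config(n_genes = 1200, seed = 17, design = male_young_design(),
                    de_fraction = 0, age_slope_fraction = 0,
                    bias_tau = c(torin = 1000, control = 4000), window = 500)
  sim <- simulate_counts(cfg)
  uncor <- run_de(sim$counts, sim$samples)
  r_uncor <- abs(length_logfc_diagnostic(tidy(uncor), sim$annotation)$pearson_r)
  m1 <- method1_threeprime(sim$windowed_counts, sim$annotation, sim$samples,
                           window = 500)
  r_m1 <- abs(length_logfc_diagnostic(m1, sim$annotation)$pearson_r)
  expect_gt(r_uncor, 0.2)
  expect_lt(r_m1, r_uncor / 2)
  # a single equal-length bin reproduces the global pipeline's tests
  cfg2 <- sim_config(n_genes = 300, seed = 18, design = male_young_design(),
                     length_log10_range = c(3, 3), de_fraction = 0.1)
  sim2 <- simulate_counts(cfg2)
  fit2 <- run_de(sim2$counts, sim2$samples)
  suppressWarnings(
    m2 <- method2_binned_tmm(sim2$counts, sim2$annotation, sim2$samples,
                             n_bins = 1, dispersion = fit2$dispersion))
  tab2 <- tidy(fit2)
  expect_equal(m2$p_value, tab2$p_value[match(m2$gene_id, tab2$gene_id)],
               tolerance = 1e-12)
})

test_that("binned TMM uses equal-count deciles, merges tiny bins, and kills the length trend", {
  ann <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000),
                        length_nt = round(10^runif(2000, 2.7, 4.3)))
  bins <- tailbias:::length_bins(ann, 10)
  expect_equal(as.integer(table(bins$bin)), rep(200L, 10))
  merge_warnings <- capture_warnings(tailbias:::length_bins(ann[1:23, ], 10))
  expect_true(any(grepl("merged", merge_warnings)))
  # post-alignment slope is zero by construction
  cfg <- sim_config(n_genes = 800, seed = 19, design = male_young_design(),
                    de_fraction = 0, age_slope_fraction = 0,
                    bias_tau = c(torin = 1000, control = 4000))
  sim <- simulate_counts(cfg)
  m2 <- method2_binned_tmm(sim$counts, sim$annotation, sim$samples)
  d <- length_logfc_diagnostic(m2, sim$annotation)
  expect_lt(abs(d$slope), 1e-9)
})

test_that("the consensus pipeline retains power when there is no differential bias", {
  cfg <- sim_config(n_genes = 1500, seed = 29, design = male_young_design(),
                    de_fraction = 0.1, de_logfc = 1, age_slope_fraction = 0)
  sim <- simulate_counts(cfg)
  fit <- consensus_de(sim$counts, sim$windowed_counts, sim$annotation,
                      sim$samples)
  truth <- dplyr::filter(sim$truth, is_de)
  tp_uncor <- nrow(dplyr::semi_join(
    dplyr::filter(tidy(fit$uncorrected), fdr < 0.05), truth, by = "gene_id"))
  tp_cons <- nrow(dplyr::semi_join(
    dplyr::filter(tidy(fit), consensus_fdr < 0.05), truth, by = "gene_id"))
  expect_gte(tp_cons, 0.7 * tp_uncor)
  # conservativeness of the fused estimates
  lfc <- cbind(fit$methods$threeprime$log_fc,
               fit$methods$binned_tmm$log_fc,
               fit$methods$slope_only$log_fc)
  expect_true(all(abs(fit$consensus$consensus_log_fc) <=
                    apply(abs(lfc), 1, min) + 1e-12))
})

test_that("consensus_de objects expose tidy, glance, and plots", {
  cfg <- sim_config(n_genes = 250, seed = 37, design = male_young_design())
  sim <- simulate_counts(cfg)
  fit <- consensus_de(sim$counts, sim$windowed_counts, sim$annotation,
                      sim$samples)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit),
               c("n_genes", "n_zeroed", "n_fdr_05_consensus",
                 "n_fdr_05_uncorrected", "dispersion", "contrast"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit$uncorrected), "ggplot")
  expect_s3_class(tidy(fit$uncorrected), "tbl_df")
  expect_output(print(fit), "Consensus")
})
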