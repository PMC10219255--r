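test_that("cpm follows its definition and normalisation identity", {
  x <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 999999),
                      s2 = c(5, 2e6 - 5))
  out <- cpm(x)
  expect_equal(out$s1[1], 1)
  expect_equal(out$s2[1], 2.5)
  expect_equal(colSums(as.matrix(out[-1])), c(s1 = 1e6, s2 = 1e6))
  bad <- tibble::tibble(gene_id = "g1", s1 = 0)
  expect_error(cpm(bad), "zero library")
  neg <- tibble::tibble(gene_id = "g1", s1 = -1)
  expect_error(cpm(neg), "negative")
})

test_that("CPM filter uses a strict threshold and the smallest-group rule", {
  # library sizes exactly 1e6 so counts equal CPM
  counts <- tibble::tibble(
    gene_id = c("boundary", "above", "filler"),
    a1 = c(1, 2, 1e6 - 3), a2 = c(1, 2, 1e6 - 3),
    b1 = c(1, 2, 1e6 - 3), b2 = c(1, 2, 1e6 - 3), b3 = c(1, 2, 1e6 - 3))
  samples <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2", "b3"),
                            diet = c("a", "a", "b", "b", "b"))
  # smallest group n = 2 -> ceil(0.5 * 2) = 1 sample must exceed CPM 1
  kept <- filter_by_cpm(counts, samples, group_vars = "diet")
  expect_false("boundary" %in% kept$gene_id) # CPM exactly 1.0 everywhere
  expect_true(all(c("above", "filler") %in% kept$gene_id))
  # smallest group n = 3 requires ceil(1.5) = 2 qualifying samples
  s3 <- tibble::tibble(sample_id = c("b1", "b2", "b3"), diet = "b")
  one_hit <- tibble::tibble(gene_id = c("g", "f"), b1 = c(2, 1e6 - 2),
                            b2 = c(0, 1e6), b3 = c(0, 1e6))
  expect_false("g" %in% filter_by_cpm(one_hit, s3, "diet")$gene_id)
  two_hit <- tibble::tibble(gene_id = c("g", "f"), b1 = c(2, 1e6 - 2),
                            b2 = c(2, 1e6 - 2), b3 = c(0, 1e6))
  expect_true("g" %in% filter_by_cpm(two_hit, s3, "diet")$gene_id)
  # nothing expressed -> empty result with a warning
  zeros <- tibble::tibble(gene_id = c("g1", "g2"), b1 = c(0, 0),
                          b2 = c(0, 0), b3 = c(0, 0))
  expect_warning(out <- filter_by_cpm(zeros, s3, "diet"), "no genes")
  expect_equal(nrow(out), 0)
})

test_that("TMM factors: identity, exact doubling, and invariances", {
  tc <- tiny_counts()
  same <- tc$counts
  same[3:5] <- same[2]
  names(same) <- names(tc$counts)
  expect_equal(tmm_factors(same)$tmm_factor, rep(1, 4), tolerance = 1e-12)
  # doubled sample: factors (1/sqrt(2), sqrt(2)) exactly
  dbl <- tibble::tibble(gene_id = paste0("g", 1:50),
                        a = 10L + (1:50), b = 2L * (10L + (1:50)))
  expect_equal(tmm_factors(dbl)$tmm_factor, c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)
  # permutation of sample order leaves each sample's factor unchanged
  f1 <- tmm_factors(tc$counts)
  perm <- tc$counts[, c("gene_id", "b2", "a1", "b1", "a2")]
  f2 <- tmm_factors(perm)
  expect_equal(f1$tmm_factor[match(f2$sample_id, f1$sample_id)],
               f2$tmm_factor, tolerance = 1e-12)
  # common rescaling of all counts cancels
  set.seed(15)
  rc <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:100)),
                         tibble::as_tibble(matrix(rnbinom(400, mu = 80,
                                                          size = 8) + 1L,
                                                  100, 4,
                                                  dimnames = list(NULL,
                                                    c("a1", "a2", "b1", "b2")))))
  fr <- tmm_factors(rc)$tmm_factor
  rscaled <- rc
  rscaled[-1] <- rscaled[-1] * 7
  expect_equal(tmm_factors(rscaled)$tmm_factor, fr, tolerance = 1e-10)
  expect_error(tmm_factors(tc$counts[, 1:2]), "2 samples")
})

test_that("TMM factors agree with the classic implementation at equal depth", {
  set.seed(31)
  m <- matrix(rnbinom(400 * 4, mu = 60, size = 5), 400, 4)
  m[, 3] <- m[, 3] + rbinom(400, 40, 0.5) * (runif(400) < 0.2) # composition
  colnames(m) <- paste0("s", 1:4)
  cnt <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:400)),
                          tibble::as_tibble(m))
  ours <- tmm_factors(cnt)$tmm_factor
  ef <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples
  size_like <- ef$norm.factors * ef$lib.size
  size_like <- size_like / exp(mean(log(size_like)))
  expect_equal(ours, size_like, tolerance = 0.02)
})

test_that("common dispersion recovers the simulation truth and demands replicates", {
  des <- male_young_design()
  cfg0 <- sim_config(n_genes = 2000, seed = 13, design = des, dispersion = 0,
                     de_fraction = 0, age_slope_fraction = 0)
  sim0 <- simulate_counts(cfg0)
  grp <- factor(sim0$samples$diet)
  expect_lte(estimate_dispersion(sim0$counts, grp), 0.02)
  cfg1 <- sim_config(n_genes = 2000, seed = 14, design = des, dispersion = 0.1,
                     de_fraction = 0, age_slope_fraction = 0)
  sim1 <- simulate_counts(cfg1)
  phi <- estimate_dispersion(sim1$counts, factor(sim1$samples$diet))
  expect_gte(phi, 0.07)
  expect_lte(phi, 0.13)
  single <- sim1$counts[, 1:3]
  expect_error(estimate_dispersion(single, factor(c("a", "b"))),
               "unidentifiable")
  zeros <- tibble::tibble(gene_id = "g1", s1 = 0, s2 = 0)
  expect_error(estimate_dispersion(zeros, factor(c("a", "a"))), "all-zero")
})

test_that("exact test: mode split gives p = 1 and labels only flip the sign", {
  cnt <- tibble::tibble(gene_id = paste0("g", 1:3),
                        a1 = c(10, 40, 7), a2 = c(12, 38, 9),
                        b1 = c(11, 41, 6), b2 = c(11, 37, 10))
  even <- tibble::tibble(gene_id = "g", a = 25, b = 25)
  res <- exact_test(even, factor(c("a", "b")), dispersion = 0.1,
                    factors = c(1, 1))
  expect_equal(res$p_value, 1)
  g_ab <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  g_ba <- factor(c("a", "a", "b", "b"), levels = c("b", "a"))
  r1 <- exact_test(cnt, g_ab, dispersion = 0.05, factors = rep(1, 4))
  r2 <- exact_test(cnt, g_ba, dispersion = 0.05, factors = rep(1, 4))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$log_fc, -r2$log_fc, tolerance = 1e-12)
  zero_grp <- tibble::tibble(gene_id = "g", a = 0, b = 5)
  expect_error(exact_test(zero_grp, factor(c("a", "b")), 0), "zero total")
})

test_that("exact test reduces to the binomial test in the Poisson equal-library limit", {
  set.seed(42)
  y1 <- sample(0:50, 40, replace = TRUE)
  y2 <- sample(0:50, 40, replace = TRUE)
  cnt <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:40)),
                          tibble::tibble(a = y1, b = y2))
  res <- exact_test(cnt, factor(c("a", "b")), dispersion = 0,
                    factors = c(1, 1))
  oracle <- mapply(function(a, b) {
    if (a + b == 0) 1 else stats::binom.test(a, a + b, 0.5)$p.value
  }, y1, y2)
  expect_equal(res$p_value, unname(oracle), tolerance = 1e-12)
})

test_that("exact test tracks the reference NB implementation at fixed dispersion", {
  set.seed(7)
  m <- matrix(rnbinom(200 * 4, mu = 100, size = 10), 200, 4,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  grp <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  cnt <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                          tibble::as_tibble(m))
  ours <- exact_test(cnt, grp, dispersion = 0.1, factors = rep(1, 4))
  d <- edgeR::DGEList(m, group = grp)
  d$samples$norm.factors <- 1
  et <- edgeR::exactTest(d, dispersion = 0.1)
  # different two-sided conventions (all-smaller-mass vs doubled tail):
  # agreement is strong but not exact
  expect_gt(cor(ours$p_value, et$table$PValue), 0.99)
  expect_lt(max(abs(ours$log_fc - et$table$logFC)), 0.05)
})

test_that("BH adjustment matches the hand computation and handles edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  # order-preserving under permutation
  p <- c(0.001, 0.04, 0.3, 0.9, 0.02)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # monotone non-decreasing in sorted order
  expect_true(all(diff(sort(bh_fdr(p))) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold-change recovery and type-I error of the uncorrected pipeline", {
  des <- male_young_design()
  cfg <- sim_config(n_genes = 1500, seed = 23, design = des,
                    de_fraction = 0.1, de_logfc = 1, age_slope_fraction = 0)
  sim <- simulate_counts(cfg)
  fit <- run_de(sim$counts, sim$samples)
  tab <- dplyr::inner_join(tidy(fit), sim$truth, by = "gene_id")
  de <- dplyr::filter(tab, is_de, mean_cpm >= 50)
  expect_equal(median(de$log_fc * sign(de$delta)), 1, tolerance = 0.15)
  null <- dplyr::filter(tab, !is_de)
  expect_gt(mean(null$p_value < 0.05), 0.02)
  expect_lt(mean(null$p_value < 0.05), 0.08)
})
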