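#' Fraction of a transcript captured under exponential 3'-coverage decay
#'
#' Models the read coverage of a transcript of length `length_nt` when
#' coverage decays exponentially with distance from the 3' end on a scale
#' `tau` (nucleotides), as happens with degraded or QIAzol-extracted RNA.
#' The captured fraction is
#' \deqn{B(L, \tau) = (\tau/L)\,(1 - e^{-L/\tau}),}
#' which is 1 in the unbiased limit (\eqn{\tau \gg L}), decreases with
#' transcript length and increases with `tau`. Differences in `tau` between
#' sample groups therefore mimic length-correlated differential expression.
#'
#' @param length_nt Transcript length(s) in nucleotides; positive.
#' @param tau 3' decay scale(s) in nucleotides; positive.
#' @return Numeric vector of capture fractions in (0, 1].
#' @examples
#' capture_fraction(1000, 1000) # 1 - exp(-1)
#' capture_fraction(1000, 1e12) # ~1, no bias
#' @export
capture_fraction <- function(length_nt, tau) {
  if (anyNA(length_nt) || any(length_nt <= 0)) abort("length_nt must be positive")
  if (anyNA(tau) || any(tau <= 0)) abort("tau must be positive")
  r <- length_nt / tau
  # expm1 keeps the tau >> L limit numerically at 1
  -expm1(-r) / r
}

# Fraction of a transcript's reads that fall in the 3'-terminal window of
# width W under the same decay model; equals 1 when W >= L.
window_fraction <- function(length_nt, tau, window) {
  w <- pmin(window, length_nt)
  -expm1(-w / tau) / -expm1(-length_nt / tau)
}

#' Configuration for a synthetic 3'-biased RNA-seq experiment
#'
#' Bundles and validates all generator parameters. Defaults emulate a
#' fly-head aging study: 2 sexes x 3 ages (2/4/6 weeks) x 2 diets
#' (torin, control) x `n_reps` replicates, negative-binomial counts with
#' per-sample exponential 3'-coverage decay.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per design cell.
#' @param design Tibble of design cells with columns `sex`, `age_weeks`
#'   (2, 4 or 6) and `diet` (`"torin"` or `"control"`). Default: the full
#'   2 x 3 x 2 design.
#' @param baseline_mean_log Named vector `c(meanlog=, sdlog=)` of the
#'   log-normal distribution of relative gene abundance.
#' @param dispersion Negative-binomial dispersion phi >= 0
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param length_log10_range Range of log10 transcript length (nt).
#' @param bias_tau 3' decay scale tau in nt: a single value, or a vector
#'   named by diet for group-dependent bias.
#' @param de_fraction,de_logfc Fraction of genes truly responding to diet,
#'   and the magnitude of their log2 effect (random sign per gene).
#' @param age_slope_fraction,age_slope Fraction of genes with a true
#'   per-timepoint log2 age slope, and its magnitude (random sign).
#' @param age_slope_groups Optional character vector of `"sex:diet"` cells
#'   in which the age slope applies (default: all cells).
#' @param lib_size Expected library size per sample.
#' @param window Width of the 3' window (nt) used for windowed counts.
#' @param seed RNG seed; fixed-seed runs are byte-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps = 3,
                       design = default_design(),
                       baseline_mean_log = c(meanlog = 4, sdlog = 1.5),
                       dispersion = 0.05,
                       length_log10_range = c(2.7, 4.3),
                       bias_tau = 2000,
                       de_fraction = 0.1,
                       de_logfc = 1,
                       age_slope_fraction = 0.1,
                       age_slope = 1,
                       age_slope_groups = NULL,
                       lib_size = 1e6,
                       window = 1000,
                       seed = 1L) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (nrow(design) == 0) abort("design must contain at least one cell")
  if (!all(c("sex", "age_weeks", "diet") %in% names(design))) {
    abort("design needs columns sex, age_weeks, diet")
  }
  if (!all(design$age_weeks %in% c(2, 4, 6))) abort("age_weeks must be 2, 4 or 6")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (any(bias_tau <= 0)) abort("bias_tau must be positive")
  if (length(bias_tau) > 1 && !all(unique(design$diet) %in% names(bias_tau))) {
    abort("group-dependent bias_tau must be named by diet level")
  }
  if (de_fraction < 0 || de_fraction > 1) abort("de_fraction must be in [0, 1]")
  if (age_slope_fraction < 0 || age_slope_fraction > 1) {
    abort("age_slope_fraction must be in [0, 1]")
  }
  if (diff(length_log10_range) < 0 || length_log10_range[1] <= 0) {
    abort("length_log10_range must be an increasing positive range")
  }
  if (lib_size <= 0) abort("lib_size must be positive")
  if (window <= 0) abort("window must be positive")
  structure(
    list(n_genes = n_genes, n_reps = n_reps, design = as_tibble(design),
         baseline_mean_log = baseline_mean_log, dispersion = dispersion,
         length_log10_range = length_log10_range, bias_tau = bias_tau,
         de_fraction = de_fraction, de_logfc = de_logfc,
         age_slope_fraction = age_slope_fraction, age_slope = age_slope,
         age_slope_groups = age_slope_groups,
         lib_size = lib_size, window = window, seed = as.integer(seed)),
    class = "sim_config")
}

#' Full 2 sexes x 3 ages x 2 diets design
#' @return Tibble of design cells.
#' @export
default_design <- function() {
  expand_grid(sex = c("male", "female"),
              age_weeks = c(2, 4, 6),
              diet = c("torin", "control"))
}

#' Simulate a 3'-biased count experiment with known truth
#'
#' Draws per-gene abundances and transcript lengths, applies the
#' exponential 3'-capture model per sample, injects diet (log2 effect
#' `de_logfc`) and age-slope effects on the selected genes, and samples
#' negative-binomial counts whose expected column sums equal `lib_size`.
#' Windowed counts for the 3'-terminal `window` nt are drawn by binomial
#' thinning of the full counts, so they never exceed them.
#'
#' @param config A [sim_config()].
#' @return A `sim_experiment` list with tibbles `counts`,
#'   `windowed_counts`, `annotation` (gene_id, length_nt), `samples`
#'   (sample sheet), `truth` (per-gene effects) and `bias` (per-sample tau).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 7))
#' sim$truth
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) abort("config must be a sim_config")
  withr::local_seed(config$seed)

  G <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(G))
  len <- round(10^runif(G, config$length_log10_range[1],
                        config$length_log10_range[2]))
  abundance <- rlnorm(G, config$baseline_mean_log[["meanlog"]],
                      config$baseline_mean_log[["sdlog"]])

  delta <- numeric(G)
  n_de <- round(config$de_fraction * G)
  if (n_de > 0) {
    idx <- sample.int(G, n_de)
    delta[idx] <- config$de_logfc * sample(c(-1, 1), n_de, replace = TRUE)
  }
  slope <- numeric(G)
  n_sl <- round(config$age_slope_fraction * G)
  if (n_sl > 0) {
    idx <- sample.int(G, n_sl)
    slope[idx] <- config$age_slope * sample(c(-1, 1), n_sl, replace = TRUE)
  }

  samples <- expand_grid(config$design, replicate = seq_len(config$n_reps)) |>
    mutate(sample_id = paste0(substr(.data$sex, 1, 1), "_",
                              .data$age_weeks, "w_", .data$diet,
                              "_r", .data$replicate)) |>
    select("sample_id", "sex", "age_weeks", "diet", "replicate")

  tau_s <- if (length(config$bias_tau) == 1) {
    rep(unname(config$bias_tau), nrow(samples))
  } else {
    unname(config$bias_tau[samples$diet])
  }
  x_s <- as.numeric(samples$diet == "torin")
  a_s <- (samples$age_weeks - 2) / 2
  cell <- paste(samples$sex, samples$diet, sep = ":")
  on_s <- if (is.null(config$age_slope_groups)) {
    rep(1, nrow(samples))
  } else {
    as.numeric(cell %in% config$age_slope_groups)
  }

  bias_mat <- outer(len, tau_s, capture_fraction)
  log2_effect <- outer(delta, x_s) + outer(slope, a_s * on_s)
  mu0 <- abundance * bias_mat * 2^log2_effect
  mu <- sweep(mu0, 2, config$lib_size / colSums(mu0), "*")

  S <- nrow(samples)
  y <- if (config$dispersion == 0) {
    rpois(G * S, as.vector(mu))
  } else {
    rnbinom(G * S, size = 1 / config$dispersion, mu = as.vector(mu))
  }
  y <- matrix(as.double(y), G, S,
              dimnames = list(gene_id, samples$sample_id))

  wfrac <- t(vapply(seq_len(G),
                    function(g) window_fraction(len[g], tau_s, config$window),
                    numeric(S)))
  yw <- matrix(as.double(rbinom(G * S, as.vector(y), as.vector(wfrac))),
               G, S, dimnames = dimnames(y))

  structure(
    list(counts = as_count_tbl(y),
         windowed_counts = as_count_tbl(yw),
         annotation = tibble(gene_id = gene_id, length_nt = len),
         samples = samples,
         truth = tibble(gene_id = gene_id, abundance = abundance,
                        delta = delta, age_slope = slope,
                        is_de = delta != 0),
         bias = tibble(sample_id = samples$sample_id, tau = tau_s),
         config = config),
    class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Synthetic 3'-biased RNA-seq experiment\n")
  cat("  genes:  ", nrow(x$annotation), "\n")
  cat("  samples:", nrow(x$samples), "\n")
  cat("  true DE genes:", sum(x$truth$is_de),
      " | age-slope genes:", sum(x$truth$age_slope != 0), "\n")
  cat("  tau range:", paste(range(x$bias$tau), collapse = "-"), "nt\n")
  invisible(x)
}

#' Simulate two lifespan cohorts under Gompertz mortality
#'
#' Hazard \eqn{h(t) = a\,\mathrm{effect}\,e^{bt}} for the treated cohort and
#' \eqn{h(t) = a e^{bt}} for the control; deaths are recorded daily
#' (lifespans are integer days, minimum 1), with no censoring.
#'
#' @param n_per_group Flies per cohort.
#' @param gompertz_a Baseline hazard at age 0, per day.
#' @param gompertz_b Rate of exponential hazard increase, per day.
#' @param effect Hazard multiplier for the treated cohort (< 1 protects).
#' @param seed RNG seed.
#' @param groups Labels for the control and treated cohorts.
#' @return Tibble with columns `group` and `lifespan_days`.
#' @examples
#' simulate_lifespans(5, effect = 0.5, seed = 1)
#' @export
simulate_lifespans <- function(n_per_group,
                               gompertz_a = 3e-4,
                               gompertz_b = 0.1,
                               effect = 1,
                               seed = 1L,
                               groups = c("control", "treated")) {
  if (n_per_group < 1) abort("n_per_group must be >= 1")
  if (gompertz_a <= 0 || gompertz_b <= 0) abort("Gompertz parameters must be positive")
  if (effect <= 0) abort("effect must be positive")
  withr::local_seed(as.integer(seed))
  draw <- function(a) {
    u <- runif(n_per_group)
    t <- log1p(-gompertz_b * log(u) / a) / gompertz_b
    pmax(1, ceiling(t))
  }
  bind_rows(
    tibble(group = groups[1], lifespan_days = draw(gompertz_a)),
    tibble(group = groups[2], lifespan_days = draw(gompertz_a * effect))
  )
}

# Gompertz quantile (continuous time): used as an oracle in tests.
gompertz_quantile <- function(p, a, b) log1p(-b * log(1 - p) / a) / b

#' Simulate a long-format qPCR Ct table
#'
#' Emits three (by default) technical replicates per biological sample for a
#' target gene and a set of reference genes, with
#' `Ct_target = mean(base_ref) - dCt_true + offsets`, where the true
#' per-group `dCt` differs by `true_log2fc` between the torin and control
#' groups. Per-sample offsets (plate/biology) apply to every gene of a
#' sample and cancel in dCt; measurement noise is i.i.d. per well.
#'
#' @param n_per_group Biological samples per group.
#' @param true_log2fc Injected log2 fold change (torin vs control) of the
#'   target; the noise-free `-ddCt` recovers it exactly.
#' @param ct_noise_sd Per-well measurement noise SD (cycles); >= 0.
#' @param target,references Gene names.
#' @param reference_ct Baseline Ct per reference gene (recycled).
#' @param baseline_delta_ct Control-group dCt (reference - target).
#' @param sample_sd SD of the per-sample plate offset (cycles).
#' @param n_tech Technical replicates per well.
#' @param sex,age_weeks Metadata constants carried into the table.
#' @param seed RNG seed.
#' @return Tibble with columns sample_id, group, sex, age_weeks, gene_id,
#'   technical_rep, ct.
#' @export
simulate_qpcr <- function(n_per_group = 3,
                          true_log2fc = 0,
                          ct_noise_sd = 0,
                          target = "Srr",
                          references = c("eIF4A", "RpL32", "alphaTub84D"),
                          reference_ct = c(19, 18, 21),
                          baseline_delta_ct = 2,
                          sample_sd = 0.5,
                          n_tech = 3,
                          sex = "male",
                          age_weeks = 6,
                          seed = 1L) {
  if (ct_noise_sd < 0) abort("ct_noise_sd must be >= 0")
  if (n_per_group < 1) abort("n_per_group must be >= 1")
  withr::local_seed(as.integer(seed))
  base <- setNames(rep_len(reference_ct, length(references)), references)
  rows <- expand_grid(group = c("control", "torin"),
                      biorep = seq_len(n_per_group)) |>
    mutate(sample_id = paste0(.data$group, "_s", .data$biorep),
           offset = rnorm(n(), 0, sample_sd))
  per_gene <- expand_grid(rows, gene_id = c(references, target),
                          technical_rep = seq_len(n_tech))
  dct_true <- baseline_delta_ct + (per_gene$group == "torin") * true_log2fc
  clean_ct <- ifelse(per_gene$gene_id == target,
                     mean(base) - dct_true,
                     base[per_gene$gene_id])
  per_gene |>
    mutate(sex = sex, age_weeks = age_weeks,
           ct = clean_ct + .data$offset + rnorm(n(), 0, ct_noise_sd)) |>
    select("sample_id", "group", "sex", "age_weeks", "gene_id",
           "technical_rep", "ct")
}
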