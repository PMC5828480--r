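test_that("cohort_spec validates its inputs", {
  expect_error(cohort_spec(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_spec(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(cohort_spec(frac_shared = 1.2), "frac_shared")
  expect_error(cohort_spec(module_size = 10000), "module_size")
  expect_error(cohort_spec(module_tissues = list("nope")), "unknown tissues")
})

test_that("simulated genotypes are valid dosages in Hardy-Weinberg proportions", {
  spec <- tiny_spec()
  g <- simulate_genotypes(spec, n = 50, seed = 3)
  expect_true(all(g$dosage %in% 0:2))
  expect_true(all(diff(g$snp_meta$pos) > 0))
  expect_equal(dim(g$dosage), c(50, spec$n_snps))

  # p = 0.5 for every SNP: genotype frequencies converge to (1/4, 1/2, 1/4)
  spec5 <- cohort_spec(n_subjects = c(a = 4000, b = 10, c = 10), n_snps = 50,
                       maf_range = c(0.5, 0.5), seed = 1)
  g5 <- simulate_genotypes(spec5, n = 4000, seed = 9)
  freqs <- table(g5$dosage) / length(g5$dosage)
  expect_equal(unname(as.vector(freqs)), c(0.25, 0.5, 0.25), tolerance = 0.02)

  # determinism under a fixed seed
  expect_identical(simulate_genotypes(spec, n = 30, seed = 11),
                   simulate_genotypes(spec, n = 30, seed = 11))
  expect_error(simulate_genotypes(spec, n = 1), "2 subjects")
})

test_that("methylation generative model reduces to its deterministic core", {
  spec <- cohort_spec(n_subjects = c(a = 40, b = 10, c = 10), n_snps = 30,
                      n_cpgs = 30, chrom_length = 3e5, frac_cis_pairs = 0,
                      noise_sd = 0, n_batches = 1, batch_shift_sd = 0,
                      module_size = 0, risk_set_size = 0, seed = 5)
  uni <- meqtlcross:::simulate_universe(spec)
  truth <- meqtlcross:::make_truth(spec, uni)
  g <- simulate_genotypes(spec, 40, seed = 1, snp_meta = uni$snp_meta)
  cv <- simulate_covariates(spec, 40, seed = 2)
  m <- simulate_methylation(g, truth, cv, spec, tissue = "a", seed = 3,
                            cpg_meta = uni$cpg_meta,
                            covariate_effects = FALSE)
  # no effects, no noise: every subject sits at the CpG baseline
  expect_true(all(m$values > 0 & m$values < 1))
  expect_equal(max(apply(m$values, 2, function(x) diff(range(x)))), 0)
  expect_equal(qlogis(m$values[1, ]), uni$cpg_meta$baseline_logit,
               ignore_attr = TRUE)
})

test_that("a planted pair shifts logit-methylation by exactly its effect", {
  spec <- cohort_spec(n_subjects = c(a = 60, b = 10, c = 10), n_snps = 30,
                      n_cpgs = 30, chrom_length = 3e5, frac_cis_pairs = 0,
                      noise_sd = 0, n_batches = 1, batch_shift_sd = 0,
                      module_size = 0, risk_set_size = 0, seed = 5)
  uni <- meqtlcross:::simulate_universe(spec)
  # plant one pair by hand inside the window
  ci <- 10
  si <- which.min(abs(uni$snp_meta$pos - uni$cpg_meta$pos[ci]))
  expect_lte(abs(uni$snp_meta$pos[si] - uni$cpg_meta$pos[ci]),
             spec$cis_window)
  truth <- list(
    planted_pairs = tibble::tibble(
      snp_id = uni$snp_meta$snp_id[si], cpg_id = uni$cpg_meta$cpg_id[ci],
      tissues = list("a"), effect = 0.4),
    module_loadings = tibble::tibble(cpg_id = character(), module = integer(),
                                     loading = double()),
    module_tissues = list(), module_effect = numeric()
  )
  g <- simulate_genotypes(spec, 60, seed = 1, snp_meta = uni$snp_meta)
  cv <- simulate_covariates(spec, 60, seed = 2)
  m <- simulate_methylation(g, truth, cv, spec, tissue = "a", seed = 3,
                            cpg_meta = uni$cpg_meta,
                            covariate_effects = FALSE)
  lg <- qlogis(m$values[, ci])
  d <- g$dosage[, si]
  expect_gte(length(unique(d)), 2)
  fit0 <- mean(lg[d == 0]); fit1 <- mean(lg[d == 1])
  expect_equal(fit1 - fit0, 0.4, tolerance = 1e-10)

  # a pair violating the cis window errors
  far <- which.max(abs(uni$snp_meta$pos - uni$cpg_meta$pos[ci]))
  truth_bad <- truth
  truth_bad$planted_pairs$snp_id <- uni$snp_meta$snp_id[far]
  expect_error(
    simulate_methylation(g, truth_bad, cv, spec, tissue = "a", seed = 3,
                         cpg_meta = uni$cpg_meta),
    "cis window")
})

test_that("scan recovers a planted effect within 3 SE on the logit scale", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 500
    g <- rbinom(n, 2, 0.3)
    y <- 0.1 + 0.4 * g + rnorm(n, 0, 0.3)
    fit <- fit_cis_association(g, y)
    abs(fit$beta - 0.4) <= 3 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("detection-p channel plants the requested failure fraction", {
  spec <- tiny_spec()
  uni <- meqtlcross:::simulate_universe(spec)
  truth <- meqtlcross:::make_truth(spec, uni)
  g <- simulate_genotypes(spec, 50, seed = 1, snp_meta = uni$snp_meta)
  cv <- simulate_covariates(spec, 50, seed = 2)
  m <- simulate_methylation(g, truth, cv, spec, tissue = "brain", seed = 3,
                            cpg_meta = uni$cpg_meta, detect_fail_frac = 0.1)
  expect_equal(mean(m$detection_p > 0.05), 0.1, tolerance = 0.1)
})

test_that("plant_annotation_set hits its target odds ratio", {
  universe <- paste0("s", 1:2000)
  meqtl <- paste0("s", 1:400)

  # OR = 1: annotation independent of the meQTL set
  ors <- vapply(1:100, function(s) {
    ann <- plant_annotation_set(universe, meqtl, target_or = 1, size = 300,
                                seed = s)
    a <- sum(ann %in% meqtl); b <- 300 - a
    c <- 400 - a; d <- 1600 - b
    (a * d) / (b * c)
  }, numeric(1))
  expect_equal(median(ors), 1, tolerance = 0.25)

  # OR -> Inf: annotation entirely inside the meQTL set
  ann_inf <- plant_annotation_set(universe, meqtl, target_or = Inf,
                                  size = 200, seed = 1)
  expect_true(all(ann_inf %in% meqtl))

  # OR = 2 recovered in expectation (Monte Carlo over 200 seeds)
  ors2 <- vapply(1:200, function(s) {
    ann <- plant_annotation_set(universe, meqtl, target_or = 2, size = 300,
                                seed = s)
    a <- sum(ann %in% meqtl); b <- 300 - a
    (a * (1600 - b)) / (b * (400 - a))
  }, numeric(1))
  expect_equal(mean(ors2), 2, tolerance = 0.15)

  expect_error(plant_annotation_set(universe, meqtl, 2, size = 3000),
               "exceeds")
  expect_error(plant_annotation_set(universe, meqtl, -1, size = 10),
               "positive")
})

test_that("build_cohort honours sharing structure and is deterministic", {
  spec <- tiny_spec(frac_shared = 1)
  coh <- build_cohort(spec)
  expect_true(all(vapply(coh$truth$planted_pairs$tissues,
                         function(ts) length(ts) == 3, logical(1))))
  # shared effects identical in sign and size across tissues by construction
  expect_named(coh$tissues, c("brain", "blood", "saliva"))

  coh2 <- build_cohort(spec)
  expect_identical(coh$tissues$brain$meth$values,
                   coh2$tissues$brain$meth$values)
  expect_identical(coh$truth$planted_pairs, coh2$truth$planted_pairs)

  spec0 <- tiny_spec(frac_cis_pairs = 0)
  coh0 <- build_cohort(spec0)
  expect_equal(nrow(coh0$truth$planted_pairs), 0)
})

test_that("null cohort scan p-values are uniform", {
  spec <- cohort_spec(n_subjects = c(a = 120, b = 10, c = 10), n_snps = 100,
                      n_cpgs = 100, chrom_length = 1e6, frac_cis_pairs = 0,
                      module_size = 0, risk_set_size = 0, n_batches = 1,
                      batch_shift_sd = 0, seed = 8)
  uni <- meqtlcross:::simulate_universe(spec)
  truth <- meqtlcross:::make_truth(spec, uni)
  g <- simulate_genotypes(spec, 120, seed = 1, snp_meta = uni$snp_meta)
  cv <- simulate_covariates(spec, 120, seed = 2)
  m <- simulate_methylation(g, truth, cv, spec, tissue = "a", seed = 3,
                            cpg_meta = uni$cpg_meta,
                            covariate_effects = FALSE)
  tab <- scan_tissue(g, m, cv, p_threshold = 1, tissue = "a")
  expect_gt(nrow(tab), 100)
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise model matches the delta-method variance prediction", {
  # var(beta) ~ noise_sd^2 * (f'(mu))^2 with f the inverse logit
  spec <- cohort_spec(n_subjects = c(a = 4000, b = 10, c = 10), n_snps = 10,
                      n_cpgs = 40, chrom_length = 1e6, frac_cis_pairs = 0,
                      noise_sd = 0.2, n_batches = 1, batch_shift_sd = 0,
                      module_size = 0, risk_set_size = 0, seed = 13)
  uni <- meqtlcross:::simulate_universe(spec)
  truth <- meqtlcross:::make_truth(spec, uni)
  g <- simulate_genotypes(spec, 4000, seed = 1, snp_meta = uni$snp_meta)
  cv <- simulate_covariates(spec, 4000, seed = 2)
  m <- simulate_methylation(g, truth, cv, spec, tissue = "a", seed = 3,
                            cpg_meta = uni$cpg_meta,
                            covariate_effects = FALSE)
  mu <- uni$cpg_meta$baseline_logit
  pred_sd <- 0.2 * dlogis(mu)
  obs_sd <- apply(m$values, 2, sd)
  expect_equal(obs_sd, pred_sd, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("LD partner reaches its target r2 in expectation", {
  spec <- tiny_spec()
  g <- simulate_genotypes(spec, 2000, seed = 4)
  g2 <- simulate_ld_partner(g, g$snp_meta$snp_id[10], target_r2 = 0.8,
                            seed = 7)
  expect_equal(ncol(g2$dosage), ncol(g$dosage) + 1)
  r2 <- genotype_r2(g2$dosage[, "snp00010"], g2$dosage[, "snp00010_ld"])
  expect_equal(r2, 0.8, tolerance = 0.1)
})
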