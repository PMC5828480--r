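test_that("genotype r2 is a squared correlation, recoding-invariant", {
  set.seed(11)
  g1 <- rbinom(500, 2, 0.3)
  expect_equal(genotype_r2(g1, g1), 1)
  expect_equal(genotype_r2(g1, 2 - g1), 1)
  r2s <- vapply(1:50, function(i) {
    genotype_r2(rbinom(1000, 2, 0.3), rbinom(1000, 2, 0.3))
  }, numeric(1))
  expect_lt(mean(r2s), 0.01)
  expect_warning(r0 <- genotype_r2(rep(1, 10), rbinom(10, 2, 0.5)),
                 "constant")
  expect_equal(r0, 0)
})

make_ld_geno <- function(blocks, n = 400, seed = 1) {
  # blocks: list of integer vectors; SNPs in one block are near-copies
  set.seed(seed)
  cols <- list(); meta <- list(); pos <- 0
  for (b in seq_along(blocks)) {
    base <- rbinom(n, 2, 0.3)
    for (k in blocks[[b]]) {
      g <- base
      flip <- runif(n) < 0.02
      g[flip] <- rbinom(sum(flip), 2, 0.3)
      pos <- pos + 1000
      cols[[length(cols) + 1]] <- g
      meta[[length(meta) + 1]] <- tibble::tibble(
        snp_id = paste0("s", length(cols)), chrom = "chr1", pos = pos,
        coding_allele = "A", other_allele = "G", maf = 0.3)
    }
  }
  geno_matrix(do.call(cbind, cols), dplyr::bind_rows(meta))
}

test_that("supervised LD pruning keeps priority SNPs and breaks high-r2 pairs", {
  g <- make_ld_geno(list(1:2), seed = 2)
  kept <- supervised_ld_prune(g, priority = "s2", r2_max = 0.7,
                              window = 1e6)
  expect_identical(kept, "s2")

  # mutually independent SNPs are all kept
  set.seed(3)
  ind <- geno_matrix(
    matrix(rbinom(400 * 5, 2, 0.3), 400),
    tibble::tibble(snp_id = paste0("s", 1:5), chrom = "chr1",
                   pos = (1:5) * 1000, coding_allele = "A",
                   other_allele = "G", maf = 0.3))
  expect_setequal(supervised_ld_prune(ind, r2_max = 0.7), ind$snp_meta$snp_id)
})

test_that("pruned set is maximal, conflict-free, and priority-optimal", {
  g <- make_ld_geno(list(1:5), seed = 4)   # chain of 5 SNPs in tight LD
  pri <- "s3"
  kept <- supervised_ld_prune(g, priority = pri, r2_max = 0.7, window = 1e6)
  r2 <- function(i, j) genotype_r2(g$dosage[, i], g$dosage[, j])
  ids <- g$snp_meta$snp_id
  feasible <- function(set) {
    if (length(set) < 2) return(TRUE)
    all(combn(set, 2, function(p) r2(p[1], p[2])) <= 0.7)
  }
  expect_true(feasible(kept))
  # maximal: no SNP outside can be added
  for (s in setdiff(ids, kept)) expect_false(feasible(c(kept, s)))
  # priority-optimal: contains as many priority SNPs as any maximal
  # feasible set found by exhaustive search
  all_sets <- unlist(lapply(1:5, function(k)
    combn(ids, k, simplify = FALSE)), recursive = FALSE)
  max_sets <- Filter(function(s) feasible(s) &&
                       all(vapply(setdiff(ids, s), function(x)
                         !feasible(c(s, x)), logical(1))), all_sets)
  best_pri <- max(vapply(max_sets, function(s) sum(s %in% pri), integer(1)))
  expect_equal(sum(kept %in% pri), best_pri)
})

test_that("MAF-matched permutation behaves at its edges and matches histograms", {
  set.seed(12)
  uni <- tibble::tibble(snp_id = paste0("s", 1:1000),
                        maf = runif(1000, 0.01, 0.5))
  query <- sample(uni$snp_id, 100)

  # annotation covering the universe: observed proportion 1, p_perm 0
  res <- maf_matched_permutation(query, uni$snp_id, uni, n_sets = 200,
                                 seed = 1)
  expect_equal(res$observed_proportion, 1)
  expect_equal(res$p_perm, 0)

  # explicit null sets reproduce the query's per-bin MAF histogram exactly
  res_sets <- maf_matched_permutation(query, sample(uni$snp_id, 200), uni,
                                      n_sets = 120, seed = 2,
                                      return_sets = TRUE)
  q_bins <- table(meqtlcross:::maf_bin(uni$maf[match(query, uni$snp_id)]))
  for (s in res_sets$null_sets[1:10]) {
    s_bins <- table(meqtlcross:::maf_bin(uni$maf[match(s, uni$snp_id)]))
    expect_equal(s_bins, q_bins)
  }

  # count-based and set-based null draws agree in distribution
  ann <- sample(uni$snp_id, 300)
  fast <- maf_matched_permutation(query, ann, uni, n_sets = 2000, seed = 3)
  slow <- maf_matched_permutation(query, ann, uni, n_sets = 2000, seed = 4,
                                  return_sets = TRUE)
  ks <- suppressWarnings(ks.test(fast$null_proportions,
                                 slow$null_proportions))
  expect_gt(ks$p.value, 0.001)

  expect_error(maf_matched_permutation(c("nope", query), ann, uni,
                                       n_sets = 200), "subset")
  expect_error(maf_matched_permutation(query, ann, uni, n_sets = 10),
               "at least 100")
})

test_that("fisher_2x2 matches the hypergeometric enumeration oracle", {
  expect_equal(fisher_2x2(matrix(c(10, 10, 10, 10), 2))$odds_ratio, 1)
  expect_equal(fisher_2x2(matrix(c(10, 10, 10, 10), 2))$p_fisher, 1)
  expect_equal(fisher_2x2(matrix(c(20, 10, 10, 20), 2,
                                 byrow = TRUE))$odds_ratio, 4)
  # full enumeration: margins (4,4,4,4), observed a=3 -> p = 34/70
  expect_equal(fisher_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p_fisher,
               34 / 70, tolerance = 1e-12)

  fisher_p_oracle <- function(tab) {
    a <- tab[1, 1]
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(m, k)
    probs <- dhyper(support, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_2x2(tab)$p_fisher, fisher_p_oracle(tab),
                 tolerance = 1e-10)
  }
  expect_error(fisher_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margins")
})

test_that("Haldane correction and Wald CI cover zero-cell tables", {
  res <- fisher_2x2(matrix(c(0, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(res$odds_ratio, (0.5 * 10.5) / (10.5 * 10.5))
  expect_true(res$ci_lo < res$odds_ratio & res$odds_ratio < res$ci_hi)
})

test_that("CpG context enrichment flags a planted island excess", {
  meta <- toy_cpg_meta(2000, island_frac = 0.3, seed = 14)
  islands <- meta$cpg_id[meta$island_context == "island"]
  others <- setdiff(meta$cpg_id, islands)
  set.seed(15)
  set_a <- c(sample(islands, 300), sample(others, 100))
  set_b <- sample(meta$cpg_id, 600)
  res <- cpg_context_enrichment(meta, set_a, set_b)
  isl <- res[res$context == "island", ]
  expect_gt(isl$odds_ratio, 1)
  expect_lt(isl$p_fisher, 1e-6)
  # each 2x2 covers exactly the two sets
  expect_true(all(res$a + res$b == length(set_a)))
  expect_true(all(res$c + res$d == length(set_b)))
})

test_that("context odds ratios are near 1 for same-distribution sets", {
  meta <- toy_cpg_meta(3000, seed = 16)
  set.seed(17)
  set_a <- sample(meta$cpg_id, 1000)
  set_b <- setdiff(meta$cpg_id, set_a)[1:1000]
  res <- cpg_context_enrichment(meta, set_a, set_b)
  expect_true(all(res$p_fisher > 1e-4))
})

test_that("snp_enrichment combines permutation and Fisher components", {
  set.seed(18)
  uni <- tibble::tibble(snp_id = paste0("s", 1:5000),
                        maf = runif(5000, 0.01, 0.5))
  query <- sample(uni$snp_id, 400)
  ann <- plant_annotation_set(uni$snp_id, query, target_or = 3, size = 500,
                              seed = 19)
  res <- snp_enrichment(query, ann, uni, n_sets = 1000, seed = 20)
  expect_gt(res$odds_ratio, 1.5)
  expect_lt(res$p_perm, 0.05)
  expect_lt(res$p_fisher, 0.001)
  expect_equal(res$a + res$b, 400)
})
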