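# Independent oracles and small fixture builders shared across tests.

# Normal-equations OLS oracle for the slope of g in m ~ 1 + g + C.
ols_oracle <- function(g, m, C = NULL) {
  X <- cbind(1, g, C)
  XtX <- crossprod(X)
  bhat <- solve(XtX, crossprod(X, m))
  res <- m - X %*% bhat
  df <- length(m) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * solve(XtX)[2, 2])
  t <- bhat[2] / se
  list(beta = bhat[2], se = se, t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Triple-loop TOM oracle (definitional evaluation of the overlap formula).
tom_oracle <- function(A) {
  p <- nrow(A)
  k <- rowSums(A)
  out <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    num <- sum(A[i, ] * A[, j]) + A[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best Jaccard between a planted CpG set and any detected module.
best_module_jaccard <- function(planted, labels) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) return(0)
  max(vapply(mods, function(m) jaccard(planted, names(labels)[labels == m]),
             numeric(1)))
}

# Small toy meQTL table with controllable records.
toy_meqtl_table <- function(pos, cpg_pos, beta_hat, coding = "A", other = "G",
                            maf = 0.3, n = 200, tissue = "toy",
                            chrom = "chr1") {
  k <- length(pos)
  tab <- tibble::tibble(
    snp_id = paste0("s", seq_len(k)), chrom = chrom, pos = pos,
    coding_allele = rep_len(coding, k), other_allele = rep_len(other, k),
    maf = rep_len(maf, k), cpg_id = paste0("c", seq_len(k)),
    cpg_pos = cpg_pos, beta = beta_hat, se = 1, beta_hat = beta_hat,
    p = 1e-8, n = rep_len(n, k)
  )
  meqtlcross:::new_meqtl_table(
    tab, tissue = tissue, window = 20000, p_threshold = 1e-5,
    covariates = character(), n_pairs_tested = k,
    universe_snps = tibble::tibble(snp_id = tab$snp_id, chrom = chrom,
                                   pos = pos),
    universe_cpgs = tibble::tibble(cpg_id = tab$cpg_id, chrom = chrom,
                                   pos = cpg_pos)
  )
}

# Minimal CpG metadata for context tests.
toy_cpg_meta <- function(n, island_frac = 0.5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    cpg_id = paste0("c", seq_len(n)), chrom = "chr1", pos = seq_len(n) * 100,
    gene_body = runif(n) < 0.4, tss200 = runif(n) < 0.1,
    tss1500 = runif(n) < 0.1, utr5 = runif(n) < 0.05, utr3 = runif(n) < 0.05,
    first_exon = runif(n) < 0.05, enhancer = runif(n) < 0.15,
    island_context = ifelse(runif(n) < island_frac, "island", "open_sea"),
    snp_coincident = FALSE, cross_reactive = FALSE, sex_chromosome = FALSE
  )
}

tiny_spec <- function(...) {
  cohort_spec(n_subjects = c(brain = 60, blood = 60, saliva = 60),
              n_snps = 80, n_cpgs = 80, chrom_length = 8e5,
              module_size = 20, risk_set_size = 10, seed = 42, ...)
}
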