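#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of genotype counts against the
#' proportions implied by the sample allele frequency. Yates continuity
#' correction is applied when the smallest expected count falls below 5.
#'
#' @param counts Integer vector `c(n_AA, n_Aa, n_aa)` (AA = two coding
#'   alleles).
#' @return Two-sided p-value.
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3 || any(counts < 0)) abort("counts must be 3 nonnegative values")
  n <- sum(counts)
  if (n == 0) abort("all genotype counts are zero")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (p == 0 || p == 1) return(1)  # monomorphic: trivially in HWE
  d <- abs(counts - expected)
  if (min(expected) < 5) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / expected)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes SNPs failing any of: per-SNP missingness above `max_snp_missing`,
#' minor allele frequency below `min_maf`, or a Hardy-Weinberg test p-value
#' below `hwe_alpha`. Mirrors the PLINK-style filters used by the source
#' cohort studies (first pass: missing > 10%, MAF < 0.01, HWE p < 1e-6;
#' second pass on imputed data: missing > 1%, MAF < 0.05).
#'
#' @param G A [geno_matrix()].
#' @param max_snp_missing Maximum tolerated missing fraction per SNP.
#' @param min_maf Minimum empirical minor allele frequency (exclusive bound:
#'   SNPs with MAF strictly below are removed).
#' @param hwe_alpha HWE p-value threshold.
#' @return The filtered [geno_matrix()]; attribute `qc_log` holds a tibble of
#'   per-rule removal counts (a SNP failing several rules is counted under
#'   each).
#' @export
genotype_qc <- function(G, max_snp_missing = 0.1, min_maf = 0.01,
                        hwe_alpha = 1e-6) {
  for (v in c(max_snp_missing, min_maf, hwe_alpha)) {
    if (v <= 0 || v >= 1) abort("QC thresholds must lie in (0, 1)")
  }
  d <- G$dosage
  miss <- colMeans(is.na(d))
  maf <- empirical_maf(d)
  hwe_p <- apply(d, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_test(c(sum(g == 2), sum(g == 1), sum(g == 0)))
  })
  fail_miss <- miss > max_snp_missing
  fail_maf <- maf < min_maf
  fail_hwe <- hwe_p < hwe_alpha
  keep <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep)) warn("genotype_qc removed every SNP")
  out <- subset_geno(G, keep)
  out$snp_meta$maf <- empirical_maf(out$dosage)
  attr(out, "qc_log") <- tibble::tibble(
    rule = c("missingness", "maf", "hwe"),
    threshold = c(max_snp_missing, min_maf, hwe_alpha),
    n_removed = c(sum(fail_miss), sum(fail_maf), sum(fail_hwe))
  )
  out
}

#' Methylation quality control
#'
#' Removes CpGs carrying any probe blacklist flag (SNP-coincident,
#' cross-reactive, sex chromosome), masks entries whose detection p-value
#' exceeds `detection_alpha` as missing, and removes CpGs whose missing
#' fraction then exceeds `max_missing`.
#'
#' @param M A [meth_matrix()].
#' @param max_missing Maximum tolerated per-CpG missing fraction.
#' @param detection_alpha Detection p-value threshold above which an entry is
#'   treated as missing (requires the `detection_p` channel; skipped when
#'   absent).
#' @return The filtered [meth_matrix()]; attribute `qc_log` as in
#'   [genotype_qc()].
#' @export
methylation_qc <- function(M, max_missing = 0.01, detection_alpha = 0.05) {
  flags <- intersect(BLACKLIST_FLAGS, names(M$cpg_meta))
  fail_black <- if (length(flags)) {
    Reduce(`|`, lapply(flags, function(f) M$cpg_meta[[f]]))
  } else rep(FALSE, ncol(M$values))
  values <- M$values
  if (!is.null(M$detection_p)) {
    values[M$detection_p > detection_alpha] <- NA
  }
  miss <- colMeans(is.na(values))
  fail_miss <- miss > max_missing
  keep <- !(fail_black | fail_miss)
  out <- meth_matrix(
    values[, keep, drop = FALSE], M$cpg_meta[keep, , drop = FALSE],
    detection_p = if (!is.null(M$detection_p)) M$detection_p[, keep, drop = FALSE],
    scale = M$scale
  )
  attr(out, "qc_log") <- tibble::tibble(
    rule = c("blacklist", "missingness"),
    threshold = c(NA_real_, max_missing),
    n_removed = c(sum(fail_black), sum(fail_miss & !fail_black))
  )
  out
}

#' Quantile normalization across subjects
#'
#' Forces every subject's methylation value vector to the same empirical
#' distribution (the across-subject mean of order statistics), with average
#' ranks for ties. Delegates to [limma::normalizeQuantiles()].
#'
#' @param M A [meth_matrix()] without missing values (run before
#'   imputation-dependent steps on complete entries).
#' @return A [meth_matrix()] on the same scale.
#' @export
quantile_normalize <- function(M) {
  if (nrow(M$values) < 2) return(M)
  v <- t(limma::normalizeQuantiles(t(M$values), ties = TRUE))
  dimnames(v) <- dimnames(M$values)
  # mean of order statistics of values in [0,1] stays in [0,1]
  meth_matrix(v, M$cpg_meta, detection_p = M$detection_p, scale = M$scale)
}

#' Mean imputation of missing methylation values
#'
#' Replaces each missing entry by the per-CpG mean of its observed entries.
#'
#' @param M A [meth_matrix()]; every CpG must have at least one observed
#'   value.
#' @return A complete [meth_matrix()].
#' @export
mean_impute <- function(M) {
  v <- M$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0)) {
    abort("fully-missing CpG encountered; run methylation_qc first")
  }
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mu[idx[, 2]]
  meth_matrix(v, M$cpg_meta, detection_p = M$detection_p, scale = M$scale)
}

#' Batch adjustment by parametric empirical Bayes
#'
#' Removes per-CpG batch location/scale effects with the parametric
#' empirical-Bayes scheme of [sva::ComBat()], keeping `protected` covariates
#' (diagnosis by default) in the design so their effects are preserved. When
#' the data are (near-)noise-free the EB standardization is degenerate; in
#' that case batch means conditional on the protected covariates are removed
#' by linear regression instead.
#'
#' @param M A complete [meth_matrix()].
#' @param covariates Covariate tibble containing `batch` and the protected
#'   columns, rows aligned with subjects.
#' @param protected Character vector of covariate columns whose effects must
#'   survive adjustment.
#' @return A batch-adjusted [meth_matrix()].
#' @export
batch_adjust <- function(M, covariates, protected = "diagnosis") {
  batch <- covariates$batch
  if (length(unique(batch)) < 2) {
    warn("single batch: batch_adjust returns its input")
    return(M)
  }
  if (min(table(batch)) < 2) abort("each batch needs at least 2 subjects")
  prot <- intersect(protected, names(covariates))
  mod <- if (length(prot)) {
    model.matrix(~ ., data = as.data.frame(covariates[prot]))
  } else NULL

  design <- model.matrix(~ factor(batch) + ., data = as.data.frame(
    if (length(prot)) covariates[prot] else data.frame(row.names = seq_along(batch))
  ))
  fit <- lm.fit(design, M$values)
  resid_var <- colMeans(fit$residuals^2)
  if (max(resid_var) < 1e-10) {
    # degenerate (noise-free) input: remove batch means, keep everything else
    b_idx <- grep("^factor\\(batch\\)", colnames(design))
    adj <- M$values - design[, b_idx, drop = FALSE] %*%
      fit$coefficients[b_idx, , drop = FALSE]
    # re-centre so grand means are preserved
    adj <- sweep(adj, 2, colMeans(M$values) - colMeans(adj), "+")
    v <- adj
  } else {
    v <- t(suppressMessages(
      sva::ComBat(dat = t(M$values), batch = batch, mod = mod,
                  par.prior = TRUE)
    ))
  }
  dimnames(v) <- dimnames(M$values)
  # ComBat can nudge values marginally outside [0,1]; clamp for beta scale
  if (M$scale == "beta") v <- pmin(pmax(v, 0), 1)
  meth_matrix(v, M$cpg_meta, detection_p = M$detection_p, scale = M$scale)
}

#' Rank-based inverse normal transform per CpG
#'
#' Transforms each CpG to normal quantiles of its (average-tie) ranks using
#' the Blom offset, `qnorm((rank - 3/8) / (n + 1/4))`, the transform used for
#' the whole-blood methylation in the source meQTL study.
#'
#' @param M A complete [meth_matrix()].
#' @return A [meth_matrix()] with `scale = "rank_normal"`.
#' @export
rank_normalize <- function(M) {
  v <- apply(M$values, 2, function(x) {
    if (length(unique(x)) < 2) abort("constant CpG: rank normalization undefined")
    qnorm((rank(x, ties.method = "average") - 0.375) / (length(x) + 0.25))
  })
  dimnames(v) <- dimnames(M$values)
  meth_matrix(v, M$cpg_meta, detection_p = M$detection_p, scale = "rank_normal")
}

#' Standard methylation preprocessing pipeline
#'
#' Blacklist filter and detection-p masking + missingness filter
#' ([methylation_qc()]), quantile normalization, mean imputation, then batch
#' adjustment. Normalization precedes imputation so imputed values cannot
#' distort the quantiles.
#'
#' @inheritParams methylation_qc
#' @inheritParams batch_adjust
#' @return A preprocessed [meth_matrix()].
#' @export
preprocess_methylation <- function(M, covariates, max_missing = 0.01,
                                   detection_alpha = 0.05,
                                   protected = "diagnosis") {
  M |>
    methylation_qc(max_missing = max_missing, detection_alpha = detection_alpha) |>
    quantile_normalize() |>
    mean_impute() |>
    batch_adjust(covariates, protected = protected)
}
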