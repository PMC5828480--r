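#' Enumerate cis SNP-CpG pairs
#'
#' All same-chromosome pairs with `|pos_snp - pos_cpg| <= window`, boundary
#' inclusive, each exactly once.
#'
#' @param snp_meta Data frame with `snp_id`, `chrom`, `pos`.
#' @param cpg_meta Data frame with `cpg_id`, `chrom`, `pos`.
#' @param window Maximum distance in bp (default 20 kb).
#' @return Tibble `snp_id`, `cpg_id`, `distance`, plus the matrix column
#'   indices `snp_idx`, `cpg_idx` into the supplied metadata.
#' @export
cis_pairs <- function(snp_meta, cpg_meta, window = 20000) {
  if (window <= 0) abort("window must be positive")
  out <- vector("list", 0L)
  for (ch in intersect(unique(snp_meta$chrom), unique(cpg_meta$chrom))) {
    si <- which(snp_meta$chrom == ch)
    ci <- which(cpg_meta$chrom == ch)
    sp <- snp_meta$pos[si]
    o <- order(sp)
    si <- si[o]; sp <- sp[o]
    lo <- findInterval(cpg_meta$pos[ci] - window - 1L, sp) + 1L
    hi <- findInterval(cpg_meta$pos[ci] + window, sp)
    n_each <- pmax(hi - lo + 1L, 0L)
    keep <- n_each > 0L
    if (!any(keep)) next
    cpg_rep <- rep(ci[keep], n_each[keep])
    snp_take <- sequence(n_each[keep], from = lo[keep])
    out[[length(out) + 1L]] <- tibble::tibble(
      snp_idx = si[snp_take], cpg_idx = cpg_rep
    )
  }
  if (!length(out)) {
    return(tibble::tibble(snp_id = character(), cpg_id = character(),
                          distance = integer(), snp_idx = integer(),
                          cpg_idx = integer()))
  }
  pairs <- dplyr::bind_rows(out)
  tibble::tibble(
    snp_id = snp_meta$snp_id[pairs$snp_idx],
    cpg_id = cpg_meta$cpg_id[pairs$cpg_idx],
    distance = abs(snp_meta$pos[pairs$snp_idx] - cpg_meta$pos[pairs$cpg_idx]),
    snp_idx = pairs$snp_idx, cpg_idx = pairs$cpg_idx
  )
}

#' Covariate-adjusted linear additive association for one SNP-CpG pair
#'
#' Ordinary least squares of methylation on `[1, dosage, covariates]`.
#' Reports the per-allele effect `beta`, its standard error, the normalized
#' coefficient `beta_hat = beta / se` (the t statistic, the standardized
#' methylation change per coding allele used for cross-tissue comparison),
#' and the two-sided t-test p-value on `n - k` residual degrees of freedom.
#' Subjects with a missing dosage or methylation value are removed pairwise.
#'
#' @param g Dosage vector.
#' @param m Methylation vector.
#' @param C Optional covariate matrix/data frame (no intercept column).
#' @return One-row tibble `beta`, `se`, `beta_hat`, `p`, `n`, `df`, `ok`
#'   (`FALSE` when the dosage is constant or the design collinear; statistics
#'   are then `NA`).
#' @export
fit_cis_association <- function(g, m, C = NULL) {
  if (!is.null(C)) C <- as.matrix(C)
  keep <- !is.na(g) & !is.na(m)
  if (!is.null(C)) keep <- keep & complete.cases(C)
  g <- g[keep]; m <- m[keep]
  X <- cbind(`(Intercept)` = 1, g = g, if (!is.null(C)) C[keep, , drop = FALSE])
  n <- length(g)
  bad_row <- tibble::tibble(beta = NA_real_, se = NA_real_,
                            beta_hat = NA_real_, p = NA_real_,
                            n = n, df = NA_integer_, ok = FALSE)
  if (n < ncol(X) + 1 || var(g) == 0) return(bad_row)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(bad_row)
  cf <- qr.coef(qx, m)
  res <- m - X %*% cf
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv_gg <- chol2inv(qr.R(qx))[2, 2]
  se <- sqrt(sigma2 * XtX_inv_gg)
  beta <- cf[["g"]]
  t_stat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * pt(-abs(t_stat), df)
  tibble::tibble(beta = beta, se = se, beta_hat = t_stat,
                 p = max(p, .Machine$double.xmin), n = n, df = df, ok = TRUE)
}

# Residualize the columns of Y on design X (with intercept); returns the
# residual matrix. Used by the fast scan path (Frisch-Waugh-Lovell).
residualize <- function(Y, X) {
  qr.resid(qr(X), Y)
}

build_design <- function(covariates, cols) {
  cols <- intersect(cols, names(covariates))
  if (!length(cols)) return(NULL)
  model.matrix(~ ., data = as.data.frame(covariates[cols]))[, -1, drop = FALSE]
}

#' Cis-meQTL scan of one tissue
#'
#' Fits the covariate-adjusted linear additive model for every cis SNP-CpG
#' pair within `window` and keeps pairs with `p <= p_threshold` (the scan
#' conventions of the source studies: 20 kb window, p <= 1e-5). The default
#' fast path residualizes the dosage and methylation matrices on the
#' covariates once and computes correlation-based t statistics, which equals
#' the per-pair OLS fit; `method = "perpair"` runs [fit_cis_association()]
#' pair by pair (used when dosages contain missing values).
#'
#' @param G A [geno_matrix()].
#' @param M A [meth_matrix()] (any scale).
#' @param covariates Covariate tibble aligned with subjects.
#' @param covariate_cols Columns adjusted for; defaults to age, sex,
#'   diagnosis, cell proportion, and the first three ancestry PCs, mirroring
#'   the saliva cohort's model.
#' @param window Cis window, bp.
#' @param p_threshold Retention threshold on the association p-value.
#' @param method `"fast"` or `"perpair"`.
#' @param tissue Label stored with the table.
#' @return A `meqtl_table`: a tibble with columns `snp_id`, `chrom`, `pos`,
#'   `coding_allele`, `other_allele`, `maf`, `cpg_id`, `cpg_pos`, `beta`,
#'   `se`, `beta_hat`, `p`, `n`; attributes record the tissue, thresholds,
#'   covariates, number of pairs tested, and the SNP/CpG universes scanned.
#' @export
scan_tissue <- function(G, M, covariates = NULL,
                        covariate_cols = c("age", "sex", "diagnosis",
                                           "cell_epithelial", "pc1", "pc2", "pc3"),
                        window = 20000, p_threshold = 1e-5,
                        method = c("fast", "perpair"), tissue = "tissue") {
  method <- match.arg(method)
  stopifnot(nrow(G$dosage) == nrow(M$values))
  pairs <- cis_pairs(G$snp_meta, M$cpg_meta, window = window)
  C <- if (!is.null(covariates)) build_design(covariates, covariate_cols)
  if (nrow(pairs) == 0) {
    warn("no cis pairs within the window")
    res <- tibble::tibble(beta = double(), se = double(), beta_hat = double(),
                          p = double(), n = integer(), ok = logical())
    pairs <- pairs[, c("snp_id", "cpg_id", "snp_idx", "cpg_idx")]
  } else if (method == "fast" && !anyNA(G$dosage) && !anyNA(M$values)) {
    res <- scan_fast(G$dosage, M$values, C, pairs)
  } else {
    res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      fit_cis_association(G$dosage[, pairs$snp_idx[i]],
                          M$values[, pairs$cpg_idx[i]], C)[
        , c("beta", "se", "beta_hat", "p", "n", "ok")]
    })
  }
  tab <- dplyr::bind_cols(pairs[, c("snp_id", "cpg_id", "snp_idx", "cpg_idx")], res)
  tab <- tab[!is.na(tab$ok) & tab$ok & tab$p <= p_threshold, , drop = FALSE]
  sm <- G$snp_meta[tab$snp_idx, ]
  out <- tibble::tibble(
    snp_id = tab$snp_id, chrom = sm$chrom, pos = sm$pos,
    coding_allele = sm$coding_allele, other_allele = sm$other_allele,
    maf = sm$maf, cpg_id = tab$cpg_id,
    cpg_pos = M$cpg_meta$pos[tab$cpg_idx],
    beta = tab$beta, se = tab$se, beta_hat = tab$beta_hat, p = tab$p,
    n = tab$n
  )
  new_meqtl_table(out, tissue = tissue, window = window,
                  p_threshold = p_threshold,
                  covariates = colnames(C) %||% character(),
                  n_pairs_tested = nrow(pairs),
                  universe_snps = G$snp_meta, universe_cpgs = M$cpg_meta)
}

scan_fast <- function(dosage, values, C, pairs) {
  n <- nrow(dosage)
  X <- cbind(1, C)
  Gr <- residualize(dosage, X)
  Mr <- residualize(values, X)
  df <- n - ncol(X) - 1L
  ssg <- colSums(Gr^2)
  ssm <- colSums(Mr^2)
  i <- pairs$snp_idx; j <- pairs$cpg_idx
  num <- colSums(Gr[, i, drop = FALSE] * Mr[, j, drop = FALSE])
  ok <- ssg[i] > 0
  beta <- num / ssg[i]
  sse <- pmax(ssm[j] - num^2 / ssg[i], 0)
  se <- sqrt(sse / df / ssg[i])
  t_stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- pmax(2 * pt(-abs(t_stat), df), .Machine$double.xmin)
  tibble::tibble(beta = beta, se = se, beta_hat = t_stat, p = p,
                 n = n, ok = ok & is.finite(beta))
}

new_meqtl_table <- function(x, tissue, window, p_threshold, covariates,
                            n_pairs_tested, universe_snps, universe_cpgs) {
  structure(
    x,
    class = c("meqtl_table", class(tibble::as_tibble(x))),
    tissue = tissue, window = window, p_threshold = p_threshold,
    covariates = covariates, n_pairs_tested = n_pairs_tested,
    universe_snps = universe_snps, universe_cpgs = universe_cpgs
  )
}

#' @export
print.meqtl_table <- function(x, ...) {
  cat(sprintf(
    "# meQTL table: %s | window %d bp, p <= %g | %d significant pairs (%d tested)\n",
    attr(x, "tissue"), attr(x, "window"), attr(x, "p_threshold"),
    nrow(x), attr(x, "n_pairs_tested") %||% NA
  ))
  NextMethod()
}

#' Analytic power of the cis association t-test
#'
#' Power of the two-sided slope t-test at level `alpha` for a per-allele
#' effect expressed in residual-SD units, for a biallelic SNP in
#' Hardy-Weinberg proportions: the noncentrality parameter is
#' `effect * sqrt(n * 2 * maf * (1 - maf))` and the null distribution is t
#' with `n - 2` degrees of freedom.
#'
#' @param n Sample size (> 2). Vectorized over all arguments.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param effect Per-allele effect in residual-SD units.
#' @param alpha Two-sided significance level.
#' @return Detection power in `[alpha, 1)`.
#' @export
analytic_power <- function(n, maf, effect, alpha = 1e-5) {
  stopifnot(all(n > 2), all(maf > 0), all(maf <= 0.5),
            all(alpha > 0), all(alpha < 1))
  df <- n - 2
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- effect * sqrt(n * 2 * maf * (1 - maf))
  pt(-tcrit, df, ncp) + pt(tcrit, df, ncp, lower.tail = FALSE)
}
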