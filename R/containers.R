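#' Genotype matrix container
#'
#' Couples a subjects-by-SNPs additive dosage matrix (counts of the coding
#' allele, in `{0, 1, 2}` or `NA`) with its per-SNP metadata. Dosage column
#' order and `snp_meta` row order must agree.
#'
#' @param dosage Numeric matrix, subjects in rows, SNPs in columns. Column
#'   names are SNP ids, row names subject ids.
#' @param snp_meta Data frame with one row per SNP: `snp_id`, `chrom`,
#'   `pos` (1-based), `coding_allele`, `other_allele`, `maf` (empirical minor
#'   allele frequency).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, snp_meta) {
  snp_meta <- tibble::as_tibble(snp_meta)
  stopifnot(is.matrix(dosage), nrow(snp_meta) == ncol(dosage))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && any(!(bad %in% c(0, 1, 2)))) {
    abort("dosages must be in {0, 1, 2} or NA")
  }
  needed <- c("snp_id", "chrom", "pos", "coding_allele", "other_allele", "maf")
  missing_cols <- setdiff(needed, names(snp_meta))
  if (length(missing_cols)) {
    abort(paste0("snp_meta lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(snp_meta$pos <= 0)) abort("positions must be positive (1-based)")
  if (any(snp_meta$coding_allele == snp_meta$other_allele)) {
    abort("coding_allele must differ from other_allele")
  }
  colnames(dosage) <- snp_meta$snp_id
  structure(list(dosage = dosage, snp_meta = snp_meta), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d subjects x %d SNPs (chrom %s, MAF %.3f-%.3f)\n",
    nrow(x$dosage), ncol(x$dosage),
    paste(unique(x$snp_meta$chrom), collapse = ","),
    min(x$snp_meta$maf), max(x$snp_meta$maf)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

subset_geno <- function(g, keep) {
  geno_matrix(g$dosage[, keep, drop = FALSE], g$snp_meta[keep, , drop = FALSE])
}

#' Methylation matrix container
#'
#' Couples a subjects-by-CpGs methylation value matrix with per-CpG
#' annotation. Values are beta values in `[0, 1]` until a rank normalization
#' step, after which they are real-valued (`scale` attribute tracks this).
#'
#' @param values Numeric matrix, subjects in rows, CpGs in columns.
#' @param cpg_meta Data frame, one row per CpG: `cpg_id`, `chrom`, `pos`, the
#'   logical region flags (`gene_body`, `tss200`, `tss1500`, `utr5`, `utr3`,
#'   `first_exon`, `enhancer`), `island_context` (one of `island`, `n_shore`,
#'   `s_shore`, `n_shelf`, `s_shelf`, `open_sea`) and logical blacklist flags
#'   (`snp_coincident`, `cross_reactive`, `sex_chromosome`).
#' @param detection_p Optional matrix of per-entry detection p-values, same
#'   shape as `values`.
#' @param scale `"beta"` (default) or `"rank_normal"`.
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(values, cpg_meta, detection_p = NULL, scale = "beta") {
  cpg_meta <- tibble::as_tibble(cpg_meta)
  stopifnot(is.matrix(values), nrow(cpg_meta) == ncol(values))
  if (!all(c("cpg_id", "chrom", "pos", "island_context") %in% names(cpg_meta))) {
    abort("cpg_meta needs at least cpg_id, chrom, pos, island_context")
  }
  ok_ctx <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf", "open_sea")
  if (!all(cpg_meta$island_context %in% ok_ctx)) {
    abort("island_context must be exactly one of the island/shore/shelf/open_sea categories")
  }
  if (scale == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      abort("beta values must lie in [0, 1]")
    }
  }
  if (!is.null(detection_p)) stopifnot(all(dim(detection_p) == dim(values)))
  colnames(values) <- cpg_meta$cpg_id
  structure(
    list(values = values, cpg_meta = cpg_meta, detection_p = detection_p,
         scale = scale),
    class = "meth_matrix"
  )
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf(
    "<meth_matrix> %d subjects x %d CpGs (%s scale, %d%% missing)\n",
    nrow(x$values), ncol(x$values), x$scale,
    round(100 * mean(is.na(x$values)))
  ))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$values)

subset_meth <- function(m, keep) {
  meth_matrix(
    m$values[, keep, drop = FALSE],
    m$cpg_meta[keep, , drop = FALSE],
    detection_p = if (!is.null(m$detection_p)) m$detection_p[, keep, drop = FALSE],
    scale = m$scale
  )
}

REGION_FLAGS <- c("gene_body", "tss200", "tss1500", "utr5", "utr3",
                  "first_exon", "enhancer")
BLACKLIST_FLAGS <- c("snp_coincident", "cross_reactive", "sex_chromosome")
ISLAND_CONTEXTS <- c("island", "n_shore", "s_shore", "n_shelf", "s_shelf",
                     "open_sea")
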