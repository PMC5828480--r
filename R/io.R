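#' Write and read tabular pipeline artifacts
#'
#' All stage outputs are plain TSV so every stage can be run and inspected in
#' isolation. Genotypes can additionally be written as a minimal VCF (GT
#' field, coding allele as ALT).
#'
#' @param G A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name meqtlcross-io
NULL

#' @rdname meqtlcross-io
#' @export
write_dosage_tsv <- function(G, path) {
  d <- tibble::as_tibble(t(G$dosage), .name_repair = "minimal")
  names(d) <- rownames(G$dosage)
  out <- dplyr::bind_cols(G$snp_meta[c("snp_id", "chrom", "pos",
                                       "coding_allele", "other_allele", "maf")],
                          d)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname meqtlcross-io
#' @export
read_dosage_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "coding_allele", "other_allele", "maf")
  dosage <- t(as.matrix(x[setdiff(names(x), meta_cols)]))
  colnames(dosage) <- x$snp_id
  geno_matrix(dosage, x[meta_cols])
}

#' @rdname meqtlcross-io
#' @export
write_genotypes_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=meqtlcross",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G$dosage)), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G$dosage))) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1])
    writeLines(paste(c(
      G$snp_meta$chrom[j], G$snp_meta$pos[j], G$snp_meta$snp_id[j],
      G$snp_meta$other_allele[j], G$snp_meta$coding_allele[j],
      ".", "PASS", ".", "GT", gt
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname meqtlcross-io
#' @param M A [meth_matrix()].
#' @export
write_methylation_tsv <- function(M, path) {
  d <- tibble::as_tibble(t(M$values), .name_repair = "minimal")
  names(d) <- rownames(M$values) %||% paste0("s", seq_len(nrow(M$values)))
  out <- dplyr::bind_cols(M$cpg_meta, d)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname meqtlcross-io
#' @param tab A `meqtl_table`.
#' @export
write_meqtl_table <- function(tab, path) {
  readr::write_tsv(tibble::as_tibble(tab), path)
  invisible(path)
}

#' @rdname meqtlcross-io
#' @export
read_meqtl_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  new_meqtl_table(
    x, tissue = NA_character_, window = NA, p_threshold = NA,
    covariates = character(), n_pairs_tested = NA,
    universe_snps = dplyr::distinct(x[c("snp_id", "chrom", "pos")]),
    universe_cpgs = dplyr::distinct(
      tibble::tibble(cpg_id = x$cpg_id, chrom = x$chrom, pos = x$cpg_pos))
  )
}

#' @rdname meqtlcross-io
#' @param truth A truth table from [build_cohort()].
#' @export
write_truth_table <- function(truth, path) {
  pp <- truth$planted_pairs
  pp$tissues <- vapply(pp$tissues, paste, character(1), collapse = ",")
  readr::write_tsv(pp, path)
  invisible(path)
}
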