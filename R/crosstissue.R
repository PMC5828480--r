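STRAND_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize meQTL coding alleles between two studies
#'
#' For records of the same SNP (matched by chromosome position), determines
#' the multiplier to apply to study B's effect so both describe the effect of
#' the same allele: `+1` when coding alleles agree directly or after strand
#' complement, `-1` when coding/other are swapped (directly or after
#' complement). Palindromic SNPs (A/T or C/G) are dropped as
#' strand-ambiguous, as are irreconcilable allele pairs; drops are recorded,
#' not raised.
#'
#' @param coding_a,other_a,coding_b,other_b Character vectors of alleles
#'   (A/C/G/T), recycled to a common length.
#' @return Tibble with `sign` (`+1`, `-1`, or `NA` when dropped) and
#'   `drop_reason` (`NA`, `"palindromic"`, or `"allele_mismatch"`).
#' @export
harmonize_alleles <- function(coding_a, other_a, coding_b, other_b) {
  n <- max(lengths(list(coding_a, other_a, coding_b, other_b)))
  ca <- rep_len(toupper(coding_a), n); oa <- rep_len(toupper(other_a), n)
  cb <- rep_len(toupper(coding_b), n); ob <- rep_len(toupper(other_b), n)
  pal <- ca == STRAND_COMPLEMENT[oa]  # A/T or C/G pair in study A
  cbf <- STRAND_COMPLEMENT[cb]; obf <- STRAND_COMPLEMENT[ob]
  same <- (ca == cb & oa == ob) | (ca == cbf & oa == obf)
  swap <- (ca == ob & oa == cb) | (ca == obf & oa == cbf)
  sign <- dplyr::case_when(pal ~ NA_real_, same ~ 1, swap ~ -1,
                           TRUE ~ NA_real_)
  reason <- dplyr::case_when(
    pal ~ "palindromic",
    !same & !swap ~ "allele_mismatch",
    TRUE ~ NA_character_
  )
  tibble::tibble(sign = sign, drop_reason = reason)
}

#' Match meQTL tables from two tissues
#'
#' Pairs records present in both tables, keyed by SNP chromosome position and
#' CpG chromosome position (not by id), with alleles harmonized by
#' [harmonize_alleles()]. The returned sign multiplier is applied to study
#' B's `beta_hat` in all downstream statistics.
#'
#' @param tab_a,tab_b `meqtl_table` objects (or tibbles with the same
#'   columns).
#' @return A `matched_pairs` tibble: SNP/CpG keys, `beta_hat_a`,
#'   `beta_hat_b` (unharmonized), `sign`, `maf_a`, `maf_b`, `n_a`, `n_b`;
#'   attribute `drops` counts pairs discarded per reason.
#' @export
match_tables <- function(tab_a, tab_b) {
  key <- function(t) paste(t$chrom, t$pos, t$cpg_pos, sep = ":")
  a <- tibble::as_tibble(tab_a); b <- tibble::as_tibble(tab_b)
  a$.key <- key(a); b$.key <- key(b)
  j <- dplyr::inner_join(a, b, by = ".key", suffix = c("_a", "_b"))
  if (nrow(j) == 0) warn("no shared meQTL-CpG pairs between the tables")
  h <- harmonize_alleles(j$coding_allele_a, j$other_allele_a,
                         j$coding_allele_b, j$other_allele_b)
  dr <- table(h$drop_reason[!is.na(h$drop_reason)])
  drops <- tibble::tibble(reason = names(dr), n = as.integer(dr))
  out <- tibble::tibble(
    chrom = j$chrom_a, pos = j$pos_a, cpg_pos = j$cpg_pos_a,
    snp_id = j$snp_id_a, cpg_id = j$cpg_id_a,
    beta_hat_a = j$beta_hat_a, beta_hat_b = j$beta_hat_b,
    sign = h$sign, maf_a = j$maf_a, maf_b = j$maf_b,
    n_a = j$n_a, n_b = j$n_b
  )[!is.na(h$sign), ]
  structure(out, class = c("matched_pairs", class(out)), drops = drops)
}

#' Sign concordance and effect-pattern similarity of matched pairs
#'
#' Fraction of matched meQTL-CpG pairs whose normalized effects have the
#' same sign after allele harmonization, and the Spearman rank correlation
#' of the harmonized effects (average ranks for ties). A `beta_hat` of
#' exactly zero is counted as positive sign and tallied in `n_zero`.
#'
#' @param matched A `matched_pairs` tibble from [match_tables()].
#' @return One-row tibble `n_pairs`, `same_sign_fraction`, `spearman_rho`,
#'   `n_zero`.
#' @export
concordance_stats <- function(matched) {
  a <- matched$beta_hat_a
  b <- matched$beta_hat_b * matched$sign
  n <- length(a)
  same <- mean((a >= 0) == (b >= 0))
  rho <- if (n >= 2) cor(a, b, method = "spearman") else NA_real_
  tibble::tibble(n_pairs = n, same_sign_fraction = same,
                 spearman_rho = rho, n_zero = sum(a == 0 | b == 0))
}

restrict_pairs <- function(matched, restricted) {
  eff_a <- abs(matched$beta_hat_a) / sqrt(matched$n_a * 2 * matched$maf_a * (1 - matched$maf_a))
  eff_b <- abs(matched$beta_hat_b) / sqrt(matched$n_b * 2 * matched$maf_b * (1 - matched$maf_b))
  keep <- abs(matched$maf_a - matched$maf_b) < restricted$max_maf_diff &
    analytic_power(restricted$n_ref, matched$maf_a, eff_a) >= restricted$min_power &
    analytic_power(restricted$n_ref, matched$maf_b, eff_b) >= restricted$min_power
  matched[keep, , drop = FALSE]
}

#' Cross-tissue overlap summary
#'
#' Restricts every table to the SNPs and CpGs present in all scans' universes
#' (matched by chromosome position), then reports, per tissue, the fraction
#' of common SNPs with cis-meQTL effects and of common CpGs targeted; per
#' tissue pair, the shared pair/meQTL/CpG counts and the per-tissue shared
#' fractions (denominator: that tissue's own significant set in the common
#' universe), with sign-concordance and Spearman statistics of the matched
#' effects; and, for three or more tables, the all-tissue intersection.
#'
#' In restricted mode (`restricted = list(max_maf_diff =, min_power =,
#' n_ref =)`), matched pairs are first filtered to MAF-concordant pairs
#' (difference below `max_maf_diff`) whose implied per-allele effects reach
#' `min_power` detection power at `n_ref` samples, emulating a
#' detection-power-controlled comparison.
#'
#' @param tables Named list of >= 2 `meqtl_table` objects.
#' @param restricted Optional list with `max_maf_diff`, `min_power`, `n_ref`.
#' @return An `overlap_summary` object: list of tibbles `per_tissue`,
#'   `pairwise`, and `threeway` (when >= 3 tables).
#' @export
overlap_summary <- function(tables, restricted = NULL) {
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables))) {
    names(tables) <- vapply(tables, function(t) attr(t, "tissue") %||% "t",
                            character(1))
  }
  snp_key <- function(meta) paste(meta$chrom, meta$pos, sep = ":")
  cpg_key <- function(meta) paste(meta$chrom, meta$pos, sep = ":")
  uni_snps <- Reduce(intersect, lapply(tables, function(t)
    snp_key(attr(t, "universe_snps"))))
  uni_cpgs <- Reduce(intersect, lapply(tables, function(t)
    cpg_key(attr(t, "universe_cpgs"))))

  restricted_tab <- lapply(tables, function(t) {
    tt <- tibble::as_tibble(t)
    tt[paste(tt$chrom, tt$pos, sep = ":") %in% uni_snps &
         paste(tt$chrom, tt$cpg_pos, sep = ":") %in% uni_cpgs, ]
  })

  per_tissue <- purrr::imap_dfr(restricted_tab, function(tt, nm) {
    tibble::tibble(
      tissue = nm,
      n_pairs = nrow(tt),
      n_meqtl = dplyr::n_distinct(paste(tt$chrom, tt$pos)),
      n_cpg = dplyr::n_distinct(paste(tt$chrom, tt$cpg_pos)),
      frac_common_snps_meqtl = dplyr::n_distinct(paste(tt$chrom, tt$pos, sep = ":")) /
        length(uni_snps),
      frac_common_cpgs_targeted = dplyr::n_distinct(paste(tt$chrom, tt$cpg_pos, sep = ":")) /
        length(uni_cpgs)
    )
  })

  combos <- utils::combn(names(tables), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(combos, function(nm) {
    a <- restricted_tab[[nm[1]]]; b <- restricted_tab[[nm[2]]]
    matched <- match_tables(a, b)
    if (!is.null(restricted)) matched <- restrict_pairs(matched, restricted)
    conc <- concordance_stats(matched)
    if (is.null(restricted)) {
      # sharing is defined by position matching alone; allele harmonization
      # (which drops palindromic SNPs) only gates the effect comparison
      pk <- function(t) paste(t$chrom, t$pos, t$cpg_pos, sep = ":")
      shared_keys <- intersect(pk(a), pk(b))
      sh <- a[pk(a) %in% shared_keys, ]
      n_shared <- length(shared_keys)
      shared_snps <- dplyr::n_distinct(paste(sh$chrom, sh$pos))
      shared_cpgs <- dplyr::n_distinct(paste(sh$chrom, sh$cpg_pos))
    } else {
      n_shared <- nrow(matched)
      shared_snps <- dplyr::n_distinct(paste(matched$chrom, matched$pos))
      shared_cpgs <- dplyr::n_distinct(paste(matched$chrom, matched$cpg_pos))
    }
    tibble::tibble(
      tissue_a = nm[1], tissue_b = nm[2],
      n_shared_pairs = n_shared,
      frac_pairs_a = n_shared / max(nrow(a), 1),
      frac_pairs_b = n_shared / max(nrow(b), 1),
      frac_meqtl_a = shared_snps /
        max(dplyr::n_distinct(paste(a$chrom, a$pos)), 1),
      frac_meqtl_b = shared_snps /
        max(dplyr::n_distinct(paste(b$chrom, b$pos)), 1),
      frac_cpg_a = shared_cpgs /
        max(dplyr::n_distinct(paste(a$chrom, a$cpg_pos)), 1),
      frac_cpg_b = shared_cpgs /
        max(dplyr::n_distinct(paste(b$chrom, b$cpg_pos)), 1),
      same_sign_fraction = conc$same_sign_fraction,
      spearman_rho = conc$spearman_rho
    )
  })

  threeway <- NULL
  if (length(tables) >= 3) {
    pair_keys <- lapply(restricted_tab, function(tt)
      paste(tt$chrom, tt$pos, tt$cpg_pos, sep = ":"))
    shared <- Reduce(intersect, pair_keys)
    first <- restricted_tab[[1]]
    fk <- paste(first$chrom, first$pos, first$cpg_pos, sep = ":")
    sh <- first[fk %in% shared, ]
    threeway <- tibble::tibble(
      n_shared_pairs = length(shared),
      n_shared_meqtl = dplyr::n_distinct(paste(sh$chrom, sh$pos)),
      n_shared_cpg = dplyr::n_distinct(paste(sh$chrom, sh$cpg_pos))
    )
  }

  structure(
    list(per_tissue = per_tissue, pairwise = pairwise, threeway = threeway,
         n_common_snps = length(uni_snps), n_common_cpgs = length(uni_cpgs),
         restricted = restricted),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d common SNPs, %d common CpGs%s\n",
              x$n_common_snps, x$n_common_cpgs,
              if (!is.null(x$restricted)) " (restricted mode)" else ""))
  print(x$per_tissue)
  print(x$pairwise)
  if (!is.null(x$threeway)) print(x$threeway)
  invisible(x)
}

#' Overlap percentages from printed counts
#'
#' Bookkeeping helper used in overlap and enrichment reports: converts
#' overlap counts and their denominators to percentages on the 0-100 scale,
#' rounded to a given number of digits.
#'
#' @param counts Data frame with columns `label`, `n_overlap`, `n_total`.
#' @param digits Decimal places to round to (default 2, the convention used
#'   in cohort reports).
#' @return The input with a `pct` column, `100 * n_overlap / n_total`.
#' @export
overlap_percentages <- function(counts, digits = 2) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("n_overlap", "n_total") %in% names(counts)))
  if (any(counts$n_overlap > counts$n_total)) {
    abort("overlap counts cannot exceed totals")
  }
  counts$pct <- round(100 * counts$n_overlap / counts$n_total, digits)
  counts
}
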