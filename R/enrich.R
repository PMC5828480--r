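#' Composite LD between two SNPs
#'
#' Squared Pearson correlation of additive dosage vectors. Invariant to
#' allele recoding (`g -> 2 - g`). A constant vector makes the correlation
#' undefined; it is treated as `r^2 = 0` with a warning.
#'
#' @param g1,g2 Dosage vectors of equal length.
#' @return Squared correlation in `[0, 1]`.
#' @export
genotype_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (var(g1) == 0 || var(g2) == 0) {
    warn("constant dosage vector: r^2 undefined, returning 0")
    return(0)
  }
  cor(g1, g2)^2
}

#' Annotation-supervised greedy LD pruning
#'
#' Greedy scan that keeps a SNP iff its `r^2` with every already-kept SNP
#' within `window` bp is at most `r2_max`. Priority SNPs (e.g. GWAS risk
#' loci) are processed first, in position order, then the remaining SNPs in
#' position order — so a priority SNP is never removed in favor of a
#' non-priority partner.
#'
#' @param G A [geno_matrix()].
#' @param priority Character vector of SNP ids to keep with high priority.
#' @param r2_max Pruning threshold in (0, 1) (0.7 in the source analysis).
#' @param window Maximum bp distance at which two SNPs are compared.
#' @return Character vector of kept SNP ids (position order).
#' @export
supervised_ld_prune <- function(G, priority = character(), r2_max = 0.7,
                                window = 1e6) {
  if (r2_max <= 0 || r2_max >= 1) abort("r2_max must lie in (0, 1)")
  meta <- G$snp_meta
  is_pri <- meta$snp_id %in% priority
  ord <- c(which(is_pri)[order(meta$pos[which(is_pri)])],
           which(!is_pri)[order(meta$pos[which(!is_pri)])])
  kept <- integer()
  for (i in ord) {
    close_kept <- kept[meta$chrom[kept] == meta$chrom[i] &
                         abs(meta$pos[kept] - meta$pos[i]) <= window]
    ok <- TRUE
    for (k in close_kept) {
      r2 <- suppressWarnings(genotype_r2(G$dosage[, i], G$dosage[, k]))
      if (r2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  meta$snp_id[sort(kept)]
}

maf_bin <- function(maf, bin_width = 0.05) {
  nb <- ceiling(0.5 / bin_width)
  pmin(floor(maf / bin_width), nb - 1L)  # last bin right-closed at 0.5
}

#' MAF-matched permutation enrichment test
#'
#' Tests whether `query` SNPs overlap `annotation` more than random SNP sets
#' of the same size and similar MAF distribution drawn from `universe`.
#' Query SNPs are binned by MAF (bins of `bin_width`, last bin right-closed
#' at 0.5) and each null set is drawn without replacement within bins,
#' matching the query's per-bin counts. The empirical p-value is the
#' fraction of null sets with a strictly higher overlap proportion than
#' observed; a value of 0 should be reported as `< 1/n_sets`.
#'
#' The default path draws only the per-bin annotation-overlap counts of each
#' null set (hypergeometric within each bin), which has exactly the null
#' distribution of the overlap proportion under set sampling;
#' `return_sets = TRUE` materializes the explicit SNP sets instead.
#'
#' @param query Character vector of query SNP ids (must be in `universe`).
#' @param annotation Character vector of annotated SNP ids.
#' @param universe Data frame with `snp_id` and `maf` for the (pruned) SNP
#'   universe.
#' @param bin_width MAF bin width (default 0.05).
#' @param n_sets Number of null sets (>= 100; 1e5 in the source analysis).
#' @param seed RNG seed.
#' @param return_sets If `TRUE`, also return the sampled null sets (list of
#'   character vectors); forces explicit set sampling.
#' @return A list of class `perm_enrichment`: `observed_proportion`,
#'   `p_perm`, `n_sets`, `null_proportions`, and optionally `null_sets`.
#' @export
maf_matched_permutation <- function(query, annotation, universe,
                                    bin_width = 0.05, n_sets = 1e5,
                                    seed = 1, return_sets = FALSE) {
  if (n_sets < 100) abort("n_sets must be at least 100")
  universe <- tibble::as_tibble(universe)
  stopifnot(all(c("snp_id", "maf") %in% names(universe)))
  if (!all(query %in% universe$snp_id)) {
    abort("query must be a subset of the universe")
  }
  set.seed(seed)
  q_n <- length(query)
  observed <- mean(query %in% annotation)
  universe$bin <- maf_bin(universe$maf, bin_width)
  universe$in_ann <- universe$snp_id %in% annotation
  q_bins <- universe$bin[match(query, universe$snp_id)]
  q_counts <- table(factor(q_bins, levels = sort(unique(universe$bin))))
  u_by_bin <- split(seq_len(nrow(universe)), universe$bin)

  short <- names(q_counts)[q_counts > vapply(u_by_bin[names(q_counts)],
                                             length, integer(1))]
  if (length(short)) {
    abort(paste0("universe too small in MAF bin(s): ",
                 paste(short, collapse = ", ")))
  }

  if (return_sets) {
    null_sets <- vector("list", n_sets)
    null_counts <- numeric(n_sets)
    for (s in seq_len(n_sets)) {
      picks <- unlist(lapply(names(q_counts)[q_counts > 0], function(b) {
        idx <- u_by_bin[[b]]
        idx[sample.int(length(idx), q_counts[[b]])]
      }), use.names = FALSE)
      null_sets[[s]] <- universe$snp_id[picks]
      null_counts[s] <- sum(universe$in_ann[picks])
    }
  } else {
    null_sets <- NULL
    null_counts <- rep(0, n_sets)
    for (b in names(q_counts)[q_counts > 0]) {
      idx <- u_by_bin[[b]]
      m_b <- sum(universe$in_ann[idx])
      null_counts <- null_counts +
        rhyper(n_sets, m_b, length(idx) - m_b, q_counts[[b]])
    }
  }
  null_prop <- null_counts / q_n
  structure(
    list(observed_proportion = observed,
         p_perm = mean(null_prop > observed),
         n_sets = n_sets, null_proportions = null_prop,
         null_sets = null_sets),
    class = "perm_enrichment"
  )
}

#' @export
print.perm_enrichment <- function(x, ...) {
  p_str <- if (x$p_perm == 0) sprintf("< %g", 1 / x$n_sets) else
    format(x$p_perm)
  cat(sprintf("<perm_enrichment> observed proportion %.4g, P_perm %s (%d null sets)\n",
              x$observed_proportion, p_str, x$n_sets))
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Reports the sample odds ratio `ad/bc` (with Haldane's 0.5 correction when
#' any cell is zero), a Wald 95% confidence interval on the log odds ratio,
#' and the two-sided exact p-value (sum of hypergeometric probabilities of
#' tables at most as probable as the observed one, via
#' [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of nonnegative counts; rows = set membership,
#'   columns = annotation status.
#' @return One-row tibble `odds_ratio`, `ci_lo`, `ci_hi`, `p_fisher`, plus
#'   the four cell counts `a`, `b`, `c`, `d`.
#' @export
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("fisher_2x2 requires all margins positive")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  hald <- if (any(table == 0)) 0.5 else 0
  or <- ((a + hald) * (d + hald)) / ((b + hald) * (c + hald))
  se_log <- sqrt(1 / (a + hald) + 1 / (b + hald) + 1 / (c + hald) + 1 / (d + hald))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se_log)
  p <- fisher.test(table)$p.value
  tibble::tibble(odds_ratio = or, ci_lo = ci[1], ci_hi = ci[2],
                 p_fisher = p, a = a, b = b, c = c, d = d)
}

#' Full SNP-set enrichment result (permutation + Fisher)
#'
#' Combines [maf_matched_permutation()] with [fisher_2x2()] on the 2x2 table
#' (in query vs not) x (in annotation vs not) over the universe, the
#' reporting format of the source enrichment analyses (OR, 95% CI, P_perm,
#' P_Fisher).
#'
#' @inheritParams maf_matched_permutation
#' @return An `enrichment_result` tibble: `observed_proportion`, `p_perm`,
#'   `n_sets`, `odds_ratio`, `ci_lo`, `ci_hi`, `p_fisher` and the 2x2
#'   counts. Attribute `null_proportions` carries the permutation null.
#' @export
snp_enrichment <- function(query, annotation, universe, bin_width = 0.05,
                           n_sets = 1e5, seed = 1) {
  perm <- maf_matched_permutation(query, annotation, universe,
                                  bin_width = bin_width, n_sets = n_sets,
                                  seed = seed)
  in_q <- universe$snp_id %in% query
  in_a <- universe$snp_id %in% annotation
  tab <- matrix(c(sum(in_q & in_a), sum(in_q & !in_a),
                  sum(!in_q & in_a), sum(!in_q & !in_a)),
                nrow = 2, byrow = TRUE)
  fish <- fisher_2x2(tab)
  out <- dplyr::bind_cols(
    tibble::tibble(observed_proportion = perm$observed_proportion,
                   p_perm = perm$p_perm, n_sets = perm$n_sets),
    fish
  )
  structure(out, class = c("enrichment_result", class(out)),
            null_proportions = perm$null_proportions)
}

#' CpG genomic-context enrichment
#'
#' For each gene-region flag and each CpG-island context, a two-sided Fisher
#' exact test comparing the odds of context membership between two CpG sets
#' (e.g. cross-tissue targeted vs tissue-specific targeted, or combined
#' targeted vs non-targeted).
#'
#' @param cpg_meta CpG metadata with region flags and `island_context`.
#' @param set_a,set_b Character vectors of CpG ids (the contrast).
#' @return An `enrichment_result` tibble with one row per context: `context`,
#'   `kind` (`"region"` or `"island"`), OR, CI, `p_fisher`, and counts.
#'   Contexts with an empty margin are skipped with a message.
#' @export
cpg_context_enrichment <- function(cpg_meta, set_a, set_b) {
  meta <- tibble::as_tibble(cpg_meta)
  in_a <- meta$cpg_id %in% set_a
  in_b <- meta$cpg_id %in% set_b
  contexts <- c(
    setNames(as.list(intersect(REGION_FLAGS, names(meta))),
             intersect(REGION_FLAGS, names(meta))),
    setNames(lapply(ISLAND_CONTEXTS, function(ic) NULL), ISLAND_CONTEXTS)
  )
  rows <- purrr::imap(contexts, function(col, ctx) {
    in_ctx <- if (!is.null(col)) meta[[col]] else meta$island_context == ctx
    tab <- matrix(c(sum(in_a & in_ctx), sum(in_a & !in_ctx),
                    sum(in_b & in_ctx), sum(in_b & !in_ctx)),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      message("skipping context with empty margin: ", ctx)
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(context = ctx,
                     kind = if (!is.null(col)) "region" else "island"),
      fisher_2x2(tab)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  structure(out, class = c("enrichment_result", class(out)))
}
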