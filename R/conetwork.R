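#' Unsigned power adjacency from a methylation matrix
#'
#' `a_ij = |cor(m_i, m_j)|^power` over CpGs (unsigned network), with the
#' diagonal set to 0 for connectivity computations. The soft power defaults
#' to 6, the convention of weighted co-methylation network analysis.
#'
#' @param values Subjects-by-CpGs numeric matrix (or a [meth_matrix()]).
#' @param power Soft-thresholding exponent.
#' @return Symmetric adjacency matrix with zero diagonal.
#' @export
correlation_adjacency <- function(values, power = 6) {
  if (inherits(values, "meth_matrix")) values <- values$values
  if (nrow(values) < 3) abort("need at least 3 subjects")
  const <- which(apply(values, 2, var) == 0)
  if (length(const)) {
    abort(paste0("constant CpGs: ",
                 paste(colnames(values)[const] %||% const, collapse = ", ")))
  }
  A <- abs(cor(values))^power
  diag(A) <- 0
  A
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the row sums of the adjacency; `TOM_ii = 1`. Measures how much two
#' nodes share neighbours in addition to their direct connection.
#'
#' @param A Symmetric adjacency in `[0, 1]` with zero diagonal.
#' @return A `tom` matrix (entries in `[0, 1]`, unit diagonal); attribute
#'   `provenance` is `"single"`.
#' @export
tom_similarity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-12) abort("adjacency must be symmetric")
  if (any(diag(A) != 0)) abort("adjacency must have zero diagonal")
  if (min(A) < 0 || max(A) > 1) abort("adjacency entries must lie in [0, 1]")
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  structure(tom, provenance = "single", class = c("tom", "matrix", "array"))
}

#' Consensus topological overlap across tissues
#'
#' Element-wise minimum of per-tissue TOMs, so a pair of CpGs is only as
#' similar as it is in its least-similar tissue. With `scale = TRUE`, inputs
#' are first quantile-aligned by matching their 95th percentile of
#' off-diagonal entries to the first input's (a documented extension,
#' default off).
#'
#' @param toms List of >= 2 `tom` matrices over the same CpGs in the same
#'   order.
#' @param scale Quantile-align inputs before taking the minimum.
#' @return A `tom` matrix with `provenance = "consensus"`.
#' @export
consensus_tom <- function(toms, scale = FALSE) {
  stopifnot(length(toms) >= 2)
  dims <- vapply(toms, function(t) ncol(t), integer(1))
  nms <- lapply(toms, colnames)
  if (length(unique(dims)) != 1 ||
      (!is.null(nms[[1]]) && !all(vapply(nms, identical, logical(1), nms[[1]])))) {
    abort("all TOMs must cover the same CpGs in the same order")
  }
  if (scale) {
    off <- function(t) t[upper.tri(t)]
    ref_q <- quantile(off(toms[[1]]), 0.95)
    toms <- lapply(toms, function(t) {
      q <- quantile(off(t), 0.95)
      out <- if (q > 0) pmin(t * (ref_q / q), 1) else t
      diag(out) <- 1
      out
    })
  }
  cons <- Reduce(pmin, toms)
  diag(cons) <- 1
  structure(cons, provenance = "consensus", class = c("tom", "matrix", "array"))
}

#' Module detection by static tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a fixed height (`cut_height` times the maximum merge height);
#' clusters smaller than `min_size` are assigned the unlabeled class 0.
#' Remaining modules are labelled 1, 2, ... in decreasing size order.
#'
#' @param tom A `tom` matrix.
#' @param min_size Minimum module size (default 30).
#' @param cut_height Fraction of the maximum merge height at which to cut
#'   (default 0.995).
#' @return Integer vector of module labels, named by CpG when the TOM has
#'   column names.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.995) {
  if (min_size < 2) abort("min_size must be >= 2")
  if (cut_height <= 0 || cut_height > 1) abort("cut_height must lie in (0, 1]")
  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  labels <- cutree(tree, h = cut_height * max(tree$height))
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_size]
  out <- integer(length(labels))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep)) out[labels == keep[i]] <- i
  }
  names(out) <- colnames(tom)
  out
}

#' Module eigengene
#'
#' First principal component scores of the standardized module CpG matrix,
#' scaled to unit variance and sign-oriented so the mean correlation with
#' the module's CpGs is positive.
#'
#' @param values Subjects-by-CpGs matrix of the module's CpGs (at least two
#'   CpGs and three subjects), or a [meth_matrix()].
#' @return Numeric vector of per-subject eigengene scores.
#' @export
module_eigengene <- function(values) {
  if (inherits(values, "meth_matrix")) values <- values$values
  stopifnot(ncol(values) >= 2, nrow(values) >= 3)
  Z <- scale(values)
  # constant CpGs carry no signal; scale() yields NaN - reject
  if (anyNA(Z)) abort("constant CpG in module")
  sv <- svd(Z, nu = 1, nv = 0)
  if (sv$d[1] < 1e-12) abort("rank-0 module matrix")
  me <- sv$u[, 1]
  me <- me / sd(me)
  if (mean(cor(me, Z)) < 0) me <- -me
  me
}

fisher_combine_p <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  stat <- -2 * sum(log(p))
  pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}

stouffer_combine_z <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  sum(z) / sqrt(length(z))
}

# signed z-score equivalent of a t statistic
t_to_z <- function(t, df) {
  sign(t) * qnorm(pt(abs(t), df, lower.tail = FALSE), lower.tail = FALSE)
}

#' Consensus module disease-association statistics
#'
#' For each module: the per-tissue module eigengene is regressed on
#' diagnosis plus covariates (t statistic and p-value for diagnosis); the
#' per-tissue p-values are combined by Fisher's method (chi-square with 2k
#' df; a Stouffer combination of the per-tissue t statistics is also
#' reported, since the two can differ noticeably for two tissues). Module
#' membership (MM) of each CpG is the Stouffer combination across tissues of
#' Fisher r-to-z transformed CpG-eigengene correlations; methylation
#' significance (MS) is the Stouffer combination of the per-tissue
#' diagnosis-association z-scores of the CpG itself (same covariate
#' adjustment). `mm_ms_r` is the Pearson correlation of MM and MS over the
#' module's CpGs.
#'
#' @param modules Integer module labels (0 = unassigned) named or ordered by
#'   CpG, as from [detect_modules()].
#' @param tissue_data Named list; each element a list with `meth` (a
#'   [meth_matrix()] or matrix over the same CpGs) and `covariates` (tibble
#'   with `diagnosis` and the adjustment columns).
#' @param covariate_cols Covariates adjusted for in the ME and CpG models.
#' @param combine `"fisher"` (default) or `"stouffer"` for `combined_p`.
#' @return A `consensus_modules` tibble, one row per module: `module`,
#'   `size`, per-tissue `t_<tissue>` / `p_<tissue>` columns, `combined_p`,
#'   `combined_p_stouffer`, `mm_ms_r`, and a list-column `cpg_stats` of
#'   per-CpG tibbles (`cpg_id`, `mm`, `ms`).
#' @export
module_disease_stats <- function(modules, tissue_data,
                                 covariate_cols = c("age", "sex",
                                                    "cell_epithelial",
                                                    "pc1", "pc2", "pc3"),
                                 combine = c("fisher", "stouffer")) {
  combine <- match.arg(combine)
  tissues <- names(tissue_data)
  get_values <- function(td) {
    if (inherits(td$meth, "meth_matrix")) td$meth$values else td$meth
  }
  mod_ids <- sort(setdiff(unique(modules), 0L))
  cpg_names <- names(modules) %||% colnames(get_values(tissue_data[[1]]))

  rows <- purrr::map(mod_ids, function(m) {
    idx <- which(modules == m)
    per_tissue <- purrr::map(tissue_data, function(td) {
      V <- get_values(td)[, idx, drop = FALSE]
      cv <- td$covariates
      C <- build_design(cv, covariate_cols)
      X <- cbind(1, diagnosis = cv$diagnosis, C)
      me <- module_eigengene(V)
      fit_t <- function(y) {
        qx <- qr(X)
        cf <- qr.coef(qx, y)
        res <- y - X %*% cf
        df <- length(y) - ncol(X)
        se <- sqrt(sum(res^2) / df * chol2inv(qr.R(qx))[2, 2])
        t <- cf[["diagnosis"]] / se
        c(t = t, p = 2 * pt(-abs(t), df), df = df)
      }
      me_stat <- fit_t(me)
      n <- nrow(V)
      r <- drop(cor(V, me))
      mm_z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(n - 3)
      ms_z <- vapply(seq_len(ncol(V)), function(j) {
        st <- fit_t(V[, j])
        t_to_z(st[["t"]], st[["df"]])
      }, numeric(1))
      list(t = me_stat[["t"]], p = me_stat[["p"]], mm_z = mm_z, ms_z = ms_z)
    })
    t_vec <- vapply(per_tissue, `[[`, numeric(1), "t")
    p_vec <- vapply(per_tissue, `[[`, numeric(1), "p")
    mm <- apply(vapply(per_tissue, `[[`, numeric(length(idx)), "mm_z"),
                1, stouffer_combine_z)
    ms <- apply(vapply(per_tissue, `[[`, numeric(length(idx)), "ms_z"),
                1, stouffer_combine_z)
    comb_fisher <- fisher_combine_p(p_vec)
    z_comb <- stouffer_combine_z(t_vec)  # t approx z at these df
    comb_stouffer <- 2 * pnorm(-abs(z_comb))
    row <- tibble::tibble(module = m, size = length(idx))
    for (tn in tissues) {
      row[[paste0("t_", tn)]] <- per_tissue[[tn]]$t
      row[[paste0("p_", tn)]] <- per_tissue[[tn]]$p
    }
    row$combined_p <- if (combine == "fisher") comb_fisher else comb_stouffer
    row$combined_p_stouffer <- comb_stouffer
    row$combined_p_fisher <- comb_fisher
    row$mm_ms_r <- if (length(idx) >= 3) cor(mm, ms) else NA_real_
    ids <- if (is.null(cpg_names)) as.character(idx) else cpg_names[idx]
    row$cpg_stats <- list(tibble::tibble(cpg_id = ids, mm = mm, ms = ms))
    row
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("consensus_modules", class(out)),
            tissues = tissues, combine = combine)
}

#' Consensus co-methylation network analysis, end to end
#'
#' Builds per-tissue unsigned power adjacencies and TOMs over a common CpG
#' set, forms the consensus TOM (element-wise minimum), detects modules by
#' static tree cut, and computes module disease statistics.
#'
#' @inheritParams module_disease_stats
#' @param power Soft-thresholding exponent (default 6).
#' @param min_size,cut_height Module detection parameters.
#' @param scale Quantile-align the per-tissue TOMs (see [consensus_tom()]).
#' @return A list of class `conetwork`: `modules` (labels), `summary` (the
#'   [module_disease_stats()] tibble), `consensus` (the consensus TOM) and
#'   `toms` (per-tissue TOMs).
#' @export
consensus_network <- function(tissue_data, power = 6, min_size = 30,
                              cut_height = 0.995, scale = FALSE,
                              covariate_cols = c("age", "sex",
                                                 "cell_epithelial",
                                                 "pc1", "pc2", "pc3"),
                              combine = c("fisher", "stouffer")) {
  toms <- purrr::map(tissue_data, function(td) {
    v <- if (inherits(td$meth, "meth_matrix")) td$meth$values else td$meth
    tom_similarity(correlation_adjacency(v, power = power))
  })
  cons <- consensus_tom(toms, scale = scale)
  modules <- detect_modules(cons, min_size = min_size, cut_height = cut_height)
  summary <- if (any(modules > 0)) {
    module_disease_stats(modules, tissue_data,
                         covariate_cols = covariate_cols, combine = combine)
  } else {
    warn("no modules above min_size; returning empty summary")
    tibble::tibble()
  }
  structure(list(modules = modules, summary = summary, consensus = cons,
                 toms = toms),
            class = "conetwork")
}

#' @export
print.conetwork <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$modules), 0L))
  cat(sprintf("<conetwork> %d CpGs, %d modules (%d unassigned)\n",
              length(x$modules), n_mod, sum(x$modules == 0)))
  if (nrow(x$summary)) {
    print(dplyr::select(tibble::as_tibble(x$summary), -dplyr::any_of("cpg_stats")))
  }
  invisible(x)
}
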