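#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a meQTL table
#'
#' @param x A `meqtl_table`.
#' @param ... Unused.
#' @return A plain tibble of records.
#' @exportS3Method generics::tidy
tidy.meqtl_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row scan summary
#'
#' @param x A `meqtl_table`.
#' @param ... Unused.
#' @return Tibble with tissue, thresholds, pair/SNP/CpG counts.
#' @exportS3Method generics::glance
glance.meqtl_table <- function(x, ...) {
  tibble::tibble(
    tissue = attr(x, "tissue"),
    window = attr(x, "window"),
    p_threshold = attr(x, "p_threshold"),
    n_pairs_tested = attr(x, "n_pairs_tested"),
    n_significant = nrow(x),
    n_meqtl = dplyr::n_distinct(x$snp_id),
    n_cpg = dplyr::n_distinct(x$cpg_id)
  )
}

#' Tidy an overlap summary into one long tibble
#'
#' @param x An `overlap_summary`.
#' @param ... Unused.
#' @return Long tibble `section`, `label`, `statistic`, `value`.
#' @exportS3Method generics::tidy
tidy.overlap_summary <- function(x, ...) {
  pt <- tidyr::pivot_longer(x$per_tissue, -"tissue", names_to = "statistic",
                            values_to = "value")
  pt <- tibble::tibble(section = "per_tissue", label = pt$tissue,
                       statistic = pt$statistic, value = pt$value)
  pw <- tidyr::pivot_longer(x$pairwise, -c("tissue_a", "tissue_b"),
                            names_to = "statistic", values_to = "value")
  pw <- tibble::tibble(section = "pairwise",
                       label = paste(pw$tissue_a, pw$tissue_b, sep = ":"),
                       statistic = pw$statistic, value = pw$value)
  out <- dplyr::bind_rows(pt, pw)
  if (!is.null(x$threeway)) {
    tw <- tidyr::pivot_longer(x$threeway, dplyr::everything(),
                              names_to = "statistic", values_to = "value")
    out <- dplyr::bind_rows(out, tibble::tibble(
      section = "threeway", label = "all", statistic = tw$statistic,
      value = tw$value))
  }
  out
}

#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A plain tibble.
#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) tibble::as_tibble(x)

#' Tidy consensus module statistics
#'
#' @param x A `consensus_modules` tibble.
#' @param ... Unused.
#' @return Per-CpG tibble `module`, `cpg_id`, `mm`, `ms`.
#' @exportS3Method generics::tidy
tidy.consensus_modules <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(tibble::as_tibble(x), "module", "cpg_stats"),
    "cpg_stats"
  )
}

#' Per-module summary without per-CpG detail
#'
#' @param x A `consensus_modules` tibble.
#' @param ... Unused.
#' @return The module-level tibble (no list columns).
#' @exportS3Method generics::glance
glance.consensus_modules <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"cpg_stats")
}

#' Scatter of harmonized cross-tissue effects
#'
#' Normalized effects (`beta_hat`) of matched meQTL-CpG pairs, study B
#' harmonized to study A's coding alleles; the sign-concordant quadrants
#' make the same-sign fraction visible.
#'
#' @param object A `matched_pairs` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.matched_pairs <- function(object, ...) {
  df <- tibble::tibble(a = object$beta_hat_a,
                       b = object$beta_hat_b * object$sign)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "normalized effect, study A",
                  y = "normalized effect, study B (harmonized)")
}

#' Forest plot of enrichment odds ratios
#'
#' @param object An `enrichment_result` tibble (one or more rows; rows are
#'   labelled by `context` when present).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- df$context %||% as.character(seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL)
}

#' Module membership vs methylation significance
#'
#' One panel per consensus module: each CpG's combined module membership
#' Z-score (MM) against its combined disease-association Z-score (MS), the
#' diagnostic for disease-relevant modules.
#'
#' @param object A `consensus_modules` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_modules <- function(object, ...) {
  df <- tidy.consensus_modules(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mm, y = .data$ms)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::facet_wrap(~ module, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "module membership (combined Z)",
                  y = "methylation significance (combined Z)")
}
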