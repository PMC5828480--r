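#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run with the pipeline's
#' defaults (cis window 20 kb, scan threshold 1e-5, LD r2 0.7, MAF bin width
#' 0.05, adjacency power 6). Accepts a YAML file path or a named list of
#' overrides; unknown fields raise an error, and every parameter is echoed
#' in the run report so there are no hidden defaults.
#'
#' @param config Optional YAML path or named list overriding defaults.
#' @param spec A [cohort_spec()] for the simulation stage (default
#'   `cohort_spec()`).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(config = NULL, spec = cohort_spec()) {
  defaults <- list(
    window = 20000, p_threshold = 1e-5,
    max_snp_missing = 0.1, min_maf = 0.01, hwe_alpha = 1e-6,
    max_missing = 0.01, detection_alpha = 0.05,
    r2_max = 0.7, prune_window = 1e6, bin_width = 0.05, n_sets = 2000,
    power = 6, min_size = 30, cut_height = 0.995,
    seed = spec$seed
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    bad <- setdiff(names(config), names(defaults))
    if (length(bad)) abort(paste0("unknown config fields: ",
                                  paste(bad, collapse = ", ")))
    defaults[names(config)] <- config
  }
  stopifnot(defaults$window > 0, defaults$p_threshold >= 0,
            defaults$r2_max > 0, defaults$r2_max < 1,
            defaults$bin_width > 0, defaults$n_sets >= 100,
            defaults$power > 0, defaults$min_size >= 2)
  structure(c(defaults, list(spec = spec)), class = "run_config")
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> QC -> per-tissue cis-meQTL scan -> cross-tissue comparison ->
#' annotation enrichment (against the cohort's planted risk-SNP set, after
#' supervised LD pruning) -> consensus co-methylation network. All stage
#' outputs are written as TSV into `out_dir` together with a plain-text
#' report echoing every stage parameter and a log; identical config and seed
#' reproduce identical outputs.
#'
#' @param config A [pipeline_config()] (or arguments accepted by it).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `tables`, `overlap`, `enrichment`, `network`, paths).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (!inherits(config, "run_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(paste0(format(Sys.time(), "%H:%M:%S "), msg), log_con)
    message(msg)
  }
  run_stage <- function(name, expr) {
    say("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      say("stage %s: FAILED (%s)", name, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    say("stage %s: done", name)
    res
  }

  cohort <- run_stage("simulate", build_cohort(config$spec))
  tissues <- names(cohort$tissues)

  qc_done <- run_stage("qc", purrr::map(cohort$tissues, function(td) {
    g <- genotype_qc(td$geno, config$max_snp_missing, config$min_maf,
                     config$hwe_alpha)
    m <- td$meth |>
      methylation_qc(config$max_missing, config$detection_alpha) |>
      quantile_normalize() |>
      mean_impute() |>
      batch_adjust(td$covariates)
    list(geno = g, meth = m, covariates = td$covariates)
  }))

  tables <- run_stage("scan", purrr::imap(qc_done, function(td, tn) {
    tab <- scan_tissue(td$geno, td$meth, td$covariates,
                       window = config$window,
                       p_threshold = config$p_threshold, tissue = tn)
    write_meqtl_table(tab, file.path(out_dir, paste0("meqtl_", tn, ".tsv")))
    tab
  }))

  overlap <- run_stage("compare", {
    empty <- vapply(tables, nrow, integer(1)) == 0
    if (any(empty)) warn(paste("empty meQTL tables:",
                               paste(tissues[empty], collapse = ", ")))
    ov <- overlap_summary(tables)
    readr::write_tsv(ov$per_tissue, file.path(out_dir, "overlap_per_tissue.tsv"))
    readr::write_tsv(ov$pairwise, file.path(out_dir, "overlap_pairwise.tsv"))
    ov
  })

  enrichment <- run_stage("enrich", {
    g1 <- qc_done[[1]]$geno
    detected <- unique(unlist(lapply(tables, function(t) t$snp_id)))
    risk <- cohort$truth$risk_snps
    pruned <- supervised_ld_prune(g1, priority = risk,
                                  r2_max = config$r2_max,
                                  window = config$prune_window)
    uni <- g1$snp_meta[g1$snp_meta$snp_id %in% pruned, c("snp_id", "maf")]
    query <- intersect(detected, uni$snp_id)
    if (length(query) < 2) {
      warn("too few detected meQTLs for enrichment; skipping")
      NULL
    } else {
      enr <- snp_enrichment(query, intersect(risk, uni$snp_id), uni,
                            bin_width = config$bin_width,
                            n_sets = config$n_sets, seed = config$seed)
      readr::write_tsv(tibble::as_tibble(enr),
                       file.path(out_dir, "enrichment.tsv"))
      enr
    }
  })

  network <- run_stage("network", {
    target_cpgs <- Reduce(intersect, lapply(tables, function(t) t$cpg_id))
    module_pool <- unique(cohort$truth$module_loadings$cpg_id)
    use_cpgs <- union(target_cpgs, module_pool)
    use_cpgs <- intersect(colnames(qc_done[[1]]$meth$values), use_cpgs)
    if (length(use_cpgs) < config$min_size) {
      warn("too few cross-tissue CpGs for network analysis; skipping")
      NULL
    } else {
      td <- purrr::map(qc_done, function(x) {
        keep <- match(use_cpgs, colnames(x$meth$values))
        list(meth = x$meth$values[, keep, drop = FALSE],
             covariates = x$covariates)
      })
      net <- consensus_network(td, power = config$power,
                               min_size = config$min_size,
                               cut_height = config$cut_height)
      readr::write_tsv(
        tibble::tibble(cpg_id = names(net$modules), module = net$modules),
        file.path(out_dir, "modules.tsv"))
      if (nrow(net$summary)) {
        readr::write_tsv(
          dplyr::select(tibble::as_tibble(net$summary), -"cpg_stats"),
          file.path(out_dir, "module_summary.tsv"))
      }
      net
    }
  })

  report <- c(
    "meqtlcross pipeline report",
    "==========================",
    sprintf("seed: %d", config$seed),
    sprintf("tissues: %s", paste(tissues, collapse = ", ")),
    sprintf("subjects: %s", paste(names(config$spec$n_subjects),
                                  config$spec$n_subjects, sep = "=",
                                  collapse = " ")),
    "stage parameters:",
    sprintf("  genotype QC: max missing %g, min MAF %g, HWE alpha %g",
            config$max_snp_missing, config$min_maf, config$hwe_alpha),
    sprintf("  methylation QC: max missing %g, detection alpha %g",
            config$max_missing, config$detection_alpha),
    sprintf("  scan: window %d bp, p threshold %g", config$window,
            config$p_threshold),
    sprintf("  enrichment: LD r2 max %g (window %g bp), MAF bin %g, %d null sets",
            config$r2_max, config$prune_window, config$bin_width,
            config$n_sets),
    sprintf("  network: power %g, min module size %d, cut height %g",
            config$power, config$min_size, config$cut_height),
    "results:",
    sprintf("  meQTL pairs per tissue: %s",
            paste(tissues, vapply(tables, nrow, integer(1)), sep = "=",
                  collapse = " ")),
    if (!is.null(overlap$threeway))
      sprintf("  pairs shared by all tissues: %d",
              overlap$threeway$n_shared_pairs),
    if (!is.null(enrichment))
      sprintf("  risk-set enrichment: OR %.2f, P_perm %s, P_Fisher %.3g",
              enrichment$odds_ratio,
              if (enrichment$p_perm == 0)
                sprintf("< %g", 1 / enrichment$n_sets)
              else format(enrichment$p_perm),
              enrichment$p_fisher),
    if (!is.null(network))
      sprintf("  consensus modules: %d",
              length(setdiff(unique(network$modules), 0L)))
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  say("pipeline complete: %s", out_dir)

  invisible(list(cohort = cohort, tables = tables, overlap = overlap,
                 enrichment = enrichment, network = network,
                 out_dir = out_dir))
}
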