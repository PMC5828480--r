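#' Specification of a synthetic multi-tissue cohort
#'
#' Defines the study conditions for [build_cohort()]: three tissues (by
#' default mirroring the designs of the prefrontal-cortex, whole-blood, and
#' saliva cohorts this pipeline targets: 258, 837, and 197 subjects) sharing
#' one SNP and one CpG universe on a single chromosome, with cis effects
#' planted on the logit-methylation scale that are partly shared across all
#' tissues and partly tissue-specific, batch structure, case/control labels,
#' planted co-methylation disease modules, and an annotation SNP set planted
#' at a target odds ratio against the meQTL truth set.
#'
#' @param n_subjects Named integer vector, subjects per tissue.
#' @param n_snps,n_cpgs Universe sizes.
#' @param chrom_length Chromosome length in bp; positions are 1-based.
#' @param maf_range Interval within (0, 0.5] for population MAF draws.
#' @param frac_cis_pairs Fraction of CpGs given a planted cis SNP effect.
#' @param frac_shared Fraction of planted effects present in every tissue
#'   (with identical effect size and sign); the rest are planted in exactly
#'   one tissue.
#' @param effect_size_range Per-allele effect magnitude range, logit scale.
#' @param noise_sd Residual SD on the logit scale.
#' @param cis_window Maximum planted SNP-CpG distance, bp.
#' @param n_batches Number of batches per tissue.
#' @param batch_shift_sd SD of per-(batch, CpG) location shifts, logit scale.
#' @param case_fraction Fraction of subjects labelled cases.
#' @param module_size Integer vector of planted co-methylation module sizes.
#' @param module_effect Numeric vector (recycled) of case-control shifts of
#'   each module's latent factor, logit scale.
#' @param module_tissues Optional list (one element per module) of tissue
#'   names the module is expressed in; default all tissues.
#' @param blacklist_frac Fraction of CpGs given a probe blacklist flag.
#' @param risk_set_size Size of the planted annotation ("risk locus") SNP
#'   set; 0 disables planting.
#' @param risk_target_or Target odds ratio between the annotation set and
#'   the planted meQTL SNPs.
#' @param seed Master RNG seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(brain = 258, blood = 837, saliva = 197),
                        n_snps = 500, n_cpgs = 500,
                        chrom_length = 5e6,
                        maf_range = c(0.05, 0.5),
                        frac_cis_pairs = 0.15,
                        frac_shared = 0.6,
                        effect_size_range = c(0.3, 0.8),
                        noise_sd = 0.3,
                        cis_window = 20000,
                        n_batches = 2,
                        batch_shift_sd = 0.2,
                        case_fraction = 0.5,
                        module_size = 50,
                        module_effect = 0.5,
                        module_tissues = NULL,
                        blacklist_frac = 0.02,
                        risk_set_size = 50,
                        risk_target_or = 2,
                        seed = 1) {
  assert_count(n_subjects, "n_subjects", min = 2)
  assert_count(n_snps, "n_snps"); assert_count(n_cpgs, "n_cpgs")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be an interval within (0, 0.5]")
  }
  assert_fraction(frac_cis_pairs, "frac_cis_pairs")
  assert_fraction(frac_shared, "frac_shared")
  assert_fraction(case_fraction, "case_fraction")
  if (any(module_size > n_cpgs)) abort("module_size cannot exceed n_cpgs")
  if (sum(module_size) > n_cpgs) abort("planted modules cannot cover more CpGs than exist")
  assert_fraction(blacklist_frac, "blacklist_frac")
  if (is.null(names(n_subjects))) {
    names(n_subjects) <- paste0("tissue", seq_along(n_subjects))
  }
  module_effect <- rep_len(module_effect, length(module_size))
  if (!is.null(module_tissues)) {
    stopifnot(length(module_tissues) == length(module_size))
    bad <- setdiff(unlist(module_tissues), names(n_subjects))
    if (length(bad)) abort("module_tissues refers to unknown tissues")
  }
  structure(
    list(
      n_subjects = n_subjects, n_snps = n_snps, n_cpgs = n_cpgs,
      chrom_length = chrom_length, maf_range = maf_range,
      frac_cis_pairs = frac_cis_pairs, frac_shared = frac_shared,
      effect_size_range = effect_size_range, noise_sd = noise_sd,
      cis_window = cis_window, n_batches = n_batches,
      batch_shift_sd = batch_shift_sd, case_fraction = case_fraction,
      module_size = module_size, module_effect = module_effect,
      module_tissues = module_tissues, blacklist_frac = blacklist_frac,
      risk_set_size = risk_set_size, risk_target_or = risk_target_or,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>",
      paste(names(x$n_subjects), x$n_subjects, sep = "=", collapse = " "),
      sprintf("| %d SNPs, %d CpGs, cis window %d bp, seed %d\n",
              x$n_snps, x$n_cpgs, x$cis_window, x$seed))
  invisible(x)
}

# Shared SNP/CpG universe: positions, alleles, population MAFs, CpG
# annotation, and per-CpG baseline logit-methylation.
simulate_universe <- function(spec) {
  set.seed(derive_seed(spec$seed, 1))
  bases <- c("A", "C", "G", "T")
  snp_pos <- sort(sample.int(spec$chrom_length, spec$n_snps))
  al <- t(vapply(seq_len(spec$n_snps), function(i) sample(bases, 2), character(2)))
  snp_meta <- tibble::tibble(
    snp_id = sprintf("snp%05d", seq_len(spec$n_snps)),
    chrom = "chr1", pos = snp_pos,
    coding_allele = al[, 1], other_allele = al[, 2],
    maf_pop = runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  )
  cpg_pos <- sort(sample.int(spec$chrom_length, spec$n_cpgs))
  cpg_meta <- tibble::tibble(
    cpg_id = sprintf("cg%05d", seq_len(spec$n_cpgs)),
    chrom = "chr1", pos = cpg_pos,
    gene_body = runif(spec$n_cpgs) < 0.35,
    tss200 = runif(spec$n_cpgs) < 0.10,
    tss1500 = runif(spec$n_cpgs) < 0.12,
    utr5 = runif(spec$n_cpgs) < 0.06,
    utr3 = runif(spec$n_cpgs) < 0.04,
    first_exon = runif(spec$n_cpgs) < 0.05,
    enhancer = runif(spec$n_cpgs) < 0.12,
    island_context = sample(ISLAND_CONTEXTS, spec$n_cpgs, replace = TRUE,
                            prob = c(0.30, 0.12, 0.12, 0.05, 0.05, 0.36)),
    snp_coincident = runif(spec$n_cpgs) < spec$blacklist_frac / 2,
    cross_reactive = runif(spec$n_cpgs) < spec$blacklist_frac / 2,
    sex_chromosome = FALSE,
    baseline_logit = rnorm(spec$n_cpgs, 0, 1)
  )
  list(snp_meta = snp_meta, cpg_meta = cpg_meta)
}

# Plant cis pairs and co-methylation modules; returns the truth table.
make_truth <- function(spec, universe) {
  set.seed(derive_seed(spec$seed, 2))
  tissues <- names(spec$n_subjects)
  cpg_meta <- universe$cpg_meta
  snp_meta <- universe$snp_meta

  n_target <- round(spec$frac_cis_pairs * spec$n_cpgs)
  planted <- tibble::tibble(snp_id = character(), cpg_id = character(),
                            tissues = list(), effect = double())
  if (n_target > 0) {
    cand <- sample(seq_len(spec$n_cpgs))
    rows <- list()
    for (ci in cand) {
      if (length(rows) >= n_target) break
      d <- abs(snp_meta$pos - cpg_meta$pos[ci])
      hits <- which(d <= spec$cis_window)
      if (!length(hits)) next
      si <- hits[sample.int(length(hits), 1)]
      shared <- runif(1) < spec$frac_shared
      tset <- if (shared) tissues else sample(tissues, 1)
      eff <- runif(1, spec$effect_size_range[1], spec$effect_size_range[2]) *
        sample(c(-1, 1), 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        snp_id = snp_meta$snp_id[si], cpg_id = cpg_meta$cpg_id[ci],
        tissues = list(tset), effect = eff
      )
    }
    if (length(rows)) planted <- dplyr::bind_rows(rows)
  }

  n_mod <- length(spec$module_size)
  module_loadings <- tibble::tibble(cpg_id = character(), module = integer(),
                                    loading = double())
  if (n_mod > 0 && sum(spec$module_size) > 0) {
    pool <- sample(cpg_meta$cpg_id)
    start <- 1L
    mods <- list()
    for (m in seq_len(n_mod)) {
      ids <- pool[start:(start + spec$module_size[m] - 1L)]
      start <- start + spec$module_size[m]
      mods[[m]] <- tibble::tibble(cpg_id = ids, module = m,
                                  loading = runif(spec$module_size[m], 0.8, 1))
    }
    module_loadings <- dplyr::bind_rows(mods)
  }
  module_tissues <- spec$module_tissues %||%
    replicate(n_mod, tissues, simplify = FALSE)

  risk_snps <- character()
  if (spec$risk_set_size > 0) {
    risk_snps <- plant_annotation_set(
      universe = snp_meta$snp_id,
      meqtl_truth = unique(planted$snp_id),
      target_or = spec$risk_target_or,
      size = spec$risk_set_size,
      seed = derive_seed(spec$seed, 3)
    )
  }

  structure(
    list(planted_pairs = planted, module_loadings = module_loadings,
         module_tissues = module_tissues, module_effect = spec$module_effect,
         module_cpgs = split(module_loadings$cpg_id, module_loadings$module),
         risk_snps = risk_snps, risk_target_or = spec$risk_target_or),
    class = "truth_table"
  )
}

#' Simulate biallelic genotypes in Hardy-Weinberg proportions
#'
#' Each SNP's dosage is drawn as Binomial(2, p) with p either taken from
#' `snp_meta$maf_pop` (a shared universe) or sampled in `spec$maf_range`.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of subjects (>= 2).
#' @param seed RNG seed.
#' @param snp_meta Optional universe SNP metadata (with `maf_pop`); generated
#'   from `spec` when absent.
#' @return A [geno_matrix()] whose `snp_meta` records the empirical MAF.
#' @export
simulate_genotypes <- function(spec, n = NULL, seed = spec$seed,
                               snp_meta = NULL) {
  if (is.null(snp_meta)) snp_meta <- simulate_universe(spec)$snp_meta
  n <- n %||% spec$n_subjects[[1]]
  if (n < 2) abort("need at least 2 subjects")
  set.seed(seed)
  p <- snp_meta$maf_pop
  dosage <- matrix(rbinom(n * length(p), 2, rep(p, each = n)),
                   nrow = n, ncol = length(p))
  rownames(dosage) <- sprintf("s%04d", seq_len(n))
  snp_meta$maf <- empirical_maf(dosage)
  geno_matrix(dosage, snp_meta)
}

#' Simulate a per-subject covariate table
#'
#' Age, sex, diagnosis (case/control by `case_fraction`), batch labels,
#' two-part cell-type proportions, and three ancestry PCs.
#'
#' @inheritParams simulate_genotypes
#' @param tissue Tissue label used in subject ids.
#' @return A tibble with one row per subject.
#' @export
simulate_covariates <- function(spec, n, tissue = "tissue1",
                                seed = spec$seed) {
  set.seed(seed)
  epi <- runif(n, 0.2, 0.8)
  tibble::tibble(
    subject_id = sprintf("s%04d", seq_len(n)),
    age = round(runif(n, 18, 65)),
    sex = rbinom(n, 1, 0.5),
    diagnosis = as.integer(seq_len(n) <= round(spec$case_fraction * n)),
    batch = paste0("b", 1 + (seq_len(n) - 1) %% spec$n_batches),
    cell_epithelial = epi,
    cell_leukocyte = 1 - epi,
    pc1 = rnorm(n, 0, 0.02), pc2 = rnorm(n, 0, 0.02), pc3 = rnorm(n, 0, 0.02)
  )
}

#' Simulate beta-value methylation with planted cis effects
#'
#' Generates `logit(m) = baseline + effect * dosage (planted pairs active in
#' this tissue) + covariate terms + batch shift + module latent factor +
#' N(0, noise_sd)`, then returns beta values through the inverse logit, which
#' guarantees values in (0, 1). Planted disease modules act through a shared
#' latent factor per subject (mean shifted by `module_effect` in cases) with
#' per-CpG loadings, so module CpGs are co-methylated and case-shifted at
#' once.
#'
#' @param G A [geno_matrix()] for this tissue's subjects.
#' @param truth Truth table from [build_cohort()] / `make_truth`.
#' @param covariates Covariate tibble from [simulate_covariates()].
#' @param spec A [cohort_spec()].
#' @param tissue Tissue label (selects which planted pairs/modules apply).
#' @param seed RNG seed.
#' @param cpg_meta Universe CpG metadata (with `baseline_logit`).
#' @param detect_fail_frac Fraction of entries whose detection p-value is
#'   drawn above 0.05 (simulating failed probes); default 0.
#' @param covariate_effects If `TRUE` (default) small per-CpG age/sex/cell
#'   effects are included.
#' @return A [meth_matrix()] with a `detection_p` channel.
#' @export
simulate_methylation <- function(G, truth, covariates, spec, tissue,
                                 seed = spec$seed, cpg_meta = NULL,
                                 detect_fail_frac = 0,
                                 covariate_effects = TRUE) {
  if (is.null(cpg_meta)) cpg_meta <- simulate_universe(spec)$cpg_meta
  n <- nrow(G$dosage); p <- nrow(cpg_meta)
  set.seed(seed)

  L <- matrix(rep(cpg_meta$baseline_logit, each = n), nrow = n)

  pp <- truth$planted_pairs
  if (nrow(pp)) {
    active <- vapply(pp$tissues, function(ts) tissue %in% ts, logical(1))
    for (k in which(active)) {
      si <- match(pp$snp_id[k], G$snp_meta$snp_id)
      ci <- match(pp$cpg_id[k], cpg_meta$cpg_id)
      if (is.na(si) || is.na(ci)) abort("planted pair references unknown SNP/CpG")
      if (abs(G$snp_meta$pos[si] - cpg_meta$pos[ci]) > spec$cis_window) {
        abort("planted pair violates the cis window")
      }
      L[, ci] <- L[, ci] + pp$effect[k] * G$dosage[, si]
    }
  }

  if (covariate_effects) {
    age_c <- rnorm(p, 0, 0.003); sex_c <- rnorm(p, 0, 0.05)
    cell_c <- rnorm(p, 0, 0.1)
    L <- L + outer(covariates$age - mean(covariates$age), age_c) +
      outer(covariates$sex, sex_c) +
      outer(covariates$cell_epithelial - mean(covariates$cell_epithelial), cell_c)
  }

  if (spec$n_batches > 1 && spec$batch_shift_sd > 0) {
    shifts <- matrix(rnorm(spec$n_batches * p, 0, spec$batch_shift_sd),
                     nrow = spec$n_batches)
    bi <- as.integer(sub("^b", "", covariates$batch))
    L <- L + shifts[bi, , drop = FALSE]
  }

  ml <- truth$module_loadings
  if (nrow(ml)) {
    for (m in unique(ml$module)) {
      if (!(tissue %in% truth$module_tissues[[m]])) next
      rows <- ml[ml$module == m, ]
      latent <- truth$module_effect[m] * covariates$diagnosis + rnorm(n)
      ci <- match(rows$cpg_id, cpg_meta$cpg_id)
      L[, ci] <- L[, ci] + outer(latent, rows$loading)
    }
  }

  if (spec$noise_sd > 0) L <- L + matrix(rnorm(n * p, 0, spec$noise_sd), n, p)

  beta <- inv_logit(L)
  rownames(beta) <- rownames(G$dosage)

  dp <- matrix(runif(n * p, 0, 0.05), n, p)
  if (detect_fail_frac > 0) {
    idx <- which(runif(n * p) < detect_fail_frac)
    dp[idx] <- runif(length(idx), 0.05 + 1e-9, 1)
  }
  meth_matrix(beta, cpg_meta, detection_p = dp)
}

#' Plant an annotation SNP set at a target odds ratio
#'
#' Samples a fixed-size subset of `universe` whose 2x2 association with
#' `meqtl_truth` has expected odds ratio `target_or`. The count falling
#' inside `meqtl_truth` is drawn from Fisher's noncentral hypergeometric
#' distribution with odds `target_or` (so over replicates the realized
#' sample OR concentrates on the target); members are then sampled uniformly
#' within each stratum.
#'
#' @param universe Character vector of all SNP ids.
#' @param meqtl_truth Character vector, the "true meQTL" SNP ids.
#' @param target_or Positive odds ratio (Inf places the whole set inside
#'   `meqtl_truth`).
#' @param size Size of the annotation set.
#' @param seed RNG seed.
#' @return Character vector of annotation SNP ids.
#' @export
plant_annotation_set <- function(universe, meqtl_truth, target_or, size,
                                 seed = 1) {
  if (size > length(universe)) abort("size exceeds the universe")
  if (target_or <= 0) abort("target_or must be positive")
  meqtl_truth <- intersect(meqtl_truth, universe)
  m <- length(meqtl_truth)
  nm <- length(universe) - m
  set.seed(seed)
  a_min <- max(0L, size - nm); a_max <- min(m, size)
  if (a_min > a_max) abort("infeasible target_or / size for this universe")
  if (is.infinite(target_or)) {
    a <- a_max
    if (a < size && nm < size - a) abort("infeasible target_or: not enough SNPs")
  } else {
    a_range <- a_min:a_max
    lw <- lchoose(m, a_range) + lchoose(nm, size - a_range) +
      a_range * log(target_or)
    lw <- lw - max(lw)
    a <- sample(a_range, 1, prob = exp(lw))
  }
  non <- setdiff(universe, meqtl_truth)
  c(
    if (a > 0) sample(meqtl_truth, a) else character(),
    if (size - a > 0) sample(non, size - a) else character()
  )
}

#' Duplicate a SNP in linkage disequilibrium with an existing one
#'
#' Copies a dosage column and, for a random subset of subjects, redraws the
#' value from Binomial(2, p), producing a partner SNP with expected
#' `r^2 = (1 - f)^2` where `f` is the resample fraction. Used to exercise LD
#' pruning; default cohorts are LD-free.
#'
#' @param G A [geno_matrix()].
#' @param snp_id SNP to copy.
#' @param target_r2 Desired squared correlation in (0, 1].
#' @param new_id Id for the partner SNP.
#' @param seed RNG seed.
#' @return A [geno_matrix()] with one extra column placed next to `snp_id`.
#' @export
simulate_ld_partner <- function(G, snp_id, target_r2, new_id = NULL,
                                seed = 1) {
  assert_fraction(target_r2, "target_r2", lo = 1e-9, hi = 1)
  si <- match(snp_id, G$snp_meta$snp_id)
  if (is.na(si)) abort("unknown snp_id")
  set.seed(seed)
  f <- 1 - sqrt(target_r2)
  g <- G$dosage[, si]
  p <- G$snp_meta$maf_pop[si] %||% G$snp_meta$maf[si]
  flip <- runif(length(g)) < f
  g[flip] <- rbinom(sum(flip), 2, p)
  meta <- G$snp_meta[si, ]
  meta$snp_id <- new_id %||% paste0(snp_id, "_ld")
  meta$pos <- meta$pos + 1L
  meta$maf <- min(mean(g) / 2, 1 - mean(g) / 2)
  ord <- order(c(G$snp_meta$pos, meta$pos))
  geno_matrix(cbind(G$dosage, g)[, ord, drop = FALSE],
              dplyr::bind_rows(G$snp_meta, meta)[ord, ])
}

#' Build a complete multi-tissue synthetic cohort
#'
#' Generates the shared SNP/CpG universe, plants cis pairs, modules, and the
#' annotation set, and simulates genotypes, methylation, and covariates for
#' each tissue. Shared planted pairs appear in all tissues with equal effect
#' size and sign; tissue-specific pairs in exactly one tissue. The whole
#' cohort is a deterministic function of the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `tissues` (named list of
#'   `list(geno, meth, covariates)`), `truth` (the truth table), `universe`
#'   (shared `snp_meta` / `cpg_meta`), and `spec`.
#' @export
build_cohort <- function(spec) {
  universe <- simulate_universe(spec)
  truth <- make_truth(spec, universe)
  tissues <- names(spec$n_subjects)
  out <- purrr::imap(setNames(as.list(spec$n_subjects), tissues), function(n, tn) {
    ti <- match(tn, tissues)
    g <- simulate_genotypes(spec, n, seed = derive_seed(spec$seed, 10 + ti),
                            snp_meta = universe$snp_meta)
    cv <- simulate_covariates(spec, n, tissue = tn,
                              seed = derive_seed(spec$seed, 20 + ti))
    m <- simulate_methylation(g, truth, cv, spec, tissue = tn,
                              seed = derive_seed(spec$seed, 30 + ti),
                              cpg_meta = universe$cpg_meta)
    list(geno = g, meth = m, covariates = cv)
  })
  list(tissues = out, truth = truth, universe = universe, spec = spec)
}
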