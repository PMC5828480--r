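#' @importFrom rlang abort warn %||% .data
#' @importFrom stats lm.fit
#' @importFrom stats var cor sd qnorm pnorm qt pt pchisq rnorm runif rbinom
#' @importFrom stats complete.cases model.matrix plogis qlogis setNames rhyper
#' @importFrom stats as.dist cutree hclust prcomp dhyper fisher.test lm coef
#' @importFrom stats quantile median p.adjust
NULL

logit <- stats::qlogis
inv_logit <- stats::plogis

# Derive a stream-specific RNG seed from a master seed; stays below 2^31-1 so
# set.seed() accepts it on 32-bit integer platforms.
derive_seed <- function(seed, offset) {
  ((as.double(seed) %% 1000003) * 8191 + 131071 * offset) %% 2147483647
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    abort(sprintf("`%s` must lie in [%g, %g]", name, lo, hi))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || any(x != floor(x)) || any(x < min)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  invisible(x)
}

# minor-allele frequency from a dosage vector/matrix (coding-allele counts)
empirical_maf <- function(dosage) {
  f <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}
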