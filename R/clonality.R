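#' Cancer cell fraction from read counts, purity, copy number and multiplicity
#'
#' For each mutation record computes the variant allele fraction
#' `vaf = alt / (alt + ref)` and the cancer cell fraction
#' `ccf = vaf * (purity * cn_tumor + (1 - purity) * cn_normal) /
#' (purity * m)`, where `m` is the mutant-allele multiplicity. CCF estimates
#' above 1 are reported as-is with `ccf_capped = TRUE`; the capped value
#' (`pmin(ccf, 1)`) is what the clonality rule consumes.
#'
#' @param muts a `mutation_table` data.frame with columns `alt_reads`,
#'   `ref_reads`, `purity`, `cn_tumor`, `m` and optionally `cn_normal`
#'   (default 2).
#' @return The input with added columns `vaf`, `ccf`, `ccf_capped`.
#' @export
compute_ccf <- function(muts) {
  stopifnot(is.data.frame(muts))
  if (is.null(muts$cn_normal)) muts$cn_normal <- 2L
  with(muts, {
    if (any(alt_reads + ref_reads <= 0)) stop("records need alt + ref > 0")
    if (any(m > cn_tumor)) stop("multiplicity m cannot exceed cn_tumor")
    if (any(m < 1)) stop("multiplicity m must be >= 1")
    if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  })
  muts$vaf <- muts$alt_reads / (muts$alt_reads + muts$ref_reads)
  denom <- muts$purity * muts$cn_tumor + (1 - muts$purity) * muts$cn_normal
  muts$ccf <- muts$vaf * denom / (muts$purity * muts$m)
  muts$ccf_capped <- muts$ccf > 1
  muts
}

#' 95% confidence interval on the cancer cell fraction
#'
#' Puts an exact Clopper-Pearson (beta) 95% interval on the VAF and
#' propagates it through the linear VAF-to-CCF map. Bounds are floored at 0;
#' the upper bound is not capped (the clonality rule compares it to 0.9 on
#' the CCF scale).
#'
#' @param muts output of [compute_ccf()] (or a raw `mutation_table`).
#' @return The input with added columns `ci_low`, `ci_high`.
#' @export
ccf_confidence_interval <- function(muts) {
  if (is.null(muts$ccf)) muts <- compute_ccf(muts)
  alt <- muts$alt_reads
  n <- muts$alt_reads + muts$ref_reads
  # Clopper-Pearson: exact beta interval on the binomial proportion
  vaf_lo <- ifelse(alt == 0, 0, qbeta(0.025, alt, n - alt + 1))
  vaf_hi <- ifelse(alt == n, 1, qbeta(0.975, alt + 1, n - alt))
  denom <- muts$purity * muts$cn_tumor + (1 - muts$purity) * muts$cn_normal
  f <- denom / (muts$purity * muts$m)
  muts$ci_low <- pmax(vaf_lo * f, 0)
  muts$ci_high <- vaf_hi * f
  muts
}

#' Call mutation clonality from CCF and its confidence interval
#'
#' A mutation is CLONAL when its (capped) CCF exceeds 0.8, or exceeds 0.7
#' with the upper 95% bound above 0.9; every other determinable mutation is
#' SUBCLONAL. Records with undeterminable CCF (non-finite) are
#' INDETERMINATE. A simple single-threshold variant (`ccf >= 0.8`, as used
#' for cohort-level summaries) is available via `rule = "threshold"`.
#'
#' @param muts output of [ccf_confidence_interval()].
#' @param rule `"two_branch"` (default) or `"threshold"`.
#' @return The input with an added `clonality` column.
#' @export
call_clonality <- function(muts, rule = c("two_branch", "threshold")) {
  rule <- match.arg(rule)
  if (is.null(muts$ci_high) && rule == "two_branch")
    muts <- ccf_confidence_interval(muts)
  ccf <- pmin(muts$ccf, 1)
  clonal <- switch(rule,
    two_branch = ccf > 0.8 | (ccf > 0.7 & muts$ci_high > 0.9),
    threshold = ccf >= 0.8)
  out <- ifelse(is.finite(ccf), ifelse(clonal, "CLONAL", "SUBCLONAL"),
                "INDETERMINATE")
  muts$clonality <- out
  muts
}

#' Full CCF / clonality pipeline for a mutation table
#'
#' Convenience wrapper: [compute_ccf()], [ccf_confidence_interval()],
#' [call_clonality()].
#'
#' @inheritParams compute_ccf
#' @inheritParams call_clonality
#' @return The annotated mutation table.
#' @export
ccf_calls <- function(muts, rule = c("two_branch", "threshold")) {
  call_clonality(ccf_confidence_interval(compute_ccf(muts)),
                 rule = match.arg(rule))
}
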