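#' Per-site allele fractions at HLA mismatch positions
#'
#' For each mismatched site, computes each allele's read fraction
#' `reads(allele) / (reads(A1) + reads(A2))` in tumor and normal, and
#' summarizes the tumor-versus-normal shift per allele with a two-sided
#' Student t-test across sites. Sites with zero total reads in either tissue
#' are excluded with a warning.
#'
#' @param sites an `hla_site_table` (long format: `site_pos`, `allele`,
#'   `reads_tumor`, `reads_normal`; see [simulate_hla_sites()]).
#' @return A data.frame with columns `site_pos`, `allele`, `vaf_tumor`,
#'   `vaf_normal`; per-allele t-test p-values in the `"comparison_p"`
#'   attribute.
#' @export
site_vaf <- function(sites) {
  w <- .sites_wide(sites)
  tot_t <- w$t_a1 + w$t_a2
  tot_n <- w$n_a1 + w$n_a2
  usable <- tot_t > 0 & tot_n > 0
  if (!all(usable)) {
    warning(sum(!usable), " site(s) with zero coverage excluded")
    w <- w[usable, , drop = FALSE]
    tot_t <- tot_t[usable]
    tot_n <- tot_n[usable]
  }
  out <- rbind(
    data.frame(site_pos = w$site_pos, allele = "A1",
               vaf_tumor = w$t_a1 / tot_t, vaf_normal = w$n_a1 / tot_n),
    data.frame(site_pos = w$site_pos, allele = "A2",
               vaf_tumor = w$t_a2 / tot_t, vaf_normal = w$n_a2 / tot_n))
  out <- out[order(out$site_pos, out$allele), ]
  rownames(out) <- NULL
  cmp <- vapply(c("A1", "A2"), function(a) {
    v <- out[out$allele == a, ]
    .welch_or_tie(v$vaf_tumor, v$vaf_normal, var_equal = TRUE)$p.value
  }, numeric(1))
  attr(out, "comparison_p") <- cmp
  out
}

.sites_wide <- function(sites) {
  stopifnot(is.data.frame(sites))
  a1 <- sites[sites$allele == "A1", ]
  a2 <- sites[sites$allele == "A2", ]
  if (!setequal(a1$site_pos, a2$site_pos))
    stop("both alleles must be present at every site")
  a2 <- a2[match(a1$site_pos, a2$site_pos), ]
  data.frame(site_pos = a1$site_pos,
             t_a1 = a1$reads_tumor, t_a2 = a2$reads_tumor,
             n_a1 = a1$reads_normal, n_a2 = a2$reads_normal)
}

#' Purity-corrected allele-specific copy number at each mismatch site
#'
#' A deliberately simple allelic copy-number estimator (a documented
#' stand-in for a full LOH model with BAF phasing and ploidy re-estimation):
#' at each site the depth-normalized allelic ratio is
#' `r = 0.5 * (tumor allele fraction) / (normal allele fraction)`, i.e. the
#' tumor allele fraction normalized to each sample's site depth and anchored
#' to the heterozygous-normal expectation of one half. Assuming the
#' contaminating normal contributes one copy per allele, the tumor-cell copy
#' number is `cn = (2 * r - (1 - purity)) / purity`, floored at 0 (a
#' `floored` flag marks affected sites). For a balanced diploid tumor r is
#' 1/2 and cn is 1 per allele; a fully lost allele in a pure tumor gives r =
#' 0 and cn = 0.
#'
#' @param sites an `hla_site_table`.
#' @param purity tumor purity in (0, 1\]; defaults to the table's `"purity"`
#'   attribute.
#' @return A data.frame with columns `site_pos`, `allele`, `ratio`, `cn`,
#'   `floored`.
#' @export
estimate_allele_cn <- function(sites, purity = attr(sites, "purity")) {
  if (is.null(purity) || purity <= 0 || purity > 1)
    stop("purity in (0, 1] is required")
  w <- .sites_wide(sites)
  tot_t <- w$t_a1 + w$t_a2
  tot_n <- w$n_a1 + w$n_a2
  usable <- tot_t > 0 & w$n_a1 > 0 & w$n_a2 > 0
  if (!all(usable)) {
    warning(sum(!usable), " site(s) with zero coverage excluded")
    w <- w[usable, , drop = FALSE]
    tot_t <- tot_t[usable]
    tot_n <- tot_n[usable]
  }
  out <- do.call(rbind, lapply(c("A1", "A2"), function(a) {
    ft <- (if (a == "A1") w$t_a1 else w$t_a2) / tot_t
    fn <- (if (a == "A1") w$n_a1 else w$n_a2) / tot_n
    r <- 0.5 * ft / fn
    cn_raw <- (2 * r - (1 - purity)) / purity
    data.frame(site_pos = w$site_pos, allele = a, ratio = r,
               cn = pmax(cn_raw, 0), floored = cn_raw < 0,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$site_pos, out$allele), ]
  rownames(out) <- NULL
  out
}

#' Call allele-specific HLA loss of heterozygosity
#'
#' Computes each allele's median copy number across mismatch sites
#' ([estimate_allele_cn()]) and an allelic-imbalance p-value: a two-sided
#' paired t-test of the per-site `log2(A1/A2)` read ratio in tumor against
#' the matched normal ratio (0.5 pseudocount per allele; `alternative =
#' "wilcoxon"` swaps in a paired Wilcoxon signed-rank test). LOH is called
#' when the smaller median copy number is below 0.5 AND the imbalance
#' p-value is below 0.001; the lost allele is the one with the smaller
#' median.
#'
#' @param sites an `hla_site_table` with at least 5 usable sites.
#' @param purity tumor purity; defaults to the table's attribute.
#' @param test `"t"` (paired t, default) or `"wilcoxon"`.
#' @param cn_threshold,p_threshold the decision rule's thresholds.
#' @return An object of class `loh_call`: list with `allele_cn_median`
#'   (named numeric), `imbalance_p`, `is_loh`, `lost_allele` (`"A1"`,
#'   `"A2"` or `"NONE"`), `n_sites`.
#' @export
call_hla_loh <- function(sites, purity = attr(sites, "purity"),
                         test = c("t", "wilcoxon"), cn_threshold = 0.5,
                         p_threshold = 0.001) {
  test <- match.arg(test)
  cn <- estimate_allele_cn(sites, purity = purity)
  n_sites <- length(unique(cn$site_pos))
  if (n_sites < 5) stop("need at least 5 usable mismatch sites")
  med <- c(A1 = median(cn$cn[cn$allele == "A1"]),
           A2 = median(cn$cn[cn$allele == "A2"]))
  w <- .sites_wide(sites)
  l_t <- log2((w$t_a1 + 0.5) / (w$t_a2 + 0.5))
  l_n <- log2((w$n_a1 + 0.5) / (w$n_a2 + 0.5))
  d <- l_t - l_n
  if (sd(d) == 0) {
    p <- 1  # exact tie across all sites
  } else if (test == "t") {
    p <- t.test(l_t, l_n, paired = TRUE)$p.value
  } else {
    p <- stats::wilcox.test(l_t, l_n, paired = TRUE, exact = FALSE)$p.value
  }
  is_loh <- min(med) < cn_threshold && p < p_threshold
  structure(list(allele_cn_median = med, imbalance_p = p, is_loh = is_loh,
                 lost_allele = if (is_loh) names(which.min(med)) else "NONE",
                 n_sites = n_sites),
            class = "loh_call")
}

#' @export
print.loh_call <- function(x, ...) {
  cat("HLA LOH call\n")
  cat(sprintf("  median allele CN: A1 = %.3f, A2 = %.3f\n",
              x$allele_cn_median["A1"], x$allele_cn_median["A2"]))
  cat(sprintf("  allelic imbalance p = %.3g (%d sites)\n", x$imbalance_p,
              x$n_sites))
  cat(if (x$is_loh) sprintf("  LOH: YES (lost allele %s)\n", x$lost_allele)
      else "  LOH: no\n")
  invisible(x)
}
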