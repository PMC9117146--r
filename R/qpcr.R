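#' Read a qPCR plate table
#'
#' Accepts a long comma-separated table with columns `well_id`, `condition`
#' (`MUT`/`WT`), `ct` and optionally `ct_ref` (a reference/housekeeping gene
#' Ct), and reshapes it to one row per well.
#'
#' @param path CSV file (optionally gzipped).
#' @return A data.frame of class `qpcr_plate` with columns `well_id`,
#'   `ct_mut`, `ct_wt` and, when present, `ct_ref_mut`, `ct_ref_wt`.
#' @export
read_qpcr_plate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "condition", "ct")
  if (length(setdiff(need, names(df))))
    stop("plate file needs columns: ", paste(need, collapse = ", "))
  if (!all(df$condition %in% c("MUT", "WT")))
    stop("condition must be 'MUT' or 'WT'")
  wide <- data.frame(well_id = unique(df$well_id), stringsAsFactors = FALSE)
  pick <- function(cond, col) {
    i <- match(paste(wide$well_id, cond), paste(df$well_id, df$condition))
    df[[col]][i]
  }
  wide$ct_mut <- pick("MUT", "ct")
  wide$ct_wt <- pick("WT", "ct")
  if ("ct_ref" %in% names(df)) {
    wide$ct_ref_mut <- pick("MUT", "ct_ref")
    wide$ct_ref_wt <- pick("WT", "ct_ref")
  }
  class(wide) <- c("qpcr_plate", "data.frame")
  wide
}

#' Compute per-well delta-Ct between matched MUT and WT stimulations
#'
#' Delta-Ct is `ct_wt - ct_mut`, so a positive value means fewer cycles were
#' needed under MUT stimulation, i.e. more IFNG transcript in the
#' MUT-stimulated aliquot (each cycle is roughly a 2-fold difference). With
#' `use_reference = TRUE` each condition's Ct is first normalized to the
#' reference gene (delta-delta-Ct convention):
#' `(ct_wt - ct_ref_wt) - (ct_mut - ct_ref_mut)`.
#'
#' @param plate a `qpcr_plate` (see [read_qpcr_plate()]).
#' @param use_reference normalize to the reference-gene Ct columns first?
#' @return A data.frame with columns `well_id`, `delta_ct`.
#' @export
compute_delta_ct <- function(plate, use_reference = FALSE) {
  stopifnot(is.data.frame(plate))
  bad <- is.na(plate$ct_mut) | is.na(plate$ct_wt)
  if (any(bad))
    stop("missing Ct for well(s): ",
         paste(plate$well_id[bad], collapse = ", "))
  if (any(plate$ct_mut <= 0 | plate$ct_wt <= 0))
    stop("Ct values must be positive")
  delta <- plate$ct_wt - plate$ct_mut
  if (use_reference) {
    if (is.null(plate$ct_ref_mut) || is.null(plate$ct_ref_wt))
      stop("use_reference = TRUE requires ct_ref_mut / ct_ref_wt columns")
    delta <- (plate$ct_wt - plate$ct_ref_wt) -
      (plate$ct_mut - plate$ct_ref_mut)
  }
  data.frame(well_id = plate$well_id, delta_ct = delta,
             stringsAsFactors = FALSE)
}

#' Call screen-positive hit wells from delta-Ct values
#'
#' A well is a hit when its delta-Ct is positive AND at least `k_sd` sample
#' standard deviations above the mean delta-Ct of the table. Mean and sd are
#' computed over all wells by default (the candidate included); with
#' `leave_one_out = TRUE` each well is compared against the mean/sd of the
#' remaining wells. If the sd is zero (all wells identical) no hits are
#' called.
#'
#' @param delta_ct a data.frame from [compute_delta_ct()], or a numeric
#'   vector of delta-Ct values (optionally named by well).
#' @param k_sd number of standard deviations above the mean required.
#' @param leave_one_out exclude the candidate well from the mean/sd?
#' @return A data.frame of class `hit_calls` with columns `well_id`,
#'   `delta_ct`, `mean_delta`, `sd_delta`, `threshold`, `is_hit`.
#' @export
call_hit_wells <- function(delta_ct, k_sd = 2, leave_one_out = FALSE) {
  if (is.data.frame(delta_ct)) {
    wells <- delta_ct$well_id
    x <- delta_ct$delta_ct
  } else {
    x <- as.numeric(delta_ct)
    wells <- if (!is.null(names(delta_ct))) names(delta_ct)
             else sprintf("W%02d", seq_along(x))
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 wells to estimate the plate mean and sd")
  if (leave_one_out) {
    mu <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
    s <- vapply(seq_len(n), function(i) sd(x[-i]), numeric(1))
  } else {
    mu <- rep(mean(x), n)
    s <- rep(sd(x), n)
  }
  thr <- mu + k_sd * s
  is_hit <- s > 0 & x > 0 & x >= thr
  out <- data.frame(well_id = wells, delta_ct = x, mean_delta = mu,
                    sd_delta = s, threshold = thr, is_hit = is_hit,
                    stringsAsFactors = FALSE)
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' @export
print.hit_calls <- function(x, ...) {
  cat(sprintf("qPCR screen: %d wells, %d hit(s)\n", nrow(x), sum(x$is_hit)))
  if (any(x$is_hit))
    cat("  hits:", paste(sprintf("%s (dCt %.2f)", x$well_id[x$is_hit],
                                 x$delta_ct[x$is_hit]), collapse = ", "),
        "\n")
  invisible(x)
}
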