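#' Parse a recognition-motif string
#'
#' Accepts both compact (`"xxxxGWTTK"`) and dashed (`"x-x-x-x-G-W-T-T-K"`)
#' spellings. Lowercase or uppercase `x` marks a wildcard position; any other
#' letter is a fixed residue.
#'
#' @param pattern the motif string.
#' @return An object of class `tcr_motif`: list with `pattern` (compact
#'   string, wildcards as `x`) and `length`.
#' @export
parse_motif <- function(pattern) {
  if (inherits(pattern, "tcr_motif")) return(pattern)
  compact <- gsub("-", "", pattern, fixed = TRUE)
  chars <- strsplit(compact, "")[[1]]
  if (length(chars) == 0) stop("empty motif")
  chars <- ifelse(chars %in% c("x", "X"), "x", toupper(chars))
  ok <- chars == "x" | chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(ok)) stop("invalid motif characters: ",
                     paste(unique(chars[!ok]), collapse = ", "))
  structure(list(pattern = paste(chars, collapse = ""),
                 length = length(chars)),
            class = "tcr_motif")
}

#' Format a motif for display
#'
#' @param x a `tcr_motif` (or a motif string).
#' @param dashed use the `x-x-x-x-G-W-T-T-K` spelling?
#' @return A character scalar.
#' @export
format_motif <- function(x, dashed = FALSE) {
  m <- parse_motif(x)
  if (!dashed) return(m$pattern)
  paste(strsplit(m$pattern, "")[[1]], collapse = "-")
}

#' @export
print.tcr_motif <- function(x, ...) {
  cat("TCR recognition motif:", format_motif(x, dashed = TRUE),
      sprintf("(%d fixed / %d positions)\n",
              sum(strsplit(x$pattern, "")[[1]] != "x"), x$length))
  invisible(x)
}

#' Derive a TCR recognition motif from a substitution scan
#'
#' Turns an alanine/glycine substitution-scan response table into a
#' fixed/wildcard motif over the native peptide. Two derivation rules are
#' exposed because the two natural readings of a "required" position differ:
#'
#' * `"any_detectable"` (default): a position is a wildcard if ANY amenable
#'   substitution retains a detectable response (`>= floor`); positions where
#'   every amenable substitution abolishes function are fixed. This reading
#'   keeps a position flexible whenever substitution permits reactivity
#'   regardless of magnitude.
#' * `"half_loss"`: a position is fixed only if ALL amenable substitutions
#'   lose at least `loss_threshold` (50%) of function, i.e. every response is
#'   `<= 1 - loss_threshold`; otherwise wildcard.
#'
#' Positions with no amenable substitution (native Ala or Gly at an
#' Ala/Gly-scan position) default to wildcard -- absence of evidence of TCR
#' contact -- switchable via `inamenable`.
#'
#' @param scan a `scan_table` (see [simulate_scan_table()]) with columns
#'   `position`, `substitution`, `response`, `amenable`, and the native
#'   peptide as attribute or supplied via `native_peptide`.
#' @param native_peptide native peptide sequence; defaults to the scan
#'   table's `"native_peptide"` attribute.
#' @param rule derivation rule, see above.
#' @param floor detectability floor (fraction-of-maximum units).
#' @param loss_threshold loss-of-function fraction for `"half_loss"`.
#' @param inamenable status inherited by positions with no amenable
#'   substitution.
#' @return A `tcr_motif`.
#' @export
derive_motif <- function(scan, native_peptide = attr(scan, "native_peptide"),
                         rule = c("any_detectable", "half_loss"),
                         floor = 0.10, loss_threshold = 0.50,
                         inamenable = c("wildcard", "fixed")) {
  rule <- match.arg(rule)
  inamenable <- match.arg(inamenable)
  if (is.null(native_peptide)) stop("native peptide is required")
  if (!is.data.frame(scan) || nrow(scan) == 0) stop("empty scan table")
  pep <- strsplit(toupper(native_peptide), "")[[1]]
  L <- length(pep)
  if (any(scan$position < 1 | scan$position > L))
    stop("scan positions outside 1..", L)
  pattern <- character(L)
  for (p in seq_len(L)) {
    rows <- scan[scan$position == p & scan$amenable, , drop = FALSE]
    if (nrow(rows) == 0) {
      pattern[p] <- if (inamenable == "wildcard") "x" else pep[p]
      next
    }
    resp <- rows$response
    wildcard <- switch(rule,
      any_detectable = any(resp >= floor),
      half_loss = !all(resp <= 1 - loss_threshold))
    pattern[p] <- if (wildcard) "x" else pep[p]
  }
  parse_motif(paste(pattern, collapse = ""))
}

#' Scan a protein set for motif matches
#'
#' Tests every length-L window of every sequence: a window matches when each
#' fixed motif position equals the window residue exactly (an ambiguity
#' character `X` in a sequence never matches a fixed position; wildcard
#' positions match anything). Overlapping matches are reported. This is the
#' ScanProsite-style exact-pattern search used to assess TCR
#' cross-reactivity against a proteome.
#'
#' @param motif a `tcr_motif` or motif string.
#' @param proteins a `protein_set` (named character vector of sequences; see
#'   [read_fasta()]).
#' @return A data.frame of class `motif_matches` with columns `protein_id`,
#'   `start` (1-based), `matched_window`, ordered by (protein_id, start).
#' @export
scan_proteins <- function(motif, proteins) {
  m <- parse_motif(motif)
  chars <- strsplit(m$pattern, "")[[1]]
  regex <- paste(ifelse(chars == "x", ".", chars), collapse = "")
  regex <- paste0("(?=", regex, ")")  # lookahead: overlapping matches
  ids <- names(proteins)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(proteins))
  rows <- lapply(order(ids), function(i) {
    s <- toupper(proteins[[i]])
    hits <- gregexpr(regex, s, perl = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    starts <- as.integer(hits)
    starts <- starts[starts + m$length - 1 <= nchar(s)]
    if (length(starts) == 0) return(NULL)
    data.frame(protein_id = ids[i], start = starts,
               matched_window = substring(s, starts, starts + m$length - 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), start = integer(0),
                      matched_window = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_matches", "data.frame")
  out
}
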