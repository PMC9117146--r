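#' Combine per-condition matrices into one labeled experiment
#'
#' Concatenates a MUT-stimulated and a WT-stimulated expression matrix
#' (sharing the same gene set) and attaches the condition labels. Barcodes
#' colliding between the two aliquots are suffixed `-MUT` / `-WT`.
#'
#' @param mut,wt [expr_matrix()] objects with identical gene names.
#' @return An [expr_matrix()] with condition labels.
#' @export
bind_conditions <- function(mut, wt) {
  stopifnot(inherits(mut, "expr_matrix"), inherits(wt, "expr_matrix"))
  if (!identical(mut$gene_names, wt$gene_names))
    stop("gene sets differ between conditions")
  bm <- mut$barcodes
  bw <- wt$barcodes
  if (any(bm %in% bw)) {
    bm <- paste0(bm, "-MUT")
    bw <- paste0(bw, "-WT")
  }
  counts <- cbind(mut$counts, wt$counts)
  colnames(counts) <- c(bm, bw)
  expr_matrix(counts, condition = rep(c("MUT", "WT"),
                                      c(ncol(mut$counts), ncol(wt$counts))))
}

#' Library-size normalize and log-transform counts
#'
#' Scales each cell to `scale` total counts and applies `log(1 + x)`.
#' Sparsity is preserved (zeros map to zero). Cells with zero total counts
#' must be removed upstream (see [filter_cells()]).
#'
#' @param x an [expr_matrix()].
#' @param scale target library size (counts per cell) before the log.
#' @return An object of class `norm_matrix`: like `expr_matrix` but with a
#'   dense numeric `norm` matrix in place of counts.
#' @export
normalize_counts <- function(x, scale = 10000) {
  stopifnot(inherits(x, "expr_matrix"))
  lib <- colSums(x$counts)
  if (any(lib == 0)) stop("zero-total-count cells must be removed before normalization")
  norm <- log1p(sweep(x$counts, 2, lib / scale, "/"))
  structure(list(norm = norm, gene_names = x$gene_names,
                 barcodes = x$barcodes, condition = x$condition,
                 scale = scale),
            class = "norm_matrix")
}

.cell_clonotype_map <- function(vdj) {
  u <- unique(vdj[, c("barcode", "clonotype_id")])
  if (anyDuplicated(u$barcode))
    stop("a barcode maps to more than one clonotype id")
  setNames(u$clonotype_id, u$barcode)
}

#' Per-clonotype normalized target-gene expression, split by condition
#'
#' With `scale = "linear"` expression is returned on the linear
#' library-normalized scale (counts per library-size unit, i.e. `expm1` of
#' the log-normalized matrix): the clonotype response statistic is a ratio
#' of transcript abundances, so its means live on the count scale. With
#' `scale = "log"` the log-normalized values are returned, the
#' variance-stabilized scale on which the per-clonotype t-tests run.
#'
#' @param x a `norm_matrix` with condition labels.
#' @param vdj a `vdj_table` assigning barcodes to clonotypes.
#' @param gene target gene (default IFNG).
#' @param scale `"linear"` or `"log"`.
#' @return A named list (one element per clonotype) of lists with numeric
#'   vectors `MUT` and `WT` of per-cell normalized expression.
#' @export
target_expression_by_clonotype <- function(x, vdj, gene = "IFNG",
                                           scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(x, "norm_matrix"))
  if (!gene %in% x$gene_names) stop("target gene '", gene, "' not in matrix")
  if (is.null(x$condition)) stop("matrix has no condition labels")
  map <- .cell_clonotype_map(vdj)
  assigned <- x$barcodes %in% names(map)
  cl <- map[x$barcodes[assigned]]
  expr <- x$norm[gene, assigned]
  if (scale == "linear") expr <- expm1(expr)
  cond <- x$condition[assigned]
  out <- lapply(split(seq_along(cl), cl), function(i)
    list(MUT = unname(expr[i][cond[i] == "MUT"]),
         WT = unname(expr[i][cond[i] == "WT"])))
  out
}

#' Per-clonotype MUT/WT response table
#'
#' For every clonotype, computes cell counts per condition, repertoire
#' frequency, and the pseudocounted log2 ratio of mean normalized target
#' expression between MUT- and WT-stimulated cells:
#' `log2((mean_mut + eps) / (mean_wt + eps))`. Means are taken on the linear
#' library-normalized scale (see [target_expression_by_clonotype()]), so the
#' ratio estimates the fold change in target transcripts between the two
#' stimulations. A clonotype is "evaluable"
#' when it has at least `min_cells` cells in each condition; non-evaluable
#' clonotypes are kept in the table with `log2_ratio = NA`.
#'
#' @param x a `norm_matrix` with condition labels.
#' @param vdj a `vdj_table`.
#' @param target_gene gene whose induction is scored (default `"IFNG"`).
#' @param pseudocount eps added to both means on the normalized scale.
#' @param min_cells evaluability minimum per condition.
#' @return A data.frame of class `clonotype_response` with columns
#'   `clonotype_id`, `n_cells_mut`, `n_cells_wt`, `frequency`,
#'   `mean_target_mut`, `mean_target_wt`, `log2_ratio`, `evaluable`.
#' @export
clonotype_response_table <- function(x, vdj, target_gene = "IFNG",
                                     pseudocount = 0.1, min_cells = 3) {
  split_expr <- target_expression_by_clonotype(x, vdj, target_gene)
  n_assigned <- sum(vapply(split_expr, function(e)
    length(e$MUT) + length(e$WT), numeric(1)))
  rows <- lapply(names(split_expr), function(id) {
    e <- split_expr[[id]]
    n_mut <- length(e$MUT)
    n_wt <- length(e$WT)
    ev <- n_mut >= min_cells && n_wt >= min_cells
    m_mut <- if (n_mut) mean(e$MUT) else NA_real_
    m_wt <- if (n_wt) mean(e$WT) else NA_real_
    data.frame(clonotype_id = id, n_cells_mut = n_mut, n_cells_wt = n_wt,
               frequency = (n_mut + n_wt) / n_assigned,
               mean_target_mut = m_mut, mean_target_wt = m_wt,
               log2_ratio = if (ev)
                 log2((m_mut + pseudocount) / (m_wt + pseudocount))
               else NA_real_,
               evaluable = ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$frequency, out$clonotype_id), ]
  rownames(out) <- NULL
  attr(out, "target_gene") <- target_gene
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("clonotype_response", "data.frame")
  out
}

.welch_or_tie <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    return(list(p.value = NA_real_, statistic = NA_real_))
  # exact-tie handling: two constant groups give p = 1 when equal, 0 when not
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0,
                statistic = NA_real_))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(p.value = ht$p.value, statistic = unname(ht$statistic))
}

#' Test candidate clonotypes for mutant-specific induction
#'
#' Clonotypes whose fold ratio (`2^log2_ratio`) is at least
#' `ratio_threshold` are tested with a two-sided Welch (unequal-variance)
#' t-test comparing per-cell normalized target expression between the
#' clonotype's MUT and WT cells. A clonotype is a candidate when it was
#' tested and `p < alpha`. Untested clonotypes keep `p_value = NA`.
#'
#' The gate uses the fold ratio of linear-scale means (the response table);
#' the t-test is run on whatever per-cell values are supplied -- the
#' log-normalized scale by convention (see [sift()]), where the t-test is
#' better calibrated.
#'
#' @param responses a `clonotype_response` table.
#' @param target_expression per-clonotype split expression, from
#'   [target_expression_by_clonotype()] (log scale by convention).
#' @param ratio_threshold minimal fold ratio gating the test (the Fig.-1b
#'   style dashed line; 2 means log2 ratio >= 1).
#' @param alpha significance level for candidacy.
#' @return The `responses` table with added columns `p_value`, `tested`,
#'   `is_candidate`.
#' @export
test_candidates <- function(responses, target_expression,
                            ratio_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(responses, "clonotype_response"))
  p <- rep(NA_real_, nrow(responses))
  tested <- logical(nrow(responses))
  for (i in seq_len(nrow(responses))) {
    r <- responses[i, ]
    if (!r$evaluable || is.na(r$log2_ratio)) next
    if (2^r$log2_ratio < ratio_threshold) next
    e <- target_expression[[r$clonotype_id]]
    tested[i] <- TRUE
    p[i] <- .welch_or_tie(e$MUT, e$WT)$p.value
  }
  responses$p_value <- p
  responses$tested <- tested
  responses$is_candidate <- tested & !is.na(p) & p < alpha
  responses
}

#' Predict the HLA class restriction of a clonotype from lineage markers
#'
#' Requires the pan-T marker (CD3E) to be detected (> 0) in at least half of
#' the clonotype's cells; otherwise the call is INDETERMINATE. Then compares
#' per-cell normalized CD8A versus CD4 expression with a two-sided Student
#' t-test: CLASS_I when CD8A dominates significantly (CD8 lineage implies
#' HLA class I restriction), CLASS_II when CD4 dominates, INDETERMINATE
#' otherwise.
#'
#' @param x a `norm_matrix`.
#' @param cells barcodes of the clonotype's cells.
#' @param cd8_gene,cd4_gene,cd3_gene marker gene names.
#' @param alpha significance level.
#' @return A list with `call` (`"CLASS_I"`, `"CLASS_II"`,
#'   `"INDETERMINATE"`) and `p` (the lineage-test p-value, `NA` when gated
#'   out).
#' @export
predict_hla_class <- function(x, cells, cd8_gene = "CD8A", cd4_gene = "CD4",
                              cd3_gene = "CD3E", alpha = 0.05) {
  stopifnot(inherits(x, "norm_matrix"))
  idx <- match(cells, x$barcodes)
  if (anyNA(idx)) stop("unknown barcodes in 'cells'")
  # a marker removed by the min-cells gene filter was (near-)undetected:
  # treat it as zero expression rather than failing
  marker <- function(g) {
    if (g %in% x$gene_names) x$norm[g, idx] else rep(0, length(idx))
  }
  cd3 <- marker(cd3_gene)
  if (mean(cd3 > 0) < 0.5)
    return(list(call = "INDETERMINATE", p = NA_real_))
  cd8 <- marker(cd8_gene)
  cd4 <- marker(cd4_gene)
  ht <- .welch_or_tie(cd8, cd4, var_equal = TRUE)
  call <- if (ht$p.value < alpha && mean(cd8) > mean(cd4)) "CLASS_I"
          else if (ht$p.value < alpha && mean(cd4) > mean(cd8)) "CLASS_II"
          else "INDETERMINATE"
  list(call = call, p = ht$p.value)
}

# row-wise Welch t-test between two column subsets of a matrix
.rowwise_welch <- function(mat, i1, i2) {
  n1 <- length(i1)
  n2 <- length(i2)
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  # degenerate rows: both groups constant
  flat <- se2 == 0
  p[flat] <- ifelse(abs(m1[flat] - m2[flat]) < 1e-12, 1, 0)
  t[flat] <- NA_real_
  list(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' Per-gene differential expression within one clonotype (MUT vs WT)
#'
#' Computes, for every gene, the pseudocounted log2 fold change of mean
#' normalized expression and a two-sided Welch t-test p-value between the
#' clonotype's MUT- and WT-stimulated cells, with Benjamini-Hochberg
#' adjustment across tested genes. Genes with zero expression in both
#' conditions are reported untested. Genes are flagged `"up"`/`"down"` when
#' `|log2_fc| >= fc_threshold` and `adjusted_p < alpha` (the volcano-plot
#' thresholds).
#'
#' @param x a `norm_matrix` with condition labels, or a `sift` fit.
#' @param vdj a `vdj_table` (ignored when `x` is a `sift` fit).
#' @param clonotype_id the clonotype to test.
#' @param fc_threshold absolute log2 fold-change threshold.
#' @param alpha adjusted-p significance threshold.
#' @param pseudocount eps for the fold change.
#' @return A data.frame of class `sift_de` with columns `gene`, `log2_fc`,
#'   `p_value`, `adjusted_p`, `tested`, `direction`.
#' @export
clonotype_de <- function(x, vdj = NULL, clonotype_id, fc_threshold = 1,
                         alpha = 0.05, pseudocount = 0.1) {
  if (inherits(x, "sift")) {
    vdj <- x$vdj
    x <- x$norm
  }
  stopifnot(inherits(x, "norm_matrix"))
  map <- .cell_clonotype_map(vdj)
  cells <- names(map)[map == clonotype_id]
  idx <- match(intersect(cells, x$barcodes), x$barcodes)
  if (length(idx) == 0) stop("clonotype '", clonotype_id, "' not found")
  i1 <- idx[x$condition[idx] == "MUT"]
  i2 <- idx[x$condition[idx] == "WT"]
  if (length(i1) < 2 || length(i2) < 2)
    stop("clonotype must have at least 2 cells in each condition")
  sub <- x$norm[, c(i1, i2), drop = FALSE]
  expressed <- rowSums(sub) > 0
  w <- .rowwise_welch(x$norm, i1, i2)
  # fold changes on the linear normalized scale; p-values on the
  # variance-stabilized log scale
  m1_lin <- rowMeans(expm1(x$norm[, i1, drop = FALSE]))
  m2_lin <- rowMeans(expm1(x$norm[, i2, drop = FALSE]))
  log2_fc <- log2((m1_lin + pseudocount) / (m2_lin + pseudocount))
  p <- ifelse(expressed, w$p, NA_real_)
  adj <- rep(NA_real_, length(p))
  adj[expressed] <- p.adjust(p[expressed], method = "BH")
  direction <- rep("none", length(p))
  sig <- expressed & !is.na(adj) & adj < alpha & abs(log2_fc) >= fc_threshold
  direction[sig & log2_fc > 0] <- "up"
  direction[sig & log2_fc < 0] <- "down"
  out <- data.frame(gene = x$gene_names, log2_fc = log2_fc, p_value = p,
                    adjusted_p = adj, tested = expressed,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "clonotype_id") <- clonotype_id
  class(out) <- c("sift_de", "data.frame")
  out
}

#' Retrieve the consensus paired TCR of a clonotype
#'
#' Returns the most frequent TRA and TRB chain records (V gene, J gene, CDR3
#' amino acid and nucleotide sequences) among the clonotype's cells. A
#' clonotype whose cells carry more than one TRA (or TRB) variant is flagged
#' ambiguous; a clonotype lacking a TRB entirely is flagged missing-chain.
#'
#' @param vdj a `vdj_table`.
#' @param clonotype_id clonotype to retrieve.
#' @return A list of class `tcr_report` with elements `clonotype_id`, `TRA`,
#'   `TRB` (one-row data.frames or `NULL`), `n_cells`, `ambiguous_tra`,
#'   `ambiguous_trb`, `dual_tra`, `missing_chain`.
#' @export
retrieve_tcr <- function(vdj, clonotype_id) {
  rows <- vdj[vdj$clonotype_id == clonotype_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("clonotype '", clonotype_id, "' not found")
  consensus <- function(chain) {
    ch <- rows[rows$chain == chain, , drop = FALSE]
    if (nrow(ch) == 0) return(list(rec = NULL, ambiguous = FALSE))
    key <- paste(ch$v_gene, ch$j_gene, ch$cdr3_aa, ch$cdr3_nt, sep = "|")
    tab <- sort(table(key), decreasing = TRUE)
    best <- ch[match(names(tab)[1], key), c("chain", "v_gene", "j_gene",
                                            "cdr3_aa", "cdr3_nt")]
    rownames(best) <- NULL
    list(rec = best, ambiguous = length(tab) > 1)
  }
  tra <- consensus("TRA")
  trb <- consensus("TRB")
  n_tra_per_cell <- table(rows$barcode[rows$chain == "TRA"])
  structure(list(clonotype_id = clonotype_id,
                 TRA = tra$rec, TRB = trb$rec,
                 n_cells = length(unique(rows$barcode)),
                 ambiguous_tra = tra$ambiguous,
                 ambiguous_trb = trb$ambiguous,
                 dual_tra = any(n_tra_per_cell >= 2),
                 missing_chain = is.null(tra$rec) || is.null(trb$rec)),
            class = "tcr_report")
}

#' @export
print.tcr_report <- function(x, ...) {
  cat("TCR report for", x$clonotype_id,
      sprintf("(%d cells)\n", x$n_cells))
  for (ch in c("TRA", "TRB")) {
    r <- x[[ch]]
    if (is.null(r)) cat(sprintf("  %s: missing\n", ch))
    else cat(sprintf("  %s: %s / %s  CDR3 %s\n", ch, r$v_gene, r$j_gene,
                     r$cdr3_aa))
  }
  if (x$ambiguous_tra) cat("  note: multiple TRA variants (majority shown)\n")
  if (x$ambiguous_trb) cat("  note: multiple TRB variants (majority shown)\n")
  if (x$dual_tra) cat("  note: cell(s) with two TRA chains\n")
  invisible(x)
}

#' Fit the SIFT-seq clonotype reactivity analysis
#'
#' The central analysis: starting from a QC-filtered (or raw, with
#' `qc = TRUE`) paired MUT/WT expression matrix and its V(D)J table,
#' normalizes counts, builds the per-clonotype target-gene (IFNG) response
#' table, gates clonotypes at the fold-ratio threshold, tests gated
#' clonotypes with a two-sided Welch t-test, and predicts each evaluable
#' clonotype's HLA class restriction from lineage markers.
#'
#' @param x an [expr_matrix()] with condition labels.
#' @param vdj a `vdj_table`.
#' @param target_gene activation readout gene.
#' @param ratio_threshold minimal MUT/WT fold ratio for testing.
#' @param alpha significance level for candidacy and lineage calls.
#' @param pseudocount eps of the log2 ratio.
#' @param min_cells evaluability minimum per condition.
#' @param scale normalization library size.
#' @param qc run [run_qc()] first? (set `FALSE` if already filtered).
#' @param ... further arguments to [run_qc()].
#' @return An object of class `sift`: list with `responses` (the annotated
#'   `clonotype_response` table, including `lineage_call` and `lineage_p`),
#'   `norm`, `vdj`, `qc_report`, `params`.
#' @seealso [clonotype_de()], [retrieve_tcr()], [plot.sift()]
#' @export
sift <- function(x, vdj, target_gene = "IFNG", ratio_threshold = 2,
                 alpha = 0.05, pseudocount = 0.1, min_cells = 3,
                 scale = 10000, qc = TRUE, ...) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$condition)) stop("matrix needs MUT/WT condition labels")
  qc_report <- NULL
  if (qc) {
    q <- run_qc(x, vdj, ...)
    x <- q$matrix
    vdj <- q$vdj
    qc_report <- q$report
  }
  norm <- normalize_counts(x, scale = scale)
  split_log <- target_expression_by_clonotype(norm, vdj, target_gene,
                                              scale = "log")
  responses <- clonotype_response_table(norm, vdj, target_gene = target_gene,
                                        pseudocount = pseudocount,
                                        min_cells = min_cells)
  responses <- test_candidates(responses, split_log,
                               ratio_threshold = ratio_threshold,
                               alpha = alpha)
  map <- .cell_clonotype_map(vdj)
  lineage_call <- character(nrow(responses))
  lineage_p <- rep(NA_real_, nrow(responses))
  for (i in seq_len(nrow(responses))) {
    if (!responses$evaluable[i]) {
      lineage_call[i] <- "INDETERMINATE"
      next
    }
    cells <- intersect(names(map)[map == responses$clonotype_id[i]],
                       norm$barcodes)
    lp <- predict_hla_class(norm, cells, alpha = alpha)
    lineage_call[i] <- lp$call
    lineage_p[i] <- lp$p
  }
  responses$lineage_call <- lineage_call
  responses$lineage_p <- lineage_p
  structure(list(responses = responses, norm = norm, vdj = vdj,
                 qc_report = qc_report,
                 params = list(target_gene = target_gene,
                               ratio_threshold = ratio_threshold,
                               alpha = alpha, pseudocount = pseudocount,
                               min_cells = min_cells, scale = scale)),
            class = "sift")
}

#' @export
print.sift <- function(x, ...) {
  r <- x$responses
  cat(sprintf("SIFT-seq fit: %d clonotypes (%d evaluable, %d tested)\n",
              nrow(r), sum(r$evaluable), sum(r$tested)))
  cand <- r[r$is_candidate, , drop = FALSE]
  if (nrow(cand) == 0) {
    cat("  no candidate clonotypes at alpha =", x$params$alpha, "\n")
  } else {
    cat(sprintf("  %d candidate clonotype(s):\n", nrow(cand)))
    for (i in seq_len(nrow(cand)))
      cat(sprintf("    %s  log2 %s ratio = %.2f, p = %.3g, lineage %s\n",
                  cand$clonotype_id[i], x$params$target_gene,
                  cand$log2_ratio[i], cand$p_value[i],
                  cand$lineage_call[i]))
  }
  invisible(x)
}

#' @export
summary.sift <- function(object, ...) {
  r <- object$responses
  out <- list(
    n_clonotypes = nrow(r),
    n_evaluable = sum(r$evaluable),
    n_tested = sum(r$tested),
    n_candidates = sum(r$is_candidate),
    candidates = r[r$is_candidate, , drop = FALSE],
    mean_log2_ratio = mean(r$log2_ratio, na.rm = TRUE),
    params = object$params)
  class(out) <- "summary.sift"
  out
}

#' @export
print.summary.sift <- function(x, ...) {
  cat("SIFT-seq summary\n")
  cat(sprintf("  clonotypes: %d; evaluable: %d; tested: %d; candidates: %d\n",
              x$n_clonotypes, x$n_evaluable, x$n_tested, x$n_candidates))
  cat(sprintf("  mean log2 ratio (evaluable): %.3f\n", x$mean_log2_ratio))
  if (nrow(x$candidates))
    print(x$candidates[, c("clonotype_id", "n_cells_mut", "n_cells_wt",
                           "log2_ratio", "p_value", "lineage_call")])
  invisible(x)
}

#' Clonotype response plot (frequency vs log2 ratio)
#'
#' Scatter of each evaluable clonotype's repertoire frequency against its
#' log2 MUT/WT target-gene ratio, with the fold-ratio testing threshold as a
#' dashed line and candidates highlighted.
#'
#' @param x a `sift` fit.
#' @param ... passed to [plot()].
#' @export
plot.sift <- function(x, ...) {
  r <- x$responses[x$responses$evaluable, , drop = FALSE]
  plot(r$frequency, r$log2_ratio,
       xlab = "clonotype frequency",
       ylab = sprintf("log2 %s ratio (MUT/WT)", x$params$target_gene),
       pch = 19, col = ifelse(r$is_candidate, "firebrick", "grey40"),
       log = "x", ...)
  abline(h = log2(x$params$ratio_threshold), lty = 2)
  if (any(r$is_candidate))
    text(r$frequency[r$is_candidate], r$log2_ratio[r$is_candidate],
         labels = r$clonotype_id[r$is_candidate], pos = 3, cex = 0.8)
  invisible(x)
}
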