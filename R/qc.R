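#' Remove genes detected in too few cells
#'
#' Drops genes with non-zero counts in fewer than `min_cells` cells (a gene
#' seen in exactly `min_cells` cells is retained). The cell set is unchanged.
#'
#' @param x an [expr_matrix()].
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return The filtered [expr_matrix()]; genes removed recorded in the
#'   `"genes_removed"` attribute.
#' @export
filter_genes_min_cells <- function(x, min_cells = 3) {
  stopifnot(inherits(x, "expr_matrix"))
  detected <- rowSums(x$counts > 0)
  keep <- detected >= min_cells
  if (!any(keep)) stop("all genes removed by the min-cells filter")
  out <- expr_matrix(x$counts[keep, , drop = FALSE], condition = x$condition)
  attr(out, "genes_removed") <- sum(!keep)
  out
}

#' Remove low-quality cells
#'
#' Applies, in order, the three per-cell removal rules of the standard
#' droplet QC: (1) fewer than `min_genes` detected genes; (2) mitochondrial
#' count fraction strictly greater than `max_mito` (mitochondrial genes are
#' those whose name starts with `mito_prefix`, case-insensitive); (3) more
#' than `max_genes` detected genes (a doublet/multiplet proxy). Boundary
#' cells (exactly `min_genes` detected, mito fraction exactly `max_mito`) are
#' retained. Each removed cell is attributed to the first rule that removes
#' it. Cells with zero total counts are removed under rule 1 with a warning
#' (their mito fraction is undefined).
#'
#' @param x an [expr_matrix()].
#' @param min_genes minimum detected genes.
#' @param max_mito maximum mitochondrial count fraction.
#' @param max_genes maximum detected genes.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return A list with `matrix` (filtered [expr_matrix()]) and `report` (a
#'   `qc_report`).
#' @export
filter_cells <- function(x, min_genes = 200, max_mito = 0.15,
                         max_genes = 7000, mito_prefix = "MT-") {
  stopifnot(inherits(x, "expr_matrix"))
  counts <- x$counts
  detected <- colSums(counts > 0)
  total <- colSums(counts)
  if (any(total == 0))
    warning(sum(total == 0),
            " cell(s) with zero total counts removed under the min-genes rule")
  mt <- grepl(paste0("^", mito_prefix), rownames(counts), ignore.case = TRUE)
  mito_frac <- ifelse(total > 0, colSums(counts[mt, , drop = FALSE]) / total,
                      NA_real_)
  rule1 <- detected < min_genes
  rule2 <- !rule1 & !is.na(mito_frac) & mito_frac > max_mito
  rule3 <- !rule1 & !rule2 & detected > max_genes
  keep <- !(rule1 | rule2 | rule3)
  report <- new_qc_report(
    n_cells_in = ncol(counts),
    removed = c(min_genes = sum(rule1), max_mito = sum(rule2),
                max_genes = sum(rule3)),
    retained = sum(keep),
    keep = setNames(keep, colnames(counts)))
  cond <- if (!is.null(x$condition)) x$condition[keep] else NULL
  list(matrix = expr_matrix(counts[, keep, drop = FALSE], condition = cond),
       report = report)
}

#' Restrict to cells with usable clonotype information
#'
#' Removes cells without any V(D)J record, and cells with more than `max_tra`
#' TRA or more than `max_trb` TRB contigs (likely multiplets); a cell with
#' exactly two TRA chains is retained. The V(D)J table is restricted to the
#' retained cells.
#'
#' @param x an [expr_matrix()].
#' @param vdj a `vdj_table` (see [read_contig_annotations()]).
#' @param max_tra,max_trb maximum allowed chain records per cell.
#' @return A list with `matrix`, `vdj` and `report` (a `qc_report`).
#' @export
filter_vdj_cells <- function(x, vdj, max_tra = 2, max_trb = 2) {
  stopifnot(inherits(x, "expr_matrix"), is.data.frame(vdj))
  cells <- x$barcodes
  if (!any(cells %in% vdj$barcode))
    stop("no overlap between matrix barcodes and V(D)J barcodes")
  n_tra <- table(factor(vdj$barcode[vdj$chain == "TRA"], levels = cells))
  n_trb <- table(factor(vdj$barcode[vdj$chain == "TRB"], levels = cells))
  has_vdj <- cells %in% vdj$barcode
  multi <- has_vdj & (as.vector(n_tra) > max_tra | as.vector(n_trb) > max_trb)
  keep <- has_vdj & !multi
  report <- new_qc_report(
    n_cells_in = length(cells),
    removed = c(no_clonotype = sum(!has_vdj), multi_chain = sum(multi)),
    retained = sum(keep),
    keep = setNames(keep, cells))
  cond <- if (!is.null(x$condition)) x$condition[keep] else NULL
  vdj_out <- vdj[vdj$barcode %in% cells[keep], , drop = FALSE]
  rownames(vdj_out) <- NULL
  list(matrix = expr_matrix(x$counts[, keep, drop = FALSE], condition = cond),
       vdj = vdj_out, report = report)
}

new_qc_report <- function(n_cells_in, removed, retained, keep,
                          genes_removed = NA_integer_) {
  stopifnot(sum(removed) + retained == n_cells_in)
  structure(list(n_cells_in = n_cells_in, removed = removed,
                 retained = retained, keep = keep,
                 genes_removed = genes_removed),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  if (!is.na(x$genes_removed))
    cat(sprintf("  genes removed (min-cells): %d\n", x$genes_removed))
  cat(sprintf("  cells in: %d\n", x$n_cells_in))
  for (r in names(x$removed))
    cat(sprintf("  removed (%s): %d\n", r, x$removed[[r]]))
  cat(sprintf("  cells retained: %d\n", x$retained))
  invisible(x)
}

#' Run the full quality-control cascade
#'
#' Applies, in this fixed order, the gene filter
#' ([filter_genes_min_cells()]), the cell filters ([filter_cells()]) and the
#' V(D)J filters ([filter_vdj_cells()]). The order matters for attribution:
#' each removed cell is counted under the first rule that removes it.
#' Because removing cells can push further genes below the min-cells rule
#' (and, rarely, gene removal can push cells below the min-genes rule), the
#' cascade is repeated until no gene or cell is removed, making the full QC
#' idempotent; removal counts accumulate across passes under the rule that
#' fired.
#'
#' @param x an [expr_matrix()].
#' @param vdj a `vdj_table`.
#' @param min_cells,min_genes,max_mito,max_genes,mito_prefix,max_tra,max_trb
#'   thresholds passed to the individual filters.
#' @return A list with `matrix`, `vdj` and `report` (a combined `qc_report`
#'   with per-rule removal counts `min_genes`, `max_mito`, `max_genes`,
#'   `no_clonotype`, `multi_chain`).
#' @export
run_qc <- function(x, vdj, min_cells = 3, min_genes = 200, max_mito = 0.15,
                   max_genes = 7000, mito_prefix = "MT-", max_tra = 2,
                   max_trb = 2) {
  removed <- c(min_genes = 0, max_mito = 0, max_genes = 0,
               no_clonotype = 0, multi_chain = 0)
  genes_removed <- 0
  cur <- x
  cur_vdj <- vdj
  repeat {
    g <- filter_genes_min_cells(cur, min_cells = min_cells)
    genes_removed <- genes_removed + attr(g, "genes_removed")
    c1 <- filter_cells(g, min_genes = min_genes, max_mito = max_mito,
                       max_genes = max_genes, mito_prefix = mito_prefix)
    c2 <- filter_vdj_cells(c1$matrix, cur_vdj, max_tra = max_tra,
                           max_trb = max_trb)
    removed <- removed + c(c1$report$removed, c2$report$removed)
    stable <- attr(g, "genes_removed") == 0 &&
      sum(c1$report$removed) + sum(c2$report$removed) == 0
    cur <- c2$matrix
    cur_vdj <- c2$vdj
    if (stable) break
  }
  report <- new_qc_report(
    n_cells_in = ncol(x$counts),
    removed = removed,
    retained = ncol(cur$counts),
    keep = setNames(x$barcodes %in% cur$barcodes, x$barcodes),
    genes_removed = genes_removed)
  list(matrix = cur, vdj = cur_vdj, report = report)
}
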