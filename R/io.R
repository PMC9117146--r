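#' Expression matrix container
#'
#' A genes x cells matrix of non-negative integer UMI counts with unique gene
#' names (rows), unique cell barcodes (columns) and an optional per-cell
#' stimulation condition label (`"MUT"` or `"WT"`).
#'
#' @param counts integer matrix, genes x cells, with rownames (gene names)
#'   and colnames (barcodes).
#' @param condition optional character vector of per-cell labels in
#'   `c("MUT", "WT")`, recycled names not allowed; length must equal
#'   `ncol(counts)`.
#' @return An object of class `expr_matrix`: a list with elements `counts`,
#'   `gene_names`, `barcodes`, `condition`.
#' @export
expr_matrix <- function(counts, condition = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene names (rownames) and barcodes (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("gene names must be unique")
  if (anyDuplicated(colnames(counts)))
    stop("cell barcodes must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != ncol(counts))
      stop("condition must have one label per cell")
    if (!all(condition %in% c("MUT", "WT")))
      stop("condition labels must be 'MUT' or 'WT'")
  }
  structure(
    list(counts = counts, gene_names = rownames(counts),
         barcodes = colnames(counts), condition = condition),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$condition)) {
    tab <- table(x$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.read_first_column <- function(path) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a 10x-style count matrix triplet
#'
#' Loads a Matrix Market count matrix together with its features and barcodes
#' sidecar files (one entry per line; extra tab-separated columns beyond the
#' first are ignored). The on-disk orientation is auto-detected from the
#' header dimensions: whichever axis length matches the number of features is
#' taken as the gene axis, so genes x cells and cells x genes deposits both
#' load correctly. All inputs may be gzip-compressed.
#'
#' @param matrix_path path to the Matrix Market (.mtx or .mtx.gz) file.
#' @param features_path path to the features/genes file.
#' @param barcodes_path path to the barcodes file.
#' @return An [expr_matrix()] (genes x cells).
#' @export
read_counts_matrix <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- .read_first_column(features_path)
  cells <- .read_first_column(barcodes_path)
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    # genes x cells on disk
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "matrix dimensions %d x %d match neither %d features x %d barcodes nor its transpose",
      nrow(m), ncol(m), length(genes), length(cells)))
  }
  if (anyDuplicated(cells)) stop("duplicate barcodes in barcodes file")
  if (anyDuplicated(genes)) stop("duplicate gene names in features file")
  counts <- as.matrix(m)
  dimnames(counts) <- list(genes, cells)
  expr_matrix(counts)
}

#' Write an expression matrix as a 10x-style triplet
#'
#' Inverse of [read_counts_matrix()]: writes `matrix.mtx`, `features.tsv` and
#' `barcodes.tsv` under `dir`.
#'
#' @param x an [expr_matrix()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_counts_matrix <- function(x, dir) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), paths[1])
  writeLines(x$gene_names, paths[2])
  writeLines(x$barcodes, paths[3])
  invisible(paths)
}

#' Read 10x filtered contig annotations
#'
#' Parses a comma-separated filtered-contig table into a V(D)J table. Both
#' the `cdr3`/`cdr3_nt` and `cdr3_aa`/`cdr3_nt` header dialects are accepted.
#' Rows whose chain is not TRA/TRB, or whose CDR3 is missing (`"None"` or
#' empty), are dropped; the number dropped per reason is recorded in the
#' `"dropped"` attribute. Unrecognized columns are ignored (and listed in the
#' `"extra_columns"` attribute) rather than rejected.
#'
#' @param path path to a contig annotation CSV (optionally gzipped).
#' @return A data.frame of class `vdj_table` with columns `barcode`, `chain`,
#'   `v_gene`, `j_gene`, `cdr3_aa`, `cdr3_nt`, `clonotype_id`.
#' @export
read_contig_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cdr3_col <- intersect(c("cdr3", "cdr3_aa"), names(df))[1]
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt",
                "raw_clonotype_id")
  missing <- setdiff(required, names(df))
  if (is.na(cdr3_col)) missing <- c(missing, "cdr3")
  if (length(missing))
    stop("contig file is missing required column(s): ",
         paste(missing, collapse = ", "))
  n_in <- nrow(df)
  bad_chain <- !(df$chain %in% c("TRA", "TRB"))
  cdr3 <- df[[cdr3_col]]
  bad_cdr3 <- !bad_chain & (is.na(cdr3) | cdr3 == "" | cdr3 == "None")
  keep <- !(bad_chain | bad_cdr3)
  out <- data.frame(
    barcode = df$barcode[keep],
    chain = df$chain[keep],
    v_gene = df$v_gene[keep],
    j_gene = df$j_gene[keep],
    cdr3_aa = cdr3[keep],
    cdr3_nt = df$cdr3_nt[keep],
    clonotype_id = df$raw_clonotype_id[keep],
    stringsAsFactors = FALSE)
  class(out) <- c("vdj_table", "data.frame")
  attr(out, "dropped") <- c(non_tr_chain = sum(bad_chain),
                            missing_cdr3 = sum(bad_cdr3))
  attr(out, "extra_columns") <- setdiff(names(df), c(required, cdr3_col))
  stopifnot(nrow(out) + sum(bad_chain) + sum(bad_cdr3) == n_in)
  out
}

#' Read a protein FASTA into a protein set
#'
#' Headers are truncated at the first whitespace; sequences are uppercased
#' and a single terminal stop (`*`) is stripped.
#'
#' @param path FASTA file (optionally gzipped).
#' @return A named character vector of class `protein_set` (names are ids).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) {
    warning("empty FASTA file: ", path)
    return(structure(character(0), class = "protein_set"))
  }
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA")
  structure(setNames(seqs, ids), class = "protein_set")
}

#' Write a protein set as FASTA
#'
#' @param x named character vector of sequences (a `protein_set`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(as.character(x), names(x))), path)
  invisible(path)
}

#' Read C-alpha coordinates of one chain from a PDB/mmCIF file
#'
#' Extracts the C-alpha trace of the selected chain, ordered by residue
#' number. Alternate locations are resolved per atom by highest occupancy,
#' ties broken by alphabetical altloc identifier. Residues lacking a C-alpha
#' are skipped with a warning.
#'
#' @param path a PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param chain_id chain identifier to extract.
#' @param residue_range optional length-2 integer vector `c(first, last)`.
#' @return A data.frame of class `peptide_structure` with columns `chain_id`,
#'   `residue_number`, `residue_name`, `x`, `y`, `z`.
#' @export
read_structure_ca <- function(path, chain_id, residue_range = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  pdb <- suppressWarnings(suppressMessages(
    if (ext == "cif") bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE)))
  at <- pdb$atom
  at <- at[at$chain %in% chain_id & !is.na(at$chain), , drop = FALSE]
  if (nrow(at) == 0)
    stop("chain '", chain_id, "' not found in ", path)
  resnos <- sort(unique(at$resno))
  if (!is.null(residue_range))
    resnos <- resnos[resnos >= residue_range[1] & resnos <= residue_range[2]]
  rows <- lapply(resnos, function(rn) {
    ca <- at[at$resno == rn & at$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) {
      warning("residue ", rn, " of chain ", chain_id, " has no CA; skipped")
      return(NULL)
    }
    if (nrow(ca) > 1) {
      # altloc: highest occupancy wins, then alphabetical altloc id
      occ <- ca$o
      occ[is.na(occ)] <- 1
      alt <- ca$alt
      alt[is.na(alt)] <- ""
      ca <- ca[order(-occ, alt), , drop = FALSE][1, , drop = FALSE]
    }
    data.frame(chain_id = chain_id, residue_number = rn,
               residue_name = ca$resid, x = ca$x, y = ca$y, z = ca$z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("no C-alpha atoms for chain '", chain_id, "' in requested range")
  rownames(out) <- NULL
  class(out) <- c("peptide_structure", "data.frame")
  out
}

#' C-alpha coordinates of a peptide structure as a matrix
#'
#' @param x a `peptide_structure`.
#' @return An n x 3 numeric matrix.
#' @export
ca_coords <- function(x) {
  stopifnot(inherits(x, "peptide_structure"))
  as.matrix(x[, c("x", "y", "z")])
}
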