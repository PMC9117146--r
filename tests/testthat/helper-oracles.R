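# Independent oracles used to cross-check package computations.
# These deliberately share no code with the implementation.

# Textbook Welch t-test (Welch-Satterthwaite degrees of freedom)
oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Brute-force motif window scan: explicit per-character comparison
oracle_scan_bruteforce <- function(pattern, proteins) {
  pat <- strsplit(pattern, "")[[1]]
  L <- length(pat)
  out <- list()
  for (id in sort(names(proteins))) {
    s <- strsplit(toupper(proteins[[id]]), "")[[1]]
    if (length(s) < L) next
    for (start in seq_len(length(s) - L + 1)) {
      win <- s[start:(start + L - 1)]
      ok <- TRUE
      for (j in seq_len(L)) {
        if (pat[j] != "x" && win[j] != pat[j]) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1]] <-
          data.frame(protein_id = id, start = start,
                     matched_window = paste(win, collapse = ""),
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(protein_id = character(0), start = integer(0),
                      matched_window = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Horn's quaternion method for optimal rigid superposition of b onto a:
# an algorithm independent of the SVD-based Kabsch route.
oracle_quaternion_superpose <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  M <- crossprod(b0, a0)  # sum over points of b_i a_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  R <- matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2),
    3, 3, byrow = TRUE)
  fitted <- t(R %*% t(b0)) + rep(ca, each = nrow(b))
  list(rotation = R, rmsd = sqrt(mean(rowSums((a - fitted)^2))))
}

# small helpers for building fixtures in code -------------------------------

make_expr <- function(counts, genes = NULL, cells = NULL, condition = NULL) {
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(counts)))
  if (is.null(cells)) cells <- sprintf("C%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  expr_matrix(counts, condition = condition)
}

make_vdj <- function(barcode, clonotype_id, chain = "TRA",
                     v_gene = "TRAV1-1", j_gene = "TRAJ1",
                     cdr3_aa = "CASSF", cdr3_nt = "TGTGCA") {
  df <- data.frame(barcode = barcode, chain = chain, v_gene = v_gene,
                   j_gene = j_gene, cdr3_aa = cdr3_aa, cdr3_nt = cdr3_nt,
                   clonotype_id = clonotype_id, stringsAsFactors = FALSE)
  class(df) <- c("vdj_table", "data.frame")
  df
}

# one PDB ATOM line in fixed-column format
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ") {
  sprintf("ATOM  %5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, sprintf(" %-3s", elety), alt, resid, chain, resno,
          x, y, z, occ, 20)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

site_table <- function(t_a1, t_a2, n_a1, n_a2, purity = 1) {
  n <- length(t_a1)
  s <- rbind(
    data.frame(site_pos = seq_len(n), allele = "A1", reads_tumor = t_a1,
               reads_normal = n_a1, stringsAsFactors = FALSE),
    data.frame(site_pos = seq_len(n), allele = "A2", reads_tumor = t_a2,
               reads_normal = n_a2, stringsAsFactors = FALSE))
  s <- s[order(s$site_pos, s$allele), ]
  attr(s, "purity") <- purity
  class(s) <- c("hla_site_table", "data.frame")
  s
}

random_protein_set <- function(n, max_len = 50, alphabet = NULL) {
  if (is.null(alphabet))
    alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, sample(9:max_len, 1), replace = TRUE),
          collapse = ""), character(1))
  structure(setNames(seqs, sprintf("P%03d", seq_len(n))),
            class = "protein_set")
}
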