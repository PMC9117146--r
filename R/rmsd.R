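#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the least-squares proper rotation `R` and translation `t` mapping
#' coordinate set `b` onto `a` (minimizing `sum ||a_i - (R b_i + t)||^2`)
#' via singular value decomposition of the cross-covariance matrix, with the
#' reflection case excluded by the usual determinant sign correction.
#' Degenerate (rank-deficient, e.g. collinear) point sets trigger a warning
#' but still return the SVD solution.
#'
#' @param a,b n x 3 coordinate matrices in 1:1 row correspondence, n >= 3.
#' @return An object of class `superposition`: list with `rotation` (3 x 3,
#'   determinant +1), `translation` (length-3), `rmsd_fit` (Angstrom RMSD of
#'   the fitted points).
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must match in size")
  if (nrow(a) < 3 || ncol(a) != 3)
    stop("need at least 3 points of dimension 3")
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)  # 3x3 cross-covariance
  s <- svd(h)
  if (min(s$d) < 1e-8 * max(s$d, 1))
    warning("degenerate (near-collinear) point set; superposition may be unstable")
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- ca - as.vector(rot %*% cb)
  fitted <- t(rot %*% t(b)) + rep(trans, each = nrow(b))
  rmsd <- sqrt(mean(rowSums((a - fitted)^2)))
  structure(list(rotation = rot, translation = trans, rmsd_fit = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("rigid-body superposition: RMSD = %.4f A\n", x$rmsd_fit))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition` from [kabsch_superpose()].
#' @param coords n x 3 matrix.
#' @return The transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  coords <- as.matrix(coords)
  t(sp$rotation %*% t(coords)) + rep(sp$translation, each = nrow(coords))
}

.as_ca_matrix <- function(x) {
  if (inherits(x, "peptide_structure")) ca_coords(x) else as.matrix(x)
}

#' Peptide C-alpha RMSD between two structures
#'
#' Compares two bound-peptide conformations by their C-alpha traces. With
#' `frame = "peptide"` the peptides themselves are superposed and the fit
#' RMSD is reported. With `frame = "carrier"` (default, the usual convention
#' when comparing peptides bound to the same HLA) the superposition is fit
#' on the carrier (HLA heavy chain) C-alpha lists, the transform is applied
#' to the second peptide, and the RMSD over peptide C-alpha positions is
#' reported without re-fitting.
#'
#' @param struct_a,struct_b `peptide_structure` objects (or n x 3 matrices)
#'   with equal residue counts, paired by residue order.
#' @param frame `"carrier"` or `"peptide"`.
#' @param carrier_a,carrier_b carrier-chain C-alpha structures/matrices
#'   (required for `frame = "carrier"`), equal length.
#' @return The RMSD in Angstrom.
#' @export
peptide_ca_rmsd <- function(struct_a, struct_b,
                            frame = c("carrier", "peptide"),
                            carrier_a = NULL, carrier_b = NULL) {
  frame <- match.arg(frame)
  pa <- .as_ca_matrix(struct_a)
  pb <- .as_ca_matrix(struct_b)
  if (nrow(pa) != nrow(pb))
    stop("peptides differ in residue count (", nrow(pa), " vs ", nrow(pb), ")")
  if (frame == "peptide")
    return(kabsch_superpose(pa, pb)$rmsd_fit)
  if (is.null(carrier_a) || is.null(carrier_b))
    stop("frame = 'carrier' requires carrier_a and carrier_b")
  ka <- .as_ca_matrix(carrier_a)
  kb <- .as_ca_matrix(carrier_b)
  if (nrow(ka) != nrow(kb))
    stop("carrier chains differ in residue count")
  sp <- kabsch_superpose(ka, kb)
  fitted <- apply_superposition(sp, pb)
  sqrt(mean(rowSums((pa - fitted)^2)))
}
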