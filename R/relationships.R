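# Pedigree (A), genomic (G) and combined single-step (H) relationship
# matrices.  Dense algebra throughout: target populations are desk-scale.

#' Numerator relationship matrix by the tabular method
#'
#' Computes Wright's numerator relationship matrix A with inbreeding:
#' `a_ii = 1 + F_i` where `F_i = a(sire_i, dam_i) / 2`, and for j born after
#' i, `a_ij = (a(i, sire_j) + a(i, dam_j)) / 2` (unknown parents contribute
#' 0).  The pedigree must be topologically ordered.
#'
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`; 0 = unknown).
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
build_A <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal)  # NA for unknown
  d <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    f_i <- if (!is.na(si) && !is.na(di)) A[si, di] / 2 else 0
    A[i, i] <- 1 + f_i
    if (i < n) {
      for (j in seq.int(i + 1L, n)) {
        sj <- s[j]; dj <- d[j]
        val <- 0
        if (!is.na(sj)) val <- val + A[i, sj]
        if (!is.na(dj)) val <- val + A[i, dj]
        A[i, j] <- A[j, i] <- val / 2
      }
    }
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Partition A into genotyped / non-genotyped blocks
#'
#' @param A Relationship matrix from [build_A()] (dimnames = animal ids).
#' @param genotyped_ids Ids of the genotyped animals (subset of pedigree).
#' @return List with `A11` (non-genotyped), `A12`, `A22` (genotyped), and
#'   the id vectors `nongeno_ids`, `geno_ids` fixing the (non-genotyped,
#'   genotyped) ordering used by [build_H_inv()].
#' @export
extract_A_blocks <- function(A, genotyped_ids) {
  ids <- rownames(A)
  gid <- as.character(genotyped_ids)
  if (!all(gid %in% ids)) stop_bad_arg("genotyped ids not all present in A")
  ngid <- setdiff(ids, gid)
  list(A11 = A[ngid, ngid, drop = FALSE],
       A12 = A[ngid, gid, drop = FALSE],
       A22 = A[gid, gid, drop = FALSE],
       nongeno_ids = ngid, geno_ids = gid)
}

#' Second-allele frequencies from genotype codes
#'
#' `p_j` = (mean non-missing code at SNP j) / 2, the observed frequency of
#' the second allele.
#'
#' @param geno An [snp_geno()] object.
#' @return Named numeric vector of frequencies; SNP with no non-missing
#'   call are dropped with a warning.
#' @export
compute_allele_freqs <- function(geno) {
  stopifnot(inherits(geno, "snp_geno"))
  p <- colMeans(geno$codes, na.rm = TRUE) / 2
  if (anyNA(p)) {
    warning(sprintf("%d SNP with all calls missing excluded from frequencies",
                    sum(is.na(p))))
    p <- p[!is.na(p)]
  }
  p
}

#' Centered genotype matrix Z
#'
#' Codes centered by twice the second-allele frequency (`z_ij = code - 2p_j`);
#' missing codes are imputed to the column mean `2p_j` (zero after centering).
#'
#' @inheritParams compute_allele_freqs
#' @param p Allele-frequency vector aligned with the SNP columns.
#' @return Dense numeric matrix, animals x SNP.
#' @export
center_genotypes <- function(geno, p = compute_allele_freqs(geno)) {
  stopifnot(inherits(geno, "snp_geno"))
  m <- geno$codes[, names(p), drop = FALSE]
  storage.mode(m) <- "double"
  m[is.na(m)] <- NA_real_
  z <- sweep(m, 2L, 2 * p, "-")
  z[is.na(z)] <- 0
  z
}

#' Genomic relationship matrix
#'
#' `G = ZZ' / (2 * sum_j p_j (1 - p_j))` with Z the centered genotype matrix.
#'
#' @inheritParams center_genotypes
#' @return Dense symmetric genomic relationship matrix over the genotyped
#'   animals.
#' @export
build_G <- function(geno, p = compute_allele_freqs(geno)) {
  if (any(p <= 0 | p >= 1)) {
    stop_bad_arg("allele frequencies must lie strictly in (0,1); run QC first")
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_computational("all SNP monomorphic: zero denominator")
  z <- center_genotypes(geno, p)
  g <- tcrossprod(z) / denom
  symmpart_dense(g)
}

#' Scale G to match A22's diagonal and off-diagonal means
#'
#' Solves for alpha, beta in `G* = beta * G + alpha * J` (J = all-ones) such
#' that `mean(diag(G*)) = mean(diag(A22))` and `mean(offdiag(G*)) =
#' mean(offdiag(A22))` - the default scaling of the BLUPF90 family.
#'
#' @param G,A22 Matrices of identical dimension and animal order.
#' @return Scaled matrix `G*` with attributes `alpha` and `beta`.
#' @export
tune_G_to_A22 <- function(G, A22) {
  if (!all(dim(G) == dim(A22))) stop_bad_arg("G and A22 dimensions differ")
  md_g <- mean(diag(G)); mo_g <- offdiag_mean(G)
  md_a <- mean(diag(A22)); mo_a <- offdiag_mean(A22)
  det2 <- md_g - mo_g
  if (!is.finite(det2) || abs(det2) < 1e-12) {
    stop_computational("mean diagonal equals mean off-diagonal of G: scaling system singular")
  }
  beta <- (md_a - mo_a) / det2
  alpha <- md_a - beta * md_g
  out <- beta * G + alpha
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  out
}

offdiag_mean <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(0)
  (sum(m) - sum(diag(m))) / (n * (n - 1))
}

#' Blend a genomic matrix with A22
#'
#' `G_b = alpha_blend * G + (1 - alpha_blend) * A22`; with `alpha_blend < 1`
#' and A22 positive definite this guarantees invertibility even when G is
#' rank-deficient (more animals than SNP).
#'
#' @param G Tuned genomic matrix.
#' @param A22 Pedigree relationships among the genotyped animals.
#' @param alpha_blend Weight on G, in (0, 1]; default 0.95.
#' @return Blended matrix.
#' @export
blend_G <- function(G, A22, alpha_blend = 0.95) {
  if (!all(dim(G) == dim(A22))) stop_bad_arg("G and A22 dimensions differ")
  if (!is.numeric(alpha_blend) || alpha_blend <= 0 || alpha_blend > 1) {
    stop_bad_arg("alpha_blend must lie in (0,1]")
  }
  alpha_blend * G + (1 - alpha_blend) * A22
}

#' Inverse of the single-step relationship matrix H
#'
#' `H^-1 = A^-1 + [[0, 0], [0, Gb^-1 - A22^-1]]` on the (non-genotyped,
#' genotyped) partition.  The returned matrix is ordered non-genotyped block
#' first, then genotyped, with animal ids as dimnames.
#'
#' @param A Full pedigree relationship matrix.
#' @param G_b Blended genomic matrix over the genotyped animals (dimnames
#'   must identify them); NULL when no animal is genotyped.
#' @param genotyped_ids Ids of genotyped animals (row order of `G_b`).
#' @return List with `H_inv` (dense), `order` (animal ids row order) and the
#'   blocks used.
#' @export
build_H_inv <- function(A, G_b = NULL, genotyped_ids = character()) {
  ids <- rownames(A)
  gid <- as.character(genotyped_ids)
  blocks <- extract_A_blocks(A, gid)
  ord <- c(blocks$nongeno_ids, blocks$geno_ids)
  A_ord <- A[ord, ord, drop = FALSE]
  A_inv <- chol2inv(chol(symmpart_dense(A_ord)))
  H_inv <- A_inv
  if (length(gid) > 0L) {
    if (is.null(G_b) || !all(dim(G_b) == length(gid))) {
      stop_bad_arg("G_b must be a square matrix over the genotyped animals")
    }
    if (!is.null(rownames(G_b))) G_b <- G_b[gid, gid, drop = FALSE]
    ev <- eigen(symmpart_dense(G_b), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10 * max(ev)) {
      stop_computational("G_b is not invertible; blend with A22 first")
    }
    G_b_inv <- chol2inv(chol(symmpart_dense(G_b)))
    A22_inv <- chol2inv(chol(symmpart_dense(blocks$A22)))
    idx <- seq.int(length(blocks$nongeno_ids) + 1L, length(ord))
    H_inv[idx, idx] <- H_inv[idx, idx] + G_b_inv - A22_inv
  }
  dimnames(H_inv) <- list(ord, ord)
  list(H_inv = symmpart_dense(H_inv), order = ord,
       A11 = blocks$A11, A12 = blocks$A12, A22 = blocks$A22)
}
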