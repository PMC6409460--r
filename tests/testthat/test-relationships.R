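# pedigree A, genomic G, tuning/blending, and the single-step H inverse

test_that("tabular A reproduces hand-worked and recursive values", {
  A <- build_A(ped_trio())
  expect_equal(A["1", "3"], 0.5)
  expect_equal(A["3", "3"], 1.0)
  expect_equal(A["1", "2"], 0)

  A_fs <- build_A(ped_fullsibs())
  expect_equal(A_fs["3", "4"], 0.5)

  A_in <- build_A(ped_inbred())          # 4 = sire 1 x daughter 3
  expect_equal(A_in["4", "4"], 1.25)     # F = a(1,3)/2 = 0.25
})

test_that("tabular A equals exact recursive A on random small pedigrees", {
  set.seed(101)
  for (rep in 1:25) {
    ped <- random_pedigree(sample(4:12, 1))
    A <- build_A(ped)
    expect_equal(A, recursive_A(ped), tolerance = 0)
    expect_true(isSymmetric(A))
    expect_true(all(diag(A) >= 1))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > -1e-8)
  }
})

test_that("cyclic or malformed pedigrees are rejected", {
  bad <- tibble::tibble(animal = c(1L, 2L), sire = c(2L, 1L), dam = c(0L, 0L))
  expect_error(build_A(bad), class = "ssgwaspath_structural_error")
  self <- tibble::tibble(animal = 1L, sire = 1L, dam = 0L)
  expect_error(build_A(self), class = "ssgwaspath_structural_error")
})

test_that("A blocks are plain principal submatrices", {
  ped <- simulate_pedigree(4, 2, 4, seed = 2)
  A <- build_A(ped)
  # degenerate partitions
  all_b <- extract_A_blocks(A, ped$animal)
  expect_equal(all_b$A22, A[as.character(ped$animal), as.character(ped$animal)])
  expect_equal(dim(all_b$A11), c(0L, 0L))
  none_b <- extract_A_blocks(A, integer())
  expect_equal(none_b$A11, A)
  # random subset: every entry equals a direct lookup
  sub <- sample(ped$animal, 3)
  b <- extract_A_blocks(A, sub)
  for (i in b$geno_ids) for (j in b$geno_ids) {
    expect_identical(b$A22[i, j], A[i, j])
  }
  for (i in b$nongeno_ids) for (j in b$geno_ids) {
    expect_identical(b$A12[i, j], A[i, j])
  }
  expect_error(extract_A_blocks(A, 999), class = "ssgwaspath_argument_error")
})

test_that("allele frequencies are mean codes over non-missing calls", {
  geno <- snp_geno(matrix(c(0, 1, 2,
                            2, 2, 2,
                            0, 1, NA), nrow = 3, byrow = FALSE,
                          dimnames = list(1:3, NULL)),
                   tibble::tibble(snp_id = c("a", "b", "c"),
                                  chrom = "chr1", pos = c(10, 20, 30)))
  p <- compute_allele_freqs(geno)
  # hand counts: (0,1,2) -> 0.5; (2,2,2) -> 1 (QC removes later);
  # (0,1,NA) -> 1 copy / 4 alleles = 0.25
  expect_equal(unname(p), c(0.5, 1.0, 0.25))
})

test_that("five-call hand count with a missing genotype", {
  geno <- snp_geno(matrix(c(0, 1, 2, NA, 1), ncol = 1,
                          dimnames = list(1:5, NULL)),
                   tibble::tibble(snp_id = "s", chrom = "chr1", pos = 1))
  expect_equal(unname(compute_allele_freqs(geno)), 4 / 8)
})

test_that("G matches the explicit two-animal formula and brute force", {
  g2 <- snp_geno(matrix(c(0L, 2L), ncol = 1, dimnames = list(1:2, NULL)),
                 tibble::tibble(snp_id = "s1", chrom = "chr1", pos = 5))
  G <- build_G(g2, p = c(s1 = 0.5))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-14)

  # centered constant column contributes nothing
  g1 <- snp_geno(matrix(c(1L, 1L, 0L, 2L), ncol = 2,
                        dimnames = list(1:2, NULL)),
                 tibble::tibble(snp_id = c("s1", "s2"), chrom = "chr1",
                                pos = c(5, 9)))
  G1 <- build_G(g1, p = c(s1 = 0.5, s2 = 0.5))
  # only s2 contributes; denominator now sums both loci
  expect_equal(unname(G1), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-14)

  # naive O(n^2 m) double-loop oracle on random data
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:5, 1); m <- 50
    codes <- matrix(sample(0:2, n * m, replace = TRUE), n,
                    dimnames = list(1:n, NULL))
    geno <- snp_geno(codes, tibble::tibble(
      snp_id = paste0("s", 1:m), chrom = "chr1", pos = seq_len(m) * 10))
    p <- compute_allele_freqs(geno)
    keep <- p > 0 & p < 1
    geno <- snp_geno(codes[, keep, drop = FALSE], geno$map[keep, ])
    p <- p[keep]
    G <- build_G(geno, p)
    denom <- 2 * sum(p * (1 - p))
    naive <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      naive[i, j] <- sum((codes[i, keep] - 2 * p) * (codes[j, keep] - 2 * p))
    }
    expect_equal(unname(G), naive / denom, tolerance = 1e-12)
  }
})

test_that("G is invariant to SNP column order", {
  set.seed(8)
  codes <- matrix(sample(0:2, 6 * 40, replace = TRUE), 6,
                  dimnames = list(1:6, NULL))
  geno <- snp_geno(codes, tibble::tibble(snp_id = paste0("s", 1:40),
                                         chrom = "chr1", pos = 1:40 * 7))
  p <- compute_allele_freqs(geno)
  perm <- sample(40)
  geno_p <- snp_geno(codes[, perm],
                     tibble::tibble(snp_id = paste0("s", (1:40)[perm]),
                                    chrom = "chr1", pos = sort(perm * 7)))
  # same p mapping by snp id; positions relabeled to stay sorted
  expect_equal(build_G(geno, p), build_G(geno_p, p[perm]), tolerance = 1e-12)
})

test_that("missing codes are imputed to the column mean before centering", {
  codes <- matrix(c(0L, 2L, NA), ncol = 1, dimnames = list(1:3, NULL))
  geno <- snp_geno(codes, tibble::tibble(snp_id = "s", chrom = "chr1", pos = 1))
  z <- center_genotypes(geno, p = c(s = 0.5))
  expect_equal(unname(z[, 1]), c(-1, 1, 0))
})

test_that("mean-matching scaling solves the 2x2 system exactly", {
  # fixed point: already matching
  A22 <- diag(3) + 0.1
  out <- tune_G_to_A22(A22, A22)
  expect_equal(attr(out, "beta"), 1)
  expect_equal(attr(out, "alpha"), 0, tolerance = 1e-12)

  # hand-solved case: diag means 2 -> 1, offdiag 0 -> 0
  G <- diag(c(2, 2, 2))
  target <- diag(3)
  out2 <- tune_G_to_A22(G, target)
  expect_equal(attr(out2, "beta"), 0.5)
  expect_equal(attr(out2, "alpha"), 0)

  # random case: output means hit the targets within 1e-12
  set.seed(3)
  z <- matrix(rnorm(6 * 30), 6)
  Gr <- tcrossprod(z) / 30
  A22r <- diag(6) * 1.02 + 0.03
  tuned <- tune_G_to_A22(Gr, A22r)
  expect_equal(mean(diag(tuned)), mean(diag(A22r)), tolerance = 1e-12)
  off <- function(m) (sum(m) - sum(diag(m))) / (nrow(m) * (nrow(m) - 1))
  expect_equal(off(tuned), off(A22r), tolerance = 1e-12)

  expect_error(tune_G_to_A22(matrix(1, 4, 4), diag(4)),
               class = "ssgwaspath_computational_error")
})

test_that("blending restores invertibility of a rank-deficient G", {
  expect_equal(blend_G(diag(2), diag(2) * 2, 1), diag(2))
  A22 <- diag(4) * 1.01 + 0.2
  expect_equal(blend_G(A22, A22, 0.95), A22)

  # more animals than SNP: singular G, blended is PD
  set.seed(4)
  codes <- matrix(sample(0:2, 8 * 3, replace = TRUE), 8,
                  dimnames = list(1:8, NULL))
  geno <- snp_geno(codes, tibble::tibble(snp_id = paste0("s", 1:3),
                                         chrom = "chr1", pos = 1:3 * 5))
  p <- compute_allele_freqs(geno)
  G <- build_G(geno, pmin(pmax(p, 0.05), 0.95))
  ev_g <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev_g), 1e-10)
  Gb <- blend_G(G, diag(8) * 1.05 + 0.1, 0.95)
  ev_b <- eigen(Gb, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev_b), 0)
  # symmetry and PSD preserved through tune + blend
  expect_true(isSymmetric(Gb))

  expect_error(blend_G(diag(2), diag(3)), class = "ssgwaspath_argument_error")
  expect_error(blend_G(diag(2), diag(2), 0), class = "ssgwaspath_argument_error")
})

test_that("H inverse reduces to A inverse in the degenerate cases", {
  ped <- simulate_pedigree(4, 2, 6, seed = 6)
  A <- build_A(ped)
  h0 <- build_H_inv(A)
  expect_equal(h0$H_inv, chol2inv(chol(A)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # G_b = A22: the genomic correction vanishes
  gid <- tail(ped$animal, 5)
  blocks <- extract_A_blocks(A, gid)
  h1 <- build_H_inv(A, blocks$A22, gid)
  ord <- h1$order
  expect_equal(h1$H_inv, chol2inv(chol(A[ord, ord])), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the genotyped block of H equals the blended genomic matrix", {
  ped <- simulate_pedigree(6, 1, 8, seed = 7)
  fh <- setNames(rep(c(1, 0), 3), 1:6)
  breed <- assign_breed_fractions(ped, fh)
  geno <- simulate_genotypes(ped, breed, 120, c(chr1 = 1e6), seed = 8)
  gid <- as.character(tail(ped$animal, 3))
  sub <- snp_geno(geno$codes[gid, , drop = FALSE], geno$map)
  p <- compute_allele_freqs(sub)
  keep <- p > 0.01 & p < 0.99
  sub <- snp_geno(sub$codes[, keep, drop = FALSE], sub$map[keep, ])
  p <- p[keep]
  A <- build_A(ped)
  blocks <- extract_A_blocks(A, gid)
  G_b <- blend_G(tune_G_to_A22(build_G(sub, p), blocks$A22), blocks$A22, 0.95)
  h <- build_H_inv(A, G_b, gid)
  H <- chol2inv(chol(h$H_inv))
  dimnames(H) <- dimnames(h$H_inv)
  expect_equal(H[gid, gid], G_b[gid, gid], tolerance = 1e-8)
  # H inverse itself is symmetric PSD
  ev <- eigen(h$H_inv, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(build_H_inv(A, build_G(sub, p) * 0, gid),
               class = "ssgwaspath_computational_error")
})
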