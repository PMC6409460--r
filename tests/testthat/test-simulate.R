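# synthetic-data generator: pedigrees, breed fractions, gene-drop
# genotypes, phenotypes, annotation/sets, test-interval yields

test_that("simulated pedigrees are topologically ordered and reproducible", {
  ped <- simulate_pedigree(10, 3, 10, seed = 3)
  pos <- seq_len(nrow(ped))
  sp <- match(ped$sire, ped$animal)
  dp <- match(ped$dam, ped$animal)
  known <- ped$sire != 0
  # exhaustive ancestry scan: every parent appears strictly earlier
  expect_true(all(sp[known] < pos[known]))
  expect_true(all(dp[known] < pos[known]))
  expect_true(all(ped$sire[known] != ped$dam[known]))

  again <- simulate_pedigree(10, 3, 10, seed = 3)
  expect_identical(ped, again)
  other <- simulate_pedigree(10, 3, 10, seed = 4)
  expect_false(identical(ped, other))

  expect_error(simulate_pedigree(1, 1), class = "ssgwaspath_argument_error")
  expect_error(simulate_pedigree(5, 0), class = "ssgwaspath_argument_error")
})

test_that("breed fractions propagate as parent means", {
  ped <- ped_trio()
  bf <- assign_breed_fractions(ped, c("1" = 1, "2" = 0))
  expect_equal(bf$h_fraction, c(1, 0, 0.5))
  expect_equal(bf$o_fraction, c(0, 1, 0.5))

  all_h <- assign_breed_fractions(ped, c("1" = 1, "2" = 1))
  expect_true(all(all_h$h_fraction == 1))

  expect_error(assign_breed_fractions(ped, c("1" = 1)),
               class = "ssgwaspath_argument_error")
})

test_that("breed fractions equal brute-force pedigree path averages", {
  # 3 generations from 4 founders with mixed fractions
  ped <- ped_tbl(1, 0, 0, 2, 0, 0, 3, 0, 0, 4, 0, 0,
                 5, 1, 2, 6, 3, 4, 7, 5, 6, 8, 5, 3)
  fh <- c("1" = 1, "2" = 0, "3" = 0.5, "4" = 0.5)
  bf <- assign_breed_fractions(ped, fh)
  # oracle: recursive expected founder contribution
  contrib <- function(id) {
    row <- ped[ped$animal == id, ]
    if (row$sire == 0) return(fh[[as.character(id)]])
    (contrib(row$sire) + contrib(row$dam)) / 2
  }
  for (id in ped$animal) {
    expect_equal(bf$h_fraction[bf$animal == id], contrib(id))
  }
  expect_true(all(bf$h_fraction >= 0 & bf$h_fraction <= 1))
  expect_equal(bf$h_fraction + bf$o_fraction, rep(1, nrow(ped)))
})

test_that("gene dropping respects Mendelian constraints", {
  # 2 founders, many offspring; check fixed-parent cases exhaustively
  n_off <- 200
  ped <- ped_tbl(1, 0, 0, 2, 0, 0)
  ped <- dplyr::bind_rows(ped, tibble::tibble(
    animal = 2L + seq_len(n_off), sire = 1L, dam = 2L))
  breed <- assign_breed_fractions(ped, c("1" = 1, "2" = 0))
  g <- simulate_genotypes(ped, breed, 60, c(chr1 = 1e6), seed = 5)
  codes <- g$codes
  for (j in seq_len(ncol(codes))) {
    p1 <- codes[1, j]; p2 <- codes[2, j]
    off <- codes[-(1:2), j]
    if (p1 == 0 && p2 == 0) expect_true(all(off == 0))
    if (p1 == 2 && p2 == 2) expect_true(all(off == 2))
    if (p1 == 0 && p2 == 2) expect_true(all(off == 1))   # 0 x 2 mating
    if (p1 == 2 && p2 == 0) expect_true(all(off == 1))
    # a homozygous parent transmits its allele: offspring never opposite hom.
    if (p1 == 0 || p2 == 0) expect_true(all(off < 2))
    if (p1 == 2 || p2 == 2) expect_true(all(off > 0))
  }
  expect_true(all(diff(g$map$pos) > 0))
})

test_that("founder allele frequencies are recovered within 3 binomial SE", {
  n_f <- 600
  ped <- tibble::tibble(animal = seq_len(n_f), sire = 0L, dam = 0L)
  breed <- assign_breed_fractions(ped, setNames(rep(1, n_f), seq_len(n_f)))
  p_true <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  g <- simulate_genotypes(ped, breed, 5, c(chr1 = 1e6),
                          freq_h = p_true, seed = 11)
  p_hat <- unname(compute_allele_freqs(g))
  se <- sqrt(p_true * (1 - p_true) / (2 * n_f))
  expect_true(all(abs(p_hat - p_true) <= 3 * se))
})

test_that("degenerate phenotype simulation is noise-free and deterministic", {
  ped <- ped_trio()
  breed <- assign_breed_fractions(ped, c("1" = 1, "2" = 0))
  truth <- sim_truth(Va = matrix(0, 3, 3), Ve = matrix(0, 3, 3),
                     b_breed = c(1, 2, 3), b_het = c(0, 0, 0))
  y1 <- simulate_phenotypes(ped, breed, truth = truth, n_hys = 1, seed = 1)
  y2 <- simulate_phenotypes(ped, breed, truth = truth, n_hys = 1, seed = 99)
  expect_equal(y1$records, y2$records)     # no stochastic terms left
  # y = hys + b_breed * o_fraction exactly
  expect_equal(unname(as.matrix(y1$records[, c("MY", "FY", "AFC")])),
               outer(breed$o_fraction, c(1, 2, 3)), tolerance = 1e-12)
})

test_that("simulated residual and additive covariances match the truth", {
  n_f <- 2500
  ped <- tibble::tibble(animal = seq_len(n_f), sire = 0L, dam = 0L)
  breed <- assign_breed_fractions(ped, setNames(rep(1, n_f), seq_len(n_f)))
  truth <- sim_truth(b_breed = rep(0, 3), b_het = rep(0, 3))
  phen <- simulate_phenotypes(ped, breed, truth = truth, n_hys = 1, seed = 7,
                              A = structure(diag(n_f),
                                            dimnames = list(ped$animal,
                                                            ped$animal)))
  # founders are unrelated: phenotypic covariance = Va + Ve (single HYS)
  y <- as.matrix(phen$records[, c("MY", "FY", "AFC")])
  total <- truth$Va + truth$Ve
  emp <- cov(y)
  se <- sqrt((diag(total) %o% diag(total) + total^2) / n_f)
  expect_true(all(abs(emp - total) <= 3 * se))
  # realized additive covariance of the breeding values
  bv <- as.matrix(phen$bv[, c("MY", "FY", "AFC")])
  se_a <- sqrt(((diag(truth$Va) %o% diag(truth$Va)) + truth$Va^2) / n_f)
  expect_true(all(abs(cov(bv) - truth$Va) <= 3 * se_a))
})

test_that("realized heritability matches Va/(Va+Ve) at large n", {
  n_f <- 2000
  ped <- tibble::tibble(animal = seq_len(n_f), sire = 0L, dam = 0L)
  breed <- assign_breed_fractions(ped, setNames(rep(1, n_f), seq_len(n_f)))
  truth <- sim_truth(b_breed = rep(0, 3), b_het = rep(0, 3))
  phen <- simulate_phenotypes(ped, breed, truth = truth, n_hys = 1, seed = 13,
                              A = structure(diag(n_f),
                                            dimnames = list(ped$animal,
                                                            ped$animal)))
  y <- as.matrix(phen$records[, c("MY", "FY", "AFC")])
  bv <- as.matrix(phen$bv[, c("MY", "FY", "AFC")])
  h2_true <- diag(truth$Va) / diag(truth$Va + truth$Ve)
  h2_emp <- diag(cov(bv)) / diag(cov(y))
  # Monte-Carlo SE of a variance-ratio estimate, roughly sqrt(2/n) scale
  expect_true(all(abs(h2_emp - h2_true) <= 3 * sqrt(2 / n_f)))
})

test_that("annotation intervals never overlap and outputs are reproducible", {
  ann <- simulate_annotation(c(chr1 = 2e6, chr2 = 1e6), 50, seed = 9)
  expect_equal(nrow(ann), 50)
  expect_true(all(ann$start <= ann$end))
  # brute-force all-pairs overlap scan within chromosome
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    if (nrow(a) < 2) next
    for (i in seq_len(nrow(a) - 1)) {
      for (j in seq.int(i + 1, nrow(a))) {
        expect_true(a$end[i] < a$start[j] || a$end[j] < a$start[i])
      }
    }
  }
  expect_error(simulate_annotation(c(chr1 = 1e4), 500, seed = 1),
               class = "ssgwaspath_argument_error")

  # byte-identical GMT across runs with a fixed seed
  sets <- simulate_gene_sets(ann, 6, seed = 2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(sets, f1)
  write_gmt(simulate_gene_sets(ann, 6, seed = 2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("interaction edges have no self-loops and valid confidences", {
  ann <- simulate_annotation(c(chr1 = 2e6), 40, seed = 1)
  sets <- simulate_gene_sets(ann, 4, seed = 2)
  edges <- simulate_ppi_edges(ann$gene_id, 150, within_sets = sets, seed = 3)
  expect_equal(nrow(edges), 150)
  expect_true(all(edges$gene_a != edges$gene_b))
  expect_true(all(edges$confidence >= 0 & edges$confidence <= 1))
})

test_that("test-interval yields match closed forms and trapezoid oracle", {
  # constant daily yield integrates exactly
  expect_equal(test_interval_yield(seq(15, 285, by = 30), rep(10, 10)), 3050)
  # single test day: flat projection over the whole lactation
  expect_equal(test_interval_yield(100, 12), 3660)
  # linear decline: equals the trapezoid-rule integral with flat ends
  days <- seq(15, 285, by = 30)
  yields <- 20 - 0.03 * days
  oracle <- days[1] * yields[1] +
    sum(diff(days) * (head(yields, -1) + tail(yields, -1)) / 2) +
    (305 - tail(days, 1)) * tail(yields, 1)
  expect_equal(test_interval_yield(days, yields), oracle, tolerance = 1e-12)
  # fat yield analogue: fat% x MY per test day
  fat_pct <- rep(0.04, length(days))
  expect_equal(test_interval_yield(days, fat_pct * yields),
               0.04 * oracle, tolerance = 1e-12)

  expect_error(test_interval_yield(numeric(), numeric()),
               class = "ssgwaspath_argument_error")
  expect_error(test_interval_yield(c(30, 20), c(1, 1)),
               class = "ssgwaspath_argument_error")
})
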