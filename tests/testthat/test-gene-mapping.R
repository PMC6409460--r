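# genotype QC, variance-threshold selection, SNP-to-gene assignment,
# distance bins, trait-overlap counts

test_that("QC removes low call rate and low MAF by strict 'lower than'", {
  # SNP1: 8/10 calls (0.8) -> removed; SNP2: full, p=0.5 -> kept;
  # SNP3: MAF exactly 0.01 -> kept (rule removes strictly below)
  codes <- cbind(c(rep(0L, 8), NA, NA),
                 rep(c(0L, 2L), 5),
                 c(2L, rep(1L, 0), rep(0L, 9)))
  # column 3: one animal code 2, nine code 0 -> p = 2/20 = 0.1; adjust to
  # exactly 0.01: use 100 animals instead
  codes100 <- cbind(c(rep(0L, 80), rep(NA, 20)),
                    rep(c(0L, 2L), 50),
                    c(2L, rep(0L, 99)))
  geno <- snp_geno(matrix(codes100, ncol = 3,
                          dimnames = list(1:100, NULL)),
                   tibble::tibble(snp_id = c("low_call", "ok", "maf_edge"),
                                  chrom = "chr1", pos = c(10, 20, 30)))
  out <- qc_genotypes(geno)
  expect_equal(colnames(out$codes), c("ok", "maf_edge"))
  qc <- attr(out, "qc")
  expect_equal(qc$n_input, 3L)
  expect_equal(qc$n_kept, 2L)
  expect_equal(qc$n_callrate, 1L)
  # call rate exactly 0.90 is retained
  codes_edge <- cbind(c(rep(1L, 90), rep(NA, 10)))
  g_edge <- snp_geno(matrix(codes_edge, ncol = 1,
                            dimnames = list(1:100, NULL)),
                     tibble::tibble(snp_id = "edge", chrom = "chr1", pos = 5))
  # p = 0.5 at call rate exactly the threshold -> kept
  expect_equal(ncol(qc_genotypes(g_edge)$codes), 1L)
  # everything removed -> structural error
  all_bad <- snp_geno(matrix(rep(2L, 100), ncol = 1,
                             dimnames = list(1:100, NULL)),
                      tibble::tibble(snp_id = "mono", chrom = "chr1", pos = 5))
  expect_error(qc_genotypes(all_bad), class = "ssgwaspath_structural_error")
})

test_that("variance-threshold selection keeps 'at least' the threshold", {
  eff <- tibble::tibble(
    snp_id = paste0("s", 1:6),
    varpct_MY = c(0, 0.0005, 0.001, 0.002, 0.01, 0.0001),
    varpct_FY = c(0.001, 0, 0, 0, 0, 0))
  expect_equal(filter_by_variance(eff, "MY"), c("s3", "s4", "s5"))
  expect_equal(filter_by_variance(eff, "FY"), "s1")    # boundary inclusive
  expect_equal(filter_by_variance(eff, "MY", threshold = 100), character())
  expect_error(filter_by_variance(eff, "nope"),
               class = "ssgwaspath_argument_error")
})

test_that("distance bins follow the left-closed convention", {
  ann <- tibble::tibble(gene_id = "g", chrom = "chr1",
                        start = 100000, end = 120000)
  offs <- c(0, 2500, 2501, 5000, 25000, 25001)
  snps <- tibble::tibble(snp_id = paste0("s", seq_along(offs)),
                         chrom = "chr1", pos = 100000 - offs)
  asg <- assign_to_genes(snps, ann)
  expect_equal(asg$distance, offs)
  expect_equal(asg$distance_class,
               c("inside", "<=2500", "(2500,5000]", "(2500,5000]",
                 "(5000,25000]", ">25000"))
  expect_equal(asg$eligible, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # same bins on the downstream side of the gene
  snps_dn <- dplyr::mutate(snps, pos = 120000 + offs)
  asg_dn <- assign_to_genes(snps_dn, ann)
  expect_equal(asg_dn$distance_class, asg$distance_class)
  # inside at both interval ends
  ends <- tibble::tibble(snp_id = c("a", "b"), chrom = "chr1",
                         pos = c(100000, 120000))
  expect_true(all(assign_to_genes(ends, ann)$distance_class == "inside"))
})

test_that("assignment is many-to-many and flags missing chromosomes", {
  ann <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                        start = c(1000, 3000), end = c(2500, 4000))
  # SNP at 2600: within 2500 bp of both genes
  snp <- tibble::tibble(snp_id = "s", chrom = "chr1", pos = 2600)
  asg <- assign_to_genes(snp, ann)
  expect_equal(sort(asg$gene_id), c("g1", "g2"))
  expect_true(all(asg$eligible))
  # chromosome absent from the annotation
  off <- tibble::tibble(snp_id = "x", chrom = "chrZ", pos = 5)
  asg_off <- assign_to_genes(off, ann)
  expect_true(is.na(asg_off$gene_id))
  expect_false(asg_off$eligible)
})

test_that("shrinking the window never adds assignments", {
  set.seed(12)
  ann <- simulate_annotation(c(chr1 = 5e5), 15, mean_gene_length = 5000,
                             seed = 3)
  snps <- tibble::tibble(snp_id = paste0("s", 1:80), chrom = "chr1",
                         pos = sort(sample.int(5e5, 80)))
  wide <- assign_to_genes(snps, ann, window = 2500)
  narrow <- assign_to_genes(snps, ann, window = 1000)
  wide_elig <- wide[wide$eligible, c("snp_id", "gene_id")]
  narrow_elig <- narrow[narrow$eligible, c("snp_id", "gene_id")]
  expect_true(nrow(narrow_elig) <= nrow(wide_elig))
  expect_true(all(paste(narrow_elig$snp_id, narrow_elig$gene_id) %in%
                    paste(wide_elig$snp_id, wide_elig$gene_id)))
  # every eligible assignment respects the window
  expect_true(all(wide$distance[wide$eligible] <= 2500))
  # assignment is idempotent: same input, same output
  expect_identical(assign_to_genes(snps, ann), wide)
})

test_that("distance-bin summaries add up", {
  ann <- simulate_annotation(c(chr1 = 5e5), 10, mean_gene_length = 8000,
                             seed = 5)
  set.seed(6)
  eff <- tibble::tibble(snp_id = paste0("s", 1:50), chrom = "chr1",
                        pos = sort(sample.int(5e5, 50)),
                        varpct_MY = runif(50, 0, 0.01))
  asg <- assign_to_genes(eff[, c("snp_id", "chrom", "pos")], ann)
  summ <- distance_bin_summary(asg, eff)
  expect_equal(sum(summ$n_assignments),
               sum(!is.na(asg$gene_id)))
  expect_true(all(summ$distance_class %in%
                    c("inside", "<=2500", "(2500,5000]", "(5000,25000]",
                      ">25000")))
})

test_that("trait overlap counts equal brute-force Venn enumeration", {
  same <- replicate(3, paste0("g", 1:5), simplify = FALSE)
  names(same) <- c("MY", "FY", "AFC")
  ov <- trait_overlap(same)
  expect_equal(ov$n_genes[ov$traits == "MY+FY+AFC"], 5L)
  expect_equal(sum(ov$n_genes), 5L)

  disj <- list(MY = paste0("a", 1:2), FY = paste0("b", 1:3),
               AFC = paste0("c", 1:4))
  ov2 <- trait_overlap(disj)
  expect_equal(ov2$n_genes[ov2$traits == "MY"], 2L)
  expect_equal(ov2$n_genes[ov2$traits == "FY"], 3L)
  expect_equal(ov2$n_genes[ov2$traits == "AFC"], 4L)
  expect_equal(ov2$n_genes[ov2$n_traits > 1], rep(0L, 4))

  set.seed(31)
  pool <- paste0("g", 1:40)
  rnd <- list(MY = sample(pool, 18), FY = sample(pool, 22),
              AFC = sample(pool, 11))
  ov3 <- trait_overlap(rnd)
  # brute force over every gene in the union
  uni <- unique(unlist(rnd))
  for (region in ov3$traits) {
    members <- strsplit(region, "+", fixed = TRUE)[[1]]
    manual <- sum(vapply(uni, function(g) {
      setequal(names(rnd)[vapply(rnd, function(s) g %in% s, logical(1))],
               members)
    }, logical(1)))
    expect_equal(ov3$n_genes[ov3$traits == region], manual)
  }
  # conservation: regions partition the union
  expect_equal(sum(ov3$n_genes), length(uni))
})
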