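# Genotype container and gene-drop simulation.
#
# Genotypes are copies of the second allele: 0 (homozygous 11),
# 1 (heterozygous 12/21), 2 (homozygous 22), NA = missing.

#' Construct a genotype matrix object
#'
#' @param codes Integer matrix, animals in rows, SNP in columns, entries in
#'   \{0, 1, 2, NA\} counting copies of the second allele.  Row names are
#'   animal ids, column names SNP ids.
#' @param map Tibble with one row per SNP: `snp_id`, `chrom`, `pos` (bp,
#'   1-based), in the column order of `codes`; positions must be strictly
#'   increasing within chromosome.
#' @return An object of class `snp_geno` (list with `codes` and `map`).
#' @export
snp_geno <- function(codes, map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop_bad_arg("genotype codes must be 0, 1, 2 or NA")
  map <- as_tibble(map)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map))) stop_bad_arg("map needs snp_id, chrom, pos")
  if (nrow(map) != ncol(codes)) {
    stop_bad_arg("map rows must match genotype columns")
  }
  by_chr <- split(map$pos, map$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1)))) {
    stop_bad_arg("positions must be strictly increasing within chromosome")
  }
  colnames(codes) <- map$snp_id
  structure(list(codes = codes, map = map), class = "snp_geno")
}

#' @exportS3Method base::print
print.snp_geno <- function(x, ...) {
  cat(sprintf("<snp_geno> %d animals x %d SNP on %d chromosome(s); %.2f%% missing\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom)),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.snp_geno <- function(x) dim(x$codes)

#' Gene-drop genotypes through a pedigree
#'
#' Founder genotypes are drawn per locus from breed-pool allele frequencies:
#' each of a founder's two alleles comes from the H pool with probability
#' equal to the founder's H fraction, otherwise from the O pool.  Offspring
#' receive one allele from each parent (Mendelian transmission, loci
#' independent - no linkage beyond pedigree cosegregation).
#'
#' @param ped Pedigree tibble in topological order.
#' @param breed Breed-fraction tibble from [assign_breed_fractions()].
#' @param n_snp Number of SNP to simulate.
#' @param chrom_lengths Named (or unnamed) numeric vector of chromosome
#'   lengths in bp; SNP are spread over chromosomes proportionally to length.
#' @param freq_h,freq_o Second-allele frequencies per pool: a single number,
#'   a length-`n_snp` vector, or NULL to draw each from Uniform(0.05, 0.95).
#' @param missing_rate Probability a call is set missing, completely at
#'   random (default 0; QC downstream handles missingness).  A single rate
#'   or one rate per SNP.
#' @param seed Integer seed.
#' @param map Optional SNP map tibble (`snp_id`, `chrom`, `pos`) fixing the
#'   marker positions (e.g. a gene-centric panel from [gene_centric_map()]);
#'   overrides random placement.
#' @return An [snp_geno()] object with animals in pedigree order.
#' @export
simulate_genotypes <- function(ped, breed, n_snp, chrom_lengths,
                               freq_h = NULL, freq_o = NULL,
                               missing_rate = 0, seed = 1L, map = NULL) {
  validate_pedigree(ped)
  n_snp <- check_count(n_snp, "n_snp")
  if (any(chrom_lengths <= 0)) stop_bad_arg("chromosome lengths must be positive")
  missing_rate <- vapply(missing_rate, check_prob, numeric(1),
                         name = "missing_rate")
  withr_seed(seed)

  expand_freq <- function(f, name) {
    if (is.null(f)) return(runif(n_snp, 0.05, 0.95))
    f <- rep_len(as.numeric(f), n_snp)
    if (any(f <= 0 | f >= 1)) {
      stop_bad_arg(sprintf("`%s` frequencies must lie strictly in (0,1)", name))
    }
    f
  }
  p_h <- expand_freq(freq_h, "freq_h")
  p_o <- expand_freq(freq_o, "freq_o")

  if (is.null(map)) {
    map <- random_snp_map(n_snp, chrom_lengths)
  } else {
    map <- as_tibble(map)
    if (nrow(map) != n_snp) stop_bad_arg("map must have n_snp rows")
  }
  n_animal <- nrow(ped)
  h_frac <- breed$h_fraction[match(ped$animal, breed$animal)]
  if (anyNA(h_frac)) stop_bad_arg("breed fractions missing for some animals")

  # two allele matrices (0/1 = first/second allele), animals x snp
  a1 <- matrix(0L, n_animal, n_snp)
  a2 <- matrix(0L, n_animal, n_snp)
  pos_of <- match(ped$animal, ped$animal)
  sire_row <- match(ped$sire, ped$animal)
  dam_row <- match(ped$dam, ped$animal)
  for (i in seq_len(n_animal)) {
    if (ped$sire[i] == 0L && ped$dam[i] == 0L) {
      # founder: each allele from H pool w.p. h_frac, else O pool
      from_h1 <- runif(n_snp) < h_frac[i]
      from_h2 <- runif(n_snp) < h_frac[i]
      p1 <- ifelse(from_h1, p_h, p_o)
      p2 <- ifelse(from_h2, p_h, p_o)
      a1[i, ] <- as.integer(runif(n_snp) < p1)
      a2[i, ] <- as.integer(runif(n_snp) < p2)
    } else {
      a1[i, ] <- transmit_allele(a1[sire_row[i], ], a2[sire_row[i], ])
      a2[i, ] <- transmit_allele(a1[dam_row[i], ], a2[dam_row[i], ])
    }
  }
  codes <- a1 + a2
  if (any(missing_rate > 0)) {
    rate <- matrix(rep_len(missing_rate, n_snp), n_animal, n_snp, byrow = TRUE)
    codes[runif(length(codes)) < rate] <- NA_integer_
  }
  rownames(codes) <- ped$animal
  snp_geno(codes, map)
}

transmit_allele <- function(parent_a1, parent_a2) {
  pick_first <- runif(length(parent_a1)) < 0.5
  ifelse(pick_first, parent_a1, parent_a2)
}

random_snp_map <- function(n_snp, chrom_lengths) {
  chrom_lengths <- as.numeric(chrom_lengths)
  chroms <- names(chrom_lengths) %||% paste0("chr", seq_along(chrom_lengths))
  names(chrom_lengths) <- chroms
  n_per <- as.vector(stats::xtabs(~ factor(
    sample(chroms, n_snp, replace = TRUE, prob = chrom_lengths), levels = chroms)))
  rows <- purrr::map2(chroms, n_per, function(ch, k) {
    if (k == 0L) return(NULL)
    pos <- sort(sample.int(chrom_lengths[[ch]], k, replace = FALSE))
    tibble(chrom = ch, pos = pos)
  })
  map <- dplyr::bind_rows(rows)
  map$snp_id <- sprintf("snp%05d", seq_len(nrow(map)))
  map[, c("snp_id", "chrom", "pos")]
}

#' Gene-centric SNP map
#'
#' Emulates a gene-centric genotyping panel: a fraction of markers is
#' placed uniformly inside randomly chosen gene intervals, the rest
#' uniformly along the genome.
#'
#' @param n_snp Marker count.
#' @param chrom_lengths Chromosome lengths (bp), named.
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param genic_fraction Fraction of markers placed inside genes.
#' @param seed Integer seed.
#' @param tag_intervals Optional tibble (`chrom`, `pos`) of fixed marker
#'   positions always included (candidate-gene tag markers).
#' @return SNP map tibble (`snp_id`, `chrom`, `pos`), position-sorted
#'   within chromosome.
#' @export
gene_centric_map <- function(n_snp, chrom_lengths, annotation,
                             genic_fraction = 0.35, seed = 1L,
                             tag_intervals = NULL) {
  n_snp <- check_count(n_snp, "n_snp")
  genic_fraction <- check_prob(genic_fraction, "genic_fraction")
  withr_seed(seed)
  chroms <- names(chrom_lengths) %||% paste0("chr", seq_along(chrom_lengths))
  chrom_lengths <- setNames(as.numeric(chrom_lengths), chroms)
  n_tag <- if (is.null(tag_intervals)) 0L else nrow(tag_intervals)
  if (n_tag >= n_snp) stop_bad_arg("more tag markers than panel size")
  n_genic <- round(genic_fraction * (n_snp - n_tag))
  g_idx <- sample.int(nrow(annotation), n_genic, replace = TRUE)
  genic <- tibble(
    chrom = annotation$chrom[g_idx],
    pos = floor(annotation$start[g_idx] +
                  runif(n_genic) * (annotation$end[g_idx] -
                                      annotation$start[g_idx] + 1)))
  n_bg <- n_snp - n_genic - n_tag
  bg_chrom <- sample(chroms, n_bg, replace = TRUE, prob = chrom_lengths)
  background <- tibble(chrom = bg_chrom,
                       pos = floor(runif(n_bg) * chrom_lengths[bg_chrom]) + 1)
  tags <- if (n_tag > 0L) tag_intervals[, c("chrom", "pos")] else NULL
  map <- dplyr::bind_rows(tags, genic, background) |>
    dplyr::distinct(.data$chrom, .data$pos) |>
    dplyr::arrange(.data$chrom, .data$pos)
  # deduplication may drop a few positions; top up uniformly
  while (nrow(map) < n_snp) {
    extra_chrom <- sample(chroms, n_snp - nrow(map), replace = TRUE,
                          prob = chrom_lengths)
    extra <- tibble(chrom = extra_chrom,
                    pos = floor(runif(length(extra_chrom)) *
                                  chrom_lengths[extra_chrom]) + 1)
    map <- dplyr::bind_rows(map, extra) |>
      dplyr::distinct(.data$chrom, .data$pos) |>
      dplyr::arrange(.data$chrom, .data$pos)
  }
  map$snp_id <- sprintf("snp%05d", seq_len(nrow(map)))
  map[, c("snp_id", "chrom", "pos")]
}
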