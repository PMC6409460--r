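# shared fixtures and independent oracles

# hand-specified pedigree: tibble from (animal, sire, dam) triples
ped_tbl <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(animal = as.integer(m[, 1]), sire = as.integer(m[, 2]),
                 dam = as.integer(m[, 3]))
}

# two founders + one offspring
ped_trio <- function() ped_tbl(1, 0, 0, 2, 0, 0, 3, 1, 2)

# founders 1,2; full sibs 3,4
ped_fullsibs <- function() ped_tbl(1, 0, 0, 2, 0, 0, 3, 1, 2, 4, 1, 2)

# parent-offspring mating: 4 = 1 x 3, F_4 = 0.25
ped_inbred <- function() ped_tbl(1, 0, 0, 2, 0, 0, 3, 1, 2, 4, 1, 3)

# independent oracle: numerator relationship by direct recursion
# (all values are dyadic rationals, so double arithmetic is exact)
recursive_A <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal)
  d <- match(ped$dam, ped$animal)
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i == j) {
      si <- s[i]; di <- d[i]
      f <- if (!is.na(si) && !is.na(di)) a(si, di) / 2 else 0
      return(1 + f)
    }
    if (i > j) { tmp <- i; i <- j; j <- tmp }      # ensure j later-born
    sj <- s[j]; dj <- d[j]
    v <- 0
    if (!is.na(sj)) v <- v + a(i, sj)
    if (!is.na(dj)) v <- v + a(i, dj)
    v / 2
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- a(i, j)
  dimnames(out) <- list(ped$animal, ped$animal)
  out
}

# random valid pedigree of at most n_max animals, optionally with
# parent-offspring / sib matings (inbreeding loops)
random_pedigree <- function(n_max, inbred = TRUE) {
  n_founders <- sample(2:4, 1)
  animal <- seq_len(n_founders)
  sire <- dam <- rep(0L, n_founders)
  while (length(animal) < n_max) {
    id <- length(animal) + 1L
    pool <- seq_len(id - 1L)
    if (length(pool) < 2L) break
    pair <- if (inbred) sample(pool, 2L) else {
      # prefer unrelated-ish: founders
      sample(pool, 2L)
    }
    animal <- c(animal, id)
    sire <- c(sire, pair[1]); dam <- c(dam, pair[2])
  }
  tibble::tibble(animal = as.integer(animal), sire = as.integer(sire),
                 dam = as.integer(dam))
}

# small simulated population with records on every animal
small_population <- function(n_founders = 20, n_gen = 2, n_per = 30,
                             n_hys = 3, truth = sim_truth(), seed = 42,
                             n_snp = 0) {
  ped <- simulate_pedigree(n_founders, n_gen, n_per, seed = seed)
  fh <- setNames(rep(c(1, 0, 0.5, 1), length.out = n_founders),
                 seq_len(n_founders))
  breed <- assign_breed_fractions(ped, fh)
  geno <- if (n_snp > 0) {
    simulate_genotypes(ped, breed, n_snp, c(chr1 = 5e7), seed = seed + 1)
  } else NULL
  phen <- simulate_phenotypes(ped, breed, geno, truth, n_hys = n_hys,
                              seed = seed + 2)
  list(ped = ped, breed = breed, geno = geno, records = phen$records,
       bv = phen$bv, truth = truth,
       design = build_design(phen$records, ped, breed))
}

# independent oracle: right-tail hypergeometric by exhaustive subset
# enumeration (tally of overlap sizes over all n-subsets of 1..N)
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)     # pathway = first K labels
  mean(overlaps >= k)
}

expect_monotone_loglik <- function(trace, tol = NULL) {
  ll <- trace$loglik[is.finite(trace$loglik)]
  if (is.null(tol)) tol <- 1e-7 * (1 + max(abs(ll)))
  expect_true(all(diff(ll) >= -tol))
}
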