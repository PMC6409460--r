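# Pedigree and breed-composition simulation for a two-pool admixed population.

#' Simulate a non-overlapping-generation pedigree
#'
#' Generates a pedigree of `n_founders` unrelated founders followed by
#' `n_generations` discrete generations.  Each generation's offspring are
#' produced by random unions of two distinct animals drawn from the previous
#' generation (no selection, no overlapping generations, no selfing).
#'
#' @param n_founders Number of founder animals (>= 2).
#' @param n_generations Number of offspring generations (>= 1).
#' @param n_per_generation Offspring produced in each generation.  A single
#'   count (recycled) or a vector of length `n_generations`.
#' @param seed Integer seed; the same seed reproduces the pedigree exactly.
#'
#' @return A tibble with columns `animal`, `sire`, `dam` (integer ids, 0 =
#'   unknown parent) and `generation`, in topological order: every parent
#'   appears before any of its offspring.
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              n_per_generation = n_founders, seed = 1L) {
  n_founders <- check_count(n_founders, "n_founders", min = 2L)
  n_generations <- check_count(n_generations, "n_generations", min = 1L)
  n_per_generation <- vapply(n_per_generation, check_count, integer(1),
                             name = "n_per_generation")
  n_per_generation <- rep_len(n_per_generation, n_generations)

  withr_seed(seed)
  records <- list(tibble(animal = seq_len(n_founders), sire = 0L, dam = 0L,
                         generation = 0L))
  prev <- seq_len(n_founders)
  next_id <- n_founders + 1L
  for (g in seq_len(n_generations)) {
    n_off <- n_per_generation[g]
    sires <- integer(n_off)
    dams <- integer(n_off)
    for (k in seq_len(n_off)) {
      pair <- sample(prev, 2L, replace = FALSE)  # distinct: no selfing
      sires[k] <- pair[1L]
      dams[k] <- pair[2L]
    }
    ids <- seq.int(next_id, length.out = n_off)
    records[[g + 1L]] <- tibble(animal = ids, sire = sires, dam = dams,
                                generation = g)
    prev <- ids
    next_id <- next_id + n_off
  }
  ped <- dplyr::bind_rows(records)
  validate_pedigree(ped)
  ped
}

# deterministic local RNG scope: set seed without clobbering caller state
withr_seed <- function(seed) {
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  invisible(seed)
}

#' Validate pedigree structure
#'
#' Checks that a pedigree table is topologically ordered (parents precede
#' offspring), acyclic, and that every named parent exists.
#'
#' @param ped Tibble/data frame with integer columns `animal`, `sire`, `dam`
#'   (0 = unknown parent).
#' @return `ped` invisibly; errors if the structure is invalid.
#' @export
validate_pedigree <- function(ped) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop_bad_arg("pedigree must have columns animal, sire, dam")
  }
  if (anyDuplicated(ped$animal)) stop_structural("duplicate animal ids in pedigree")
  pos <- match(ped$animal, ped$animal)
  sire_pos <- match(ped$sire, ped$animal)
  dam_pos <- match(ped$dam, ped$animal)
  known_sire <- ped$sire != 0L
  known_dam <- ped$dam != 0L
  if (any(known_sire & is.na(sire_pos)) || any(known_dam & is.na(dam_pos))) {
    stop_structural("pedigree names a parent with no record")
  }
  # topological order implies acyclicity (no animal can be its own ancestor)
  if (any(known_sire & sire_pos >= pos, na.rm = TRUE) ||
      any(known_dam & dam_pos >= pos, na.rm = TRUE)) {
    stop_structural("pedigree is not topologically ordered (parent after offspring)")
  }
  if (any(ped$sire == ped$animal | ped$dam == ped$animal)) {
    stop_structural("animal recorded as its own parent")
  }
  invisible(ped)
}

#' Assign breed fractions down a pedigree
#'
#' Founders get the fractions supplied in `founder_h`; every non-founder's
#' expected H (e.g. Holstein) fraction is the mean of its parents' fractions,
#' and the O ("other breeds") fraction is its complement.
#'
#' @param ped Pedigree tibble (topological order, see [simulate_pedigree()]).
#' @param founder_h Named numeric vector mapping founder animal id to its H
#'   fraction in \[0,1\]; every founder must be present.
#' @return Tibble with columns `animal`, `h_fraction`, `o_fraction`.
#' @export
assign_breed_fractions <- function(ped, founder_h) {
  validate_pedigree(ped)
  founders <- ped$animal[ped$sire == 0L & ped$dam == 0L]
  fh <- founder_h[as.character(founders)]
  if (anyNA(fh)) {
    stop_bad_arg("every founder must have an entry in `founder_h`")
  }
  if (any(fh < 0 | fh > 1)) stop_bad_arg("founder H fractions must lie in [0,1]")
  h <- setNames(rep(NA_real_, nrow(ped)), as.character(ped$animal))
  h[as.character(founders)] <- as.numeric(fh)
  for (i in seq_len(nrow(ped))) {
    if (ped$sire[i] != 0L || ped$dam[i] != 0L) {
      if (ped$sire[i] == 0L || ped$dam[i] == 0L) {
        stop_bad_arg("animals with exactly one known parent are not supported")
      }
      hs <- h[as.character(ped$sire[i])]
      hd <- h[as.character(ped$dam[i])]
      h[i] <- (hs + hd) / 2
    }
  }
  tibble(animal = ped$animal, h_fraction = unname(h),
         o_fraction = 1 - unname(h))
}
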