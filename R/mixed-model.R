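# Model design and Henderson mixed-model equations for the 3-trait
# genomic-polygenic model: fixed herd-year-season, breed (O-fraction)
# regression and heterosis (heterozygosity) regression; random animal
# additive genetic (var H x Va, Kronecker) and residual (var I x Ve).

#' Expected heterozygosity of a mating
#'
#' For a two-pool (H and O) admixed population, the expected fraction of
#' loci carrying one allele from each pool in the offspring of a sire with
#' fractions (sire_h, sire_o) and a dam with (dam_h, dam_o):
#' `sire_h * dam_o + sire_o * dam_h`.
#'
#' @param sire_h,sire_o,dam_h,dam_o Breed fractions; each parent's pair must
#'   sum to 1.  Vectorized.
#' @return Numeric vector of heterozygosity values in \[0,1\].
#' @export
heterozygosity <- function(sire_h, sire_o, dam_h, dam_o) {
  if (any(abs(sire_h + sire_o - 1) > 1e-8) ||
      any(abs(dam_h + dam_o - 1) > 1e-8)) {
    stop_bad_arg("each parent's breed fractions must sum to 1")
  }
  sire_h * dam_o + sire_o * dam_h
}

#' Per-animal heterozygosity covariate
#'
#' Non-founders use the parental-fraction formula of [heterozygosity()];
#' animals with unknown parents fall back to the Hardy-Weinberg expectation
#' `2 * h * o` of their own fractions.
#'
#' @param ped Pedigree tibble.
#' @param breed Breed-fraction tibble ([assign_breed_fractions()]).
#' @return Tibble `animal`, `heterozygosity`.
#' @export
animal_heterozygosity <- function(ped, breed) {
  validate_pedigree(ped)
  h <- breed$h_fraction[match(ped$animal, breed$animal)]
  o <- breed$o_fraction[match(ped$animal, breed$animal)]
  hs <- h[match(ped$sire, ped$animal)]
  hd <- h[match(ped$dam, ped$animal)]
  het <- ifelse(is.na(hs) | is.na(hd),
                2 * h * o,
                hs * (1 - hd) + (1 - hs) * hd)
  tibble(animal = ped$animal, heterozygosity = het)
}

#' Build the model design for the multi-trait genomic-polygenic model
#'
#' Assembles the response matrix, the fixed-effect design (herd-year-season
#' classes with a drop-first-level constraint, O-fraction breed regression,
#' heterozygosity regression) and the record-to-animal mapping.  Covariates
#' that are constant across records are dropped (they are confounded with
#' the class effects).
#'
#' @param records Tibble with `animal`, `hys`, and one column per trait
#'   (default traits `MY`, `FY`, `AFC`); NA = missing trait value.
#' @param ped Pedigree tibble; every record's animal must appear in it.
#' @param breed Breed-fraction tibble.
#' @param traits Character vector of trait column names.
#' @return An object of class `ssgwas_design`: list with `y` (records x
#'   traits), `X` (fixed design), `animal_idx` (row in `ped` per record),
#'   `obs` (logical observed-trait matrix), `traits`, `animal_ids`.
#' @export
build_design <- function(records, ped, breed, traits = c("MY", "FY", "AFC")) {
  validate_pedigree(ped)
  if (!all(c("animal", "hys") %in% names(records))) {
    stop_bad_arg("records need columns `animal` and `hys`")
  }
  if (!all(traits %in% names(records))) {
    stop_bad_arg("records are missing trait columns")
  }
  if (anyDuplicated(records$animal)) {
    stop_bad_arg("exactly one record per phenotyped animal is expected")
  }
  idx <- match(records$animal, ped$animal)
  if (anyNA(idx)) stop_bad_arg("records refer to animals absent from the pedigree")

  y <- as.matrix(records[traits])
  storage.mode(y) <- "double"
  obs <- !is.na(y)
  if (any(rowSums(obs) == 0L)) {
    stop_bad_arg("records with all traits missing are not allowed")
  }

  o_frac <- breed$o_fraction[match(records$animal, breed$animal)]
  het <- animal_heterozygosity(ped, breed)
  het_cov <- het$heterozygosity[idx]
  if (anyNA(o_frac) || anyNA(het_cov)) {
    stop_bad_arg("breed fractions missing for some recorded animals")
  }

  df <- tibble(hys = factor(records$hys), o_fraction = o_frac,
               heterozygosity = het_cov)
  # single HYS class collapses to an intercept-equivalent column
  terms <- if (nlevels(df$hys) > 1L) "hys" else "1"
  if (stats::sd(df$o_fraction) > 1e-12) terms <- c(terms, "o_fraction")
  if (stats::sd(df$heterozygosity) > 1e-12) terms <- c(terms, "heterozygosity")
  X <- stats::model.matrix(stats::reformulate(terms), data = df)
  structure(list(y = y, X = X, animal_idx = idx, obs = obs, traits = traits,
                 animal_ids = ped$animal, records = records$animal),
            class = "ssgwas_design")
}

#' @exportS3Method base::print
print.ssgwas_design <- function(x, ...) {
  cat(sprintf("<ssgwas_design> %d records, %d traits (%s), %d fixed-effect columns\n",
              nrow(x$y), length(x$traits), paste(x$traits, collapse = ", "),
              ncol(x$X)))
  invisible(x)
}

# symmetric basis matrices for the free parameters of a t x t covariance
vech_basis <- function(t) {
  ij <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(ij)), function(k) {
    e <- matrix(0, t, t)
    e[ij[k, 1], ij[k, 2]] <- e[ij[k, 2], ij[k, 1]] <- 1
    e
  })
}

vech <- function(m) m[lower.tri(m, diag = TRUE)]

unvech <- function(v, t) {
  m <- matrix(0, t, t)
  m[lower.tri(m, diag = TRUE)] <- v
  m + t(m) - diag(diag(m), t)
}

#' Solve Henderson's mixed-model equations
#'
#' Solves the multi-trait MME for fixed effects and genomic estimated
#' breeding values (GEBVs) of every pedigree animal, genotyped or not:
#' `var(u) = H x Va` (Kronecker, animal-major ordering) and record-level
#' residual covariance `Ve` restricted to each record's observed traits.
#'
#' @param design [build_design()] output.
#' @param H_inv Inverse relationship matrix: the list from [build_H_inv()],
#'   or a matrix with animal ids as dimnames covering all pedigree animals.
#' @param vc List with positive-definite `Va` and `Ve` (t x t).
#' @return Object of class `ssgwas_mme`: list with `fixed` (tibble of
#'   per-trait fixed-effect estimates), `gebv` (tibble animal x trait),
#'   `b`, `u` (raw vectors) and `traits`.
#' @export
solve_mme <- function(design, H_inv, vc) {
  stopifnot(inherits(design, "ssgwas_design"))
  Hi <- as_hinv_matrix(H_inv, design$animal_ids)
  Va <- vc$Va; Ve <- vc$Ve
  t_n <- length(design$traits)
  if (!is_spd(Va) || !is_spd(Ve)) stop_bad_arg("Va and Ve must be symmetric positive definite")
  Va_inv <- chol2inv(chol(symmpart_dense(Va)))

  X <- design$X; y <- design$y; obs <- design$obs
  n_rec <- nrow(y); p <- ncol(X); q <- length(design$animal_ids)
  nb <- t_n * p
  nu <- t_n * q

  # accumulate the MME blocks record by record (obs-trait subsetting of Ve)
  Cxx <- matrix(0, nb, nb); Cxu <- matrix(0, nb, nu)
  rx <- numeric(nb); ru <- numeric(nu)
  Cuu_data <- matrix(0, nu, nu)
  for (i in seq_len(n_rec)) {
    oi <- which(obs[i, ])
    Ri <- solve(Ve[oi, oi, drop = FALSE])
    xi <- X[i, ]
    a <- design$animal_idx[i]
    # expand Ri to full t x t with zeros at unobserved traits
    Rfull <- matrix(0, t_n, t_n)
    Rfull[oi, oi] <- Ri
    yi <- y[i, ]; yi[!obs[i, ]] <- 0
    # trait-major fixed blocks: column (m-1)*p + j for trait m, covariate j
    XtRX <- kronecker(Rfull, tcrossprod(xi))
    Cxx <- Cxx + XtRX
    ucols <- (a - 1L) * t_n + seq_len(t_n)
    Cxu[, ucols] <- Cxu[, ucols] + kronecker(Rfull, xi)
    Cuu_data[ucols, ucols] <- Cuu_data[ucols, ucols] + Rfull
    rx <- rx + as.vector(kronecker(Rfull %*% yi, xi))
    ru[ucols] <- ru[ucols] + Rfull %*% yi
  }
  Guu <- kronecker(Hi, Va_inv)
  C <- rbind(cbind(Cxx, Cxu), cbind(t(Cxu), Cuu_data + Guu))
  rhs <- c(rx, ru)
  sol <- tryCatch(solve(symmpart_dense(C), rhs),
                  error = function(e) stop_structural(
                    paste("singular mixed-model coefficient matrix:", conditionMessage(e))))
  b <- sol[seq_len(nb)]
  u <- sol[-seq_len(nb)]
  gebv <- tibble(
    animal = rep(design$animal_ids, each = t_n),
    trait = rep(design$traits, times = q),
    gebv = u
  )
  fixed <- tibble(
    trait = rep(design$traits, each = p),
    term = rep(colnames(X), times = t_n),
    estimate = b
  )
  structure(list(fixed = fixed, gebv = gebv, b = b, u = u,
                 traits = design$traits, animal_ids = design$animal_ids),
            class = "ssgwas_mme")
}

#' @exportS3Method base::print
print.ssgwas_mme <- function(x, ...) {
  cat(sprintf("<ssgwas_mme> %d animals x %d traits; %d fixed-effect estimates\n",
              length(x$animal_ids), length(x$traits), length(x$b)))
  invisible(x)
}

#' GEBVs in wide (animals x traits) form
#'
#' @param mme [solve_mme()] result.
#' @return Tibble with `animal` and one column per trait.
#' @export
gebv_wide <- function(mme) {
  tidyr::pivot_wider(mme$gebv, names_from = "trait", values_from = "gebv")
}

as_hinv_matrix <- function(H_inv, animal_ids) {
  m <- if (is.list(H_inv) && !is.null(H_inv$H_inv)) H_inv$H_inv else as.matrix(H_inv)
  ids <- as.character(animal_ids)
  if (is.null(rownames(m))) {
    if (nrow(m) != length(ids)) stop_bad_arg("H_inv dimension does not match pedigree")
    dimnames(m) <- list(ids, ids)
    return(m)
  }
  if (!all(ids %in% rownames(m))) stop_bad_arg("H_inv is missing some pedigree animals")
  m[ids, ids, drop = FALSE]
}
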