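# Phenotype simulation under the genomic-polygenic model, plus the
# test-interval computation of 305-day lactation yields.

#' Ground-truth parameter container for simulation
#'
#' @param Va,Ve Symmetric positive-definite t x t covariance matrices among
#'   the traits (defaults emulate a tropical multibreed dairy population:
#'   305-d milk yield in kg, 305-d fat yield in kg, age at first calving in
#'   days, with moderate heritabilities and positive MY-FY correlation).
#' @param qtl_ids Character vector of SNP ids acting as QTL (may be empty).
#' @param qtl_effects Numeric matrix, one row per QTL, one column per trait:
#'   allele-substitution effect per copy of the second allele.
#' @param hys_effects Optional numeric matrix (classes x traits) of
#'   herd-year-season effects; drawn at simulation time if NULL.
#' @param b_breed,b_het Per-trait regression coefficients on the O fraction
#'   and on heterozygosity.
#' @param traits Trait names.
#' @return List of class `sim_truth`.
#' @export
sim_truth <- function(Va = default_Va(), Ve = default_Ve(),
                      qtl_ids = character(), qtl_effects = NULL,
                      hys_effects = NULL,
                      b_breed = c(-400, -15, 30), b_het = c(250, 9, -20),
                      traits = c("MY", "FY", "AFC")) {
  # positive *semi*-definite allowed: zero matrices are legitimate degenerate
  # simulation settings (no polygene / no residual noise)
  check_psd <- function(m, name) {
    if (!isSymmetric(unname(m), tol = 1e-8)) {
      stop_bad_arg(sprintf("%s must be symmetric", name))
    }
    ev <- eigen(symmpart_dense(m), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop_bad_arg(sprintf("%s must be positive semi-definite", name))
    }
  }
  check_psd(Va, "Va"); check_psd(Ve, "Ve")
  if (length(qtl_ids) > 0L) {
    qtl_effects <- as.matrix(qtl_effects)
    if (nrow(qtl_effects) != length(qtl_ids) || ncol(qtl_effects) != nrow(Va)) {
      stop_bad_arg("qtl_effects must be one row per QTL, one column per trait")
    }
  }
  structure(list(Va = Va, Ve = Ve, qtl_ids = qtl_ids,
                 qtl_effects = qtl_effects, hys_effects = hys_effects,
                 b_breed = b_breed, b_het = b_het, traits = traits),
            class = "sim_truth")
}

# default study-scale covariances: h2 ~ 0.25 (MY), 0.25 (FY), 0.15 (AFC);
# genetic correlations MY-FY 0.75, MY-AFC -0.3, FY-AFC -0.25
#' @rdname sim_truth
#' @export
default_Va <- function() {
  sd_a <- c(MY = 400, FY = 15, AFC = 45)
  cor_a <- matrix(c(1, 0.75, -0.30,
                    0.75, 1, -0.25,
                    -0.30, -0.25, 1), 3, 3,
                  dimnames = list(names(sd_a), names(sd_a)))
  diag(sd_a) %*% cor_a %*% diag(sd_a)
}

#' @rdname sim_truth
#' @export
default_Ve <- function() {
  sd_e <- c(MY = 690, FY = 26, AFC = 107)
  cor_e <- matrix(c(1, 0.55, -0.10,
                    0.55, 1, -0.08,
                    -0.10, -0.08, 1), 3, 3,
                  dimnames = list(names(sd_e), names(sd_e)))
  diag(sd_e) %*% cor_e %*% diag(sd_e)
}

#' Simulate correlated trait records
#'
#' Phenotypes follow the fitted model: herd-year-season class effect, breed
#' regression on the O fraction, heterosis regression on heterozygosity, QTL
#' effects (sum of centered genotype codes times allele-substitution
#' effects), a polygenic breeding value drawn from `N(0, A x Va)`, and a
#' residual from `N(0, I x Ve)`.
#'
#' @param ped Pedigree tibble.
#' @param breed Breed-fraction tibble.
#' @param geno [snp_geno()] object (only needed when `truth` has QTL).
#' @param truth [sim_truth()] object.
#' @param n_hys Number of herd-year-season classes; records are assigned to
#'   classes cyclically (balanced design).
#' @param phenotyped Animal ids to phenotype (default: every animal).
#' @param seed Integer seed.
#' @param A Optional precomputed pedigree relationship matrix (its lower
#'   Cholesky-type factor is cached as attribute `"chol_factor"` across
#'   calls when supplied).
#' @return List with `records` (tibble: animal, hys, one column per trait),
#'   `bv` (true breeding values incl. QTL, animals x traits) and `truth`.
#' @export
simulate_phenotypes <- function(ped, breed, geno = NULL, truth = sim_truth(),
                                n_hys = 5L, phenotyped = ped$animal,
                                seed = 1L, A = NULL) {
  validate_pedigree(ped)
  stopifnot(inherits(truth, "sim_truth"))
  n_hys <- check_count(n_hys, "n_hys")
  withr_seed(seed)
  t_n <- nrow(truth$Va)
  traits <- truth$traits

  n <- nrow(ped)
  if (is.null(A)) A <- build_A(ped)
  La <- attr(A, "chol_factor") %||%
    t(chol(symmpart_dense(A) + diag(1e-10, n)))
  Lva <- psd_factor(truth$Va)
  # polygenic breeding values: vec ~ N(0, A x Va), animal-major
  Zn <- matrix(rnorm(n * t_n), n, t_n)
  bv_poly <- La %*% Zn %*% t(Lva)

  bv_qtl <- matrix(0, n, t_n)
  if (length(truth$qtl_ids) > 0L) {
    if (is.null(geno)) stop_bad_arg("genotypes required when truth has QTL")
    if (!all(truth$qtl_ids %in% geno$map$snp_id)) {
      stop_bad_arg("QTL ids absent from the genotype map")
    }
    codes <- geno$codes[as.character(ped$animal), truth$qtl_ids, drop = FALSE]
    storage.mode(codes) <- "double"
    p_qtl <- colMeans(codes, na.rm = TRUE) / 2
    zq <- sweep(codes, 2L, 2 * p_qtl, "-")
    zq[is.na(zq)] <- 0
    bv_qtl <- zq %*% truth$qtl_effects
  }
  bv <- bv_poly + bv_qtl

  keep <- match(phenotyped, ped$animal)
  if (anyNA(keep)) stop_bad_arg("phenotyped ids must be pedigree animals")
  n_rec <- length(keep)
  hys <- rep_len(sprintf("hys%02d", seq_len(n_hys)), n_rec)
  hys_eff <- truth$hys_effects
  if (is.null(hys_eff)) {
    # deterministic balanced class effects, half a residual SD apart
    lev <- seq_len(n_hys) - (n_hys + 1) / 2
    hys_eff <- outer(lev, sqrt(diag(truth$Ve)) / 2)
  }
  Lve <- psd_factor(truth$Ve)
  e <- matrix(rnorm(n_rec * t_n), n_rec, t_n) %*% t(Lve)

  o_frac <- breed$o_fraction[match(ped$animal[keep], breed$animal)]
  het <- animal_heterozygosity(ped, breed)$heterozygosity[keep]
  hys_idx <- as.integer(factor(hys, levels = sprintf("hys%02d", seq_len(n_hys))))
  y <- hys_eff[hys_idx, , drop = FALSE] +
    outer(o_frac, truth$b_breed) + outer(het, truth$b_het) +
    bv[keep, , drop = FALSE] + e
  colnames(y) <- traits
  records <- tibble(animal = ped$animal[keep], hys = hys)
  records <- dplyr::bind_cols(records, as_tibble(y))
  colnames(bv) <- traits
  list(records = records, bv = tibble(animal = ped$animal) |>
         dplyr::bind_cols(as_tibble(bv)),
       truth = truth)
}

# lower-triangular-like factor L with LL' = m, valid for PSD m (eigen route)
psd_factor <- function(m) {
  eg <- eigen(symmpart_dense(m), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(ev), nrow(m))
}

#' 305-day yield by the test-interval method
#'
#' Accumulates, over consecutive pairs of monthly test days, the interval
#' length times the mean of the two daily yields; the first interval is
#' projected back to day 0 at the first test's yield and the last interval
#' forward to the horizon at the last test's yield (ICAR convention).  The
#' fat-yield analogue uses daily fat yield = fat percentage times daily milk
#' yield per test day.
#'
#' @param test_days Strictly increasing day offsets within the lactation
#'   (1..horizon).
#' @param daily_yields Daily yields (kg/day) on those test days.
#' @param horizon Lactation length in days (default 305).
#' @return Cumulative yield in kg.
#' @export
test_interval_yield <- function(test_days, daily_yields, horizon = 305) {
  if (length(test_days) == 0L || length(test_days) != length(daily_yields)) {
    stop_bad_arg("test_days and daily_yields must be equal-length, non-empty")
  }
  if (any(diff(test_days) <= 0)) stop_bad_arg("test days must be strictly increasing")
  if (test_days[1] < 0 || utils::tail(test_days, 1) > horizon) {
    stop_bad_arg("test days must lie within the lactation")
  }
  k <- length(test_days)
  total <- test_days[1] * daily_yields[1]                 # day 0 projection
  if (k > 1L) {
    mids <- (daily_yields[-k] + daily_yields[-1]) / 2
    total <- total + sum(diff(test_days) * mids)
  }
  total + (horizon - test_days[k]) * daily_yields[k]      # horizon projection
}
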