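# Back-solving per-SNP allele-substitution effects from genotyped-animal
# GEBVs, per-SNP genetic-variance shares, and per-gene predicted SNP values.

#' Back-solve SNP effects from genomic breeding values
#'
#' Standard single-pass decomposition (identity SNP weight matrix):
#' `a_hat = Z' Gb^-1 u_hat / (2 sum_j p_j (1 - p_j))`, per trait.  Effects
#' are expressed per copy of the second allele, matching the Z coding.
#'
#' @param gebv Tibble of GEBVs for the genotyped animals in long form
#'   (`animal`, `trait`, `gebv`) or wide form (`animal` + one column per
#'   trait), e.g. from [solve_mme()] / [gebv_wide()].
#' @param geno [snp_geno()] object restricted to the genotyped animals
#'   (after QC).
#' @param G_b Blended/tuned genomic relationship matrix used in the fit.
#' @param p Allele frequencies used to center Z (same as in [build_G()]).
#' @return Tibble: `snp_id`, `chrom`, `pos`, `p`, then one effect column
#'   per trait (`effect_<trait>`).
#' @export
backsolve_effects <- function(gebv, geno, G_b, p = compute_allele_freqs(geno)) {
  stopifnot(inherits(geno, "snp_geno"))
  if ("gebv" %in% names(gebv)) {
    gebv <- tidyr::pivot_wider(gebv, names_from = "trait", values_from = "gebv")
  }
  ids <- rownames(geno$codes)
  gm <- as.matrix(gebv[match(ids, as.character(gebv$animal)),
                       setdiff(names(gebv), "animal"), drop = FALSE])
  if (anyNA(gm)) stop_bad_arg("GEBVs missing for some genotyped animals")
  if (!all(dim(G_b) == length(ids))) {
    stop_bad_arg("G_b dimension must match the genotyped animals")
  }
  z <- center_genotypes(geno, p)
  denom <- 2 * sum(p * (1 - p))
  sol <- solve(symmpart_dense(G_b), gm)           # Gb^-1 u, animals x traits
  eff <- crossprod(z, sol) / denom                # snp x traits
  colnames(eff) <- paste0("effect_", colnames(gm))
  map <- geno$map[match(names(p), geno$map$snp_id), ]
  dplyr::bind_cols(map, tibble(p = unname(p)), as_tibble(eff))
}

#' Per-SNP share of the genetic variance
#'
#' `v_j = 100 * 2 p_j (1 - p_j) a_hat_j^2 / sigma2_a(trait)`, the percentage
#' of a trait's additive genetic variance attributed to SNP j (analytic
#' single-SNP decomposition).  The empirical alternative replaces
#' `2p(1-p) a^2` by the variance of `Z_j a_j` across the genotyped animals.
#'
#' @param effects Tibble from [backsolve_effects()].
#' @param sigma2_a Named per-trait genetic variances (the REML `diag(Va)`).
#' @param method `"analytic"` (default) or `"empirical"`.
#' @param geno Genotypes; only needed for `method = "empirical"`.
#' @return `effects` with one `varpct_<trait>` column added per trait.
#' @export
variance_share <- function(effects, sigma2_a, method = c("analytic", "empirical"),
                           geno = NULL) {
  method <- match.arg(method)
  if (any(sigma2_a <= 0)) stop_bad_arg("per-trait genetic variances must be positive")
  eff_cols <- grep("^effect_", names(effects), value = TRUE)
  traits <- sub("^effect_", "", eff_cols)
  if (!all(traits %in% names(sigma2_a))) {
    stop_bad_arg("sigma2_a must be named by trait")
  }
  z <- if (method == "empirical") {
    if (is.null(geno)) stop_bad_arg("genotypes required for the empirical method")
    center_genotypes(geno, setNames(effects$p, effects$snp_id))
  } else NULL
  out <- effects
  for (i in seq_along(traits)) {
    a2 <- effects[[eff_cols[i]]]^2
    per_snp <- if (method == "analytic") {
      2 * effects$p * (1 - effects$p) * a2
    } else {
      unname(apply(sweep(z, 2L, effects[[eff_cols[i]]], "*"), 2L, stats::var))
    }
    out[[paste0("varpct_", traits[i])]] <- 100 * per_snp / sigma2_a[[traits[i]]]
  }
  out
}

#' Per-gene predicted SNP value
#'
#' For each gene and trait, the sum of the allele-substitution effects of
#' the SNP assigned to that gene; a SNP contributes once to every gene it
#' maps to.
#'
#' @param assignment Tibble from [assign_to_genes()] (columns `snp_id`,
#'   `gene_id`); typically pre-filtered to the enrichment-eligible classes.
#' @param effects Tibble from [backsolve_effects()] (optionally with
#'   variance shares).
#' @return Tibble: `gene_id`, per-trait `predicted_<trait>` sums and, when
#'   shares are present, per-trait `varpct_<trait>` sums plus `n_snp`.
#' @export
gene_predicted_value <- function(assignment, effects) {
  if (!all(assignment$snp_id %in% effects$snp_id)) {
    stop_bad_arg("assignment references SNP with no effect row")
  }
  eff_cols <- grep("^effect_", names(effects), value = TRUE)
  var_cols <- grep("^varpct_", names(effects), value = TRUE)
  joined <- dplyr::inner_join(
    assignment[, c("snp_id", "gene_id")],
    effects[, c("snp_id", eff_cols, var_cols)], by = "snp_id")
  out <- joined |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_snp = dplyr::n(),
                     dplyr::across(dplyr::all_of(c(eff_cols, var_cols)), sum),
                     .groups = "drop")
  names(out) <- sub("^effect_", "predicted_", names(out))
  out
}
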