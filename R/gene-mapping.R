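# Genotype QC, variance-threshold SNP selection, windowed SNP-to-gene
# assignment with distance bins, and trait-overlap (Venn) counts.

#' Genotype quality control
#'
#' Removes SNP with call rate below `min_call_rate` or minor allele
#' frequency below `min_maf` (both strict "lower than" rules; a SNP exactly
#' at a threshold is retained).  Animals are never removed.
#'
#' @param geno [snp_geno()] object.
#' @param min_call_rate Minimum fraction of non-missing calls (default 0.90).
#' @param min_maf Minimum minor allele frequency `min(p, 1-p)` (default 0.01).
#' @return Filtered [snp_geno()] with a `qc` attribute recording counts.
#' @export
qc_genotypes <- function(geno, min_call_rate = 0.90, min_maf = 0.01) {
  stopifnot(inherits(geno, "snp_geno"))
  min_call_rate <- check_prob(min_call_rate, "min_call_rate")
  min_maf <- check_prob(min_maf, "min_maf")
  call_rate <- colMeans(!is.na(geno$codes))
  p <- colMeans(geno$codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- call_rate >= min_call_rate & maf >= min_maf
  if (!any(keep)) stop_structural("quality control removed every SNP")
  out <- snp_geno(geno$codes[, keep, drop = FALSE], geno$map[keep, ])
  attr(out, "qc") <- list(n_input = ncol(geno$codes), n_kept = sum(keep),
                          n_callrate = sum(call_rate < min_call_rate),
                          n_maf = sum(maf < min_maf & call_rate >= min_call_rate))
  out
}

#' Select SNP by genetic-variance share
#'
#' Keeps SNP whose share of the trait's genetic variance is at least
#' `threshold` percent (boundary inclusive: "at least 0.001%").
#'
#' @param effects Tibble with `varpct_<trait>` columns ([variance_share()]).
#' @param trait Trait name.
#' @param threshold Minimum share in percent (default 0.001).
#' @return Character vector of retained SNP ids.
#' @export
filter_by_variance <- function(effects, trait, threshold = 0.001) {
  col <- paste0("varpct_", trait)
  if (!col %in% names(effects)) {
    stop_bad_arg(sprintf("no variance-share column for trait '%s'", trait))
  }
  effects$snp_id[effects[[col]] >= threshold]
}

distance_classes <- c("inside", "<=2500", "(2500,5000]", "(5000,25000]",
                      ">25000")

classify_distance <- function(d) {
  cut(d, breaks = c(-1, 0, 2500, 5000, 25000, Inf),
      labels = distance_classes)
}

#' Assign SNP to nearby genes
#'
#' Each SNP is matched to every gene on its chromosome whose interval
#' contains it (distance 0, class `inside`) or whose nearest edge lies
#' within `report_window` bp, binned as `<=2500`, `(2500,5000]`,
#' `(5000,25000]`; SNP matching nothing closer than 25,000 bp are reported
#' once with class `>25000` and the nearest gene (left-closed bin
#' convention at the shared edges).  Only `inside` and `<=2500` (more
#' generally distance <= `window`) are enrichment-eligible.  Many-to-many:
#' a SNP may map to several genes and a gene may collect many SNP.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos`.
#' @param annotation Tibble with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive; see [read_annotation()] for BED conversion).
#' @param window Enrichment-eligibility window in bp (default 2500,
#'   boundary inclusive).
#' @param report_window Largest binned distance (default 25000).
#' @return Tibble: `snp_id`, `gene_id`, `chrom`, `pos`, `distance`,
#'   `distance_class`, `eligible` (logical).  SNP on chromosomes absent
#'   from the annotation are flagged with `gene_id = NA`.
#' @export
assign_to_genes <- function(snps, annotation, window = 2500,
                            report_window = 25000) {
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snps))) stop_bad_arg("snps need snp_id, chrom, pos")
  if (nrow(snps) == 0L) {
    return(tibble(snp_id = character(), gene_id = character(),
                  chrom = character(), pos = numeric(), distance = numeric(),
                  distance_class = character(), eligible = logical()))
  }
  rows <- purrr::map(seq_len(nrow(snps)), function(i) {
    ch <- snps$chrom[i]; pos <- snps$pos[i]
    ann <- annotation[annotation$chrom == ch, ]
    if (nrow(ann) == 0L) {
      return(tibble(snp_id = snps$snp_id[i], gene_id = NA_character_,
                    chrom = ch, pos = pos, distance = NA_real_,
                    distance_class = NA_character_, eligible = FALSE))
    }
    d <- pmax(0, pmax(ann$start - pos, pos - ann$end))
    hit <- d <= report_window
    if (!any(hit)) {
      j <- which.min(d)
      return(tibble(snp_id = snps$snp_id[i], gene_id = ann$gene_id[j],
                    chrom = ch, pos = pos, distance = d[j],
                    distance_class = ">25000", eligible = FALSE))
    }
    tibble(snp_id = snps$snp_id[i], gene_id = ann$gene_id[hit],
           chrom = ch, pos = pos, distance = d[hit],
           distance_class = as.character(classify_distance(d[hit])),
           eligible = d[hit] <= window)
  })
  dplyr::bind_rows(rows)
}

#' Distance-bin summary per trait
#'
#' Counts SNP-gene assignments and sums variance shares by distance class,
#' the per-bin summary companion of the assignment table.
#'
#' @param assignment [assign_to_genes()] output.
#' @param effects Tibble with `varpct_<trait>` columns.
#' @return Tibble: `distance_class`, `n_assignments`, `n_snp`, per-trait
#'   summed shares over distinct SNP.
#' @export
distance_bin_summary <- function(assignment, effects) {
  var_cols <- grep("^varpct_", names(effects), value = TRUE)
  assignment |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::left_join(effects[, c("snp_id", var_cols)], by = "snp_id") |>
    dplyr::group_by(.data$distance_class) |>
    dplyr::summarise(
      n_assignments = dplyr::n(),
      n_snp = dplyr::n_distinct(.data$snp_id),
      dplyr::across(dplyr::all_of(var_cols),
                    ~ sum(.x[!duplicated(snp_id)])),
      .groups = "drop")
}

#' Trait-overlap (Venn) counts for three gene lists
#'
#' @param gene_lists Named list of three character vectors of gene ids.
#' @return Tibble with the seven Venn regions (`traits`, `n_genes`) plus
#'   per-multiplicity totals as attribute `by_multiplicity`.
#' @export
trait_overlap <- function(gene_lists) {
  if (length(gene_lists) != 3L) stop_bad_arg("exactly three gene lists expected")
  nm <- names(gene_lists) %||% paste0("trait", 1:3)
  all_genes <- unique(unlist(gene_lists))
  member <- vapply(gene_lists, function(g) all_genes %in% g,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1L, function(m) paste(nm[m], collapse = "+"))
  combos <- unlist(lapply(1:3, function(k) {
    utils::combn(nm, k, paste, collapse = "+")
  }))
  counts <- table(factor(key, levels = combos))
  out <- tibble(traits = combos, n_traits = nchar(gsub("[^+]", "", combos)) + 1L,
                n_genes = as.integer(counts))
  attr(out, "by_multiplicity") <- out |>
    dplyr::group_by(.data$n_traits) |>
    dplyr::summarise(n_genes = sum(.data$n_genes), .groups = "drop")
  out
}
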