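# Hypergeometric pathway over-representation with Bonferroni step-down
# (Holm) correction, and the per-pathway / per-category aggregation of
# variance shares and predicted SNP values.

#' Right-sided hypergeometric p-value
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` pathway genes when `n` query genes are sampled without
#' replacement from a universe of `N` genes of which `K` are in the pathway.
#'
#' @param k Observed overlap.
#' @param K Pathway size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return Probability in \[0,1\].  Vectorized.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(K, n) &
    k >= pmax(0, K + n - N)
  if (any(!ok)) stop_bad_arg("inconsistent hypergeometric counts")
  # right tail: stable log-gamma evaluation via phyper
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Holm (Bonferroni step-down) adjustment
#'
#' Sorted ascending, `adj_(i) = max_(j<=i) min(1, (m-j+1) p_(j))`, mapped
#' back to the input order.
#'
#' @param pvals Raw p-values in \[0,1\].
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric())
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    stop_bad_arg("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Pathway over-representation analysis
#'
#' Hypergeometric right-tail test of each pathway against the query gene
#' list, Holm-adjusted across the tested family, significance called at
#' `p_adjusted < alpha`.
#'
#' @param query_genes Character vector of query gene ids (intersected with
#'   the universe).
#' @param gene_sets Tibble `pathway_id`, `category`, `gene_id` (long form,
#'   e.g. [simulate_gene_sets()] or [read_gmt()]).
#' @param universe Universe gene ids.  Default: every gene belonging to at
#'   least one pathway.
#' @param alpha Family-wise significance level (default 0.05).
#' @param include_zero_overlap Keep pathways with no query hit in the
#'   adjustment family (default FALSE: they are reported with `p_raw = 1`
#'   but excluded from the Holm family).
#' @return Tibble, one row per pathway: `pathway_id`, `category`, `k`, `K`,
#'   `n`, `N`, `p_raw`, `p_adjusted`, `significant`, `hit_genes`
#'   (list-column).
#' @export
enrich <- function(query_genes, gene_sets, universe = NULL, alpha = 0.05,
                   include_zero_overlap = FALSE) {
  if (is.null(universe)) universe <- unique(gene_sets$gene_id)
  universe <- unique(universe)
  if (length(universe) == 0L) stop_bad_arg("empty gene universe")
  query <- unique(intersect(query_genes, universe))
  N <- length(universe)
  n <- length(query)
  res <- gene_sets |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::group_by(.data$pathway_id, .data$category) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$gene_id),
                     hit_genes = list(intersect(.data$gene_id, query)),
                     .groups = "drop") |>
    dplyr::mutate(k = lengths(.data$hit_genes), n = n, N = N,
                  p_raw = hypergeom_pvalue(.data$k, .data$K, n, N))
  fam <- if (include_zero_overlap) rep(TRUE, nrow(res)) else res$k > 0L
  res$p_adjusted <- NA_real_
  res$p_adjusted[fam] <- holm_adjust(res$p_raw[fam])
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res <- res[, c("pathway_id", "category", "k", "K", "n", "N", "p_raw",
                 "p_adjusted", "significant", "hit_genes")]
  class(res) <- c("ssgwas_enrichment", class(res))
  res
}

#' Aggregate gene-level statistics over pathways and categories
#'
#' Adds per-pathway sums of member-hit-gene variance shares and predicted
#' SNP values (per trait), then category subtotals and a grand total in
#' which each gene is counted once even when it belongs to several pathways
#' (union semantics).
#'
#' @param results [enrich()] output (typically filtered to significant
#'   pathways).
#' @param gene_stats Per-gene statistics from [gene_predicted_value()]
#'   (`gene_id`, `varpct_*`, `predicted_*`).
#' @return List with `pathways` (per-pathway rows), `categories` (per-
#'   category union totals) and `total` (grand union totals incl.
#'   `n_genes`).
#' @export
aggregate_pathway_stats <- function(results, gene_stats) {
  stat_cols <- grep("^(varpct|predicted)_", names(gene_stats), value = TRUE)
  sum_over <- function(genes) {
    gs <- gene_stats[gene_stats$gene_id %in% genes, , drop = FALSE]
    missing <- setdiff(genes, gs$gene_id)
    if (length(missing) > 0L) {
      stop_bad_arg(sprintf("no gene-level statistics for: %s",
                           paste(head(missing, 5), collapse = ", ")))
    }
    c(n_genes = length(unique(gs$gene_id)),
      colSums(gs[, stat_cols, drop = FALSE]))
  }
  per_path <- purrr::map(results$hit_genes, sum_over)
  pathways <- dplyr::bind_cols(
    results[, setdiff(names(results), "hit_genes")],
    as_tibble(do.call(rbind, per_path)))
  cat_tbl <- results |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(genes = list(unique(unlist(.data$hit_genes))),
                     .groups = "drop")
  categories <- dplyr::bind_cols(
    cat_tbl[, "category"],
    as_tibble(do.call(rbind, purrr::map(cat_tbl$genes, sum_over))))
  total <- as_tibble(as.list(sum_over(unique(unlist(results$hit_genes)))))
  list(pathways = pathways, categories = categories, total = total)
}
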