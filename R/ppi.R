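# Confidence-filtered protein-protein interaction network and degree
# statistics over the enriched-pathway genes.

#' Build a confidence-filtered interaction network
#'
#' Keeps edges with confidence strictly above `threshold` (the STRING
#' "high confidence" convention: an edge at exactly the threshold is
#' dropped), removes self-loops, merges duplicate unordered pairs keeping
#' the maximum confidence, and restricts to `nodes` when given.
#'
#' @param edges Tibble `gene_a`, `gene_b`, `confidence` in \[0,1\].
#' @param threshold Strict lower bound on confidence (default 0.7).
#' @param nodes Optional gene ids to which the network is restricted (both
#'   endpoints must be members), e.g. the enriched-pathway genes.
#' @param keep_isolated Include nodes with no retained edge (default FALSE:
#'   the node set is the endpoints of the retained edges).
#' @return Object of class `ssgwas_ppi`: list with `edges` (tibble),
#'   `nodes` (character), `graph` (igraph object).
#' @export
filter_ppi_edges <- function(edges, threshold = 0.7, nodes = NULL,
                             keep_isolated = FALSE) {
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% names(edges))) {
    stop_bad_arg("edges need gene_a, gene_b, confidence")
  }
  if (any(is.na(edges$gene_a) | is.na(edges$gene_b))) {
    stop_bad_arg("malformed edge: missing endpoint")
  }
  if (any(edges$confidence < 0 | edges$confidence > 1, na.rm = TRUE)) {
    stop_bad_arg("confidences must lie in [0,1]")
  }
  kept <- edges |>
    dplyr::filter(.data$confidence > threshold,
                  .data$gene_a != .data$gene_b)
  if (!is.null(nodes)) {
    kept <- dplyr::filter(kept, .data$gene_a %in% nodes,
                          .data$gene_b %in% nodes)
  }
  # canonical unordered pair, max confidence on duplicates
  kept <- if (nrow(kept) == 0L) {
    tibble(gene_a = character(), gene_b = character(), confidence = numeric())
  } else kept |>
    dplyr::mutate(lo = pmin(.data$gene_a, .data$gene_b),
                  hi = pmax(.data$gene_a, .data$gene_b)) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::rename(gene_a = "lo", gene_b = "hi")
  node_set <- sort(unique(c(kept$gene_a, kept$gene_b)))
  if (keep_isolated && !is.null(nodes)) node_set <- sort(unique(c(node_set, nodes)))
  g <- igraph::graph_from_data_frame(
    kept, directed = FALSE,
    vertices = data.frame(name = node_set, stringsAsFactors = FALSE))
  structure(list(edges = kept, nodes = node_set, graph = g,
                 threshold = threshold),
            class = "ssgwas_ppi")
}

#' @exportS3Method base::print
print.ssgwas_ppi <- function(x, ...) {
  cat(sprintf("<ssgwas_ppi> %d nodes, %d edges (confidence > %.2f)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Degree statistics of an interaction network
#'
#' @param net [filter_ppi_edges()] result.
#' @return List with `degrees` (tibble `gene_id`, `degree`), `distribution`
#'   (tibble `degree`, `n_genes`), and `summary` (one-row tibble: node and
#'   edge counts, min/max degree, fraction of nodes with degree >= 2).
#' @export
degree_stats <- function(net) {
  stopifnot(inherits(net, "ssgwas_ppi"))
  if (length(net$nodes) == 0L) {
    return(list(degrees = tibble(gene_id = character(), degree = integer()),
                distribution = tibble(degree = integer(), n_genes = integer()),
                summary = tibble(n_nodes = 0L, n_edges = 0L,
                                 min_degree = NA_integer_,
                                 max_degree = NA_integer_,
                                 frac_degree_ge2 = NA_real_)))
  }
  deg <- igraph::degree(net$graph)
  degrees <- tibble(gene_id = names(deg), degree = as.integer(deg))
  distribution <- degrees |>
    dplyr::count(.data$degree, name = "n_genes")
  summary <- tibble(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
                    min_degree = min(degrees$degree),
                    max_degree = max(degrees$degree),
                    frac_degree_ge2 = mean(degrees$degree >= 2))
  list(degrees = degrees, distribution = distribution, summary = summary)
}

#' Per-node gene summary and network totals
#'
#' Joins each network node with its degree, the number of enriched pathways
#' containing it, and its per-trait variance share and predicted SNP value;
#' also returns totals over the node set and their ratio to the enriched-
#' pathway union totals.
#'
#' @param net [filter_ppi_edges()] result.
#' @param gene_stats Per-gene statistics ([gene_predicted_value()]).
#' @param enrichment [enrich()] output restricted to the pathways defining
#'   the network gene set.
#' @return List with `nodes` (per-node tibble), `totals` (one-row tibble)
#'   and `ratio_to_pathway_totals` (per-trait variance-share ratios).
#' @export
network_gene_summary <- function(net, gene_stats, enrichment) {
  ds <- degree_stats(net)
  stat_cols <- grep("^(varpct|predicted)_", names(gene_stats), value = TRUE)
  missing <- setdiff(net$nodes, gene_stats$gene_id)
  if (length(missing) > 0L) {
    warning(sprintf("%d network genes lack statistics; excluded from totals",
                    length(missing)))
  }
  pathway_count <- enrichment |>
    dplyr::select("pathway_id", "hit_genes") |>
    tidyr::unnest("hit_genes") |>
    dplyr::count(gene_id = .data$hit_genes, name = "n_pathways")
  nodes <- ds$degrees |>
    dplyr::left_join(pathway_count, by = "gene_id") |>
    dplyr::mutate(n_pathways = dplyr::coalesce(.data$n_pathways, 0L)) |>
    dplyr::inner_join(gene_stats[, c("gene_id", stat_cols)], by = "gene_id")
  totals <- dplyr::bind_cols(
    tibble(n_genes = nrow(nodes)),
    as_tibble(as.list(colSums(nodes[, stat_cols, drop = FALSE]))))
  pathway_union <- unique(unlist(enrichment$hit_genes))
  union_stats <- gene_stats[gene_stats$gene_id %in% pathway_union, ]
  var_cols <- grep("^varpct_", stat_cols, value = TRUE)
  ratio <- purrr::map_dbl(var_cols, function(cc) {
    denom <- sum(union_stats[[cc]])
    if (denom == 0) NA_real_ else sum(nodes[[cc]]) / denom
  })
  names(ratio) <- sub("^varpct_", "", var_cols)
  list(nodes = nodes, totals = totals, ratio_to_pathway_totals = ratio)
}
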