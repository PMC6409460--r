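# Toy genome annotation, pathway (gene-set) collections in the four
# enrichment categories, and a confidence-scored interaction network:
# synthetic stand-ins for NCBI / KEGG / STRING inputs.

pathway_categories <- c("cellular processes", "nervous system",
                        "digestive system", "environment adaptation")

#' Simulate a non-overlapping gene annotation
#'
#' Genes are placed per chromosome as non-overlapping 1-based inclusive
#' intervals separated by random gaps.
#'
#' @param chrom_lengths Named or unnamed numeric vector of chromosome
#'   lengths (bp).
#' @param n_genes Total gene count.
#' @param mean_gene_length Average gene span in bp (default 12000).
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
simulate_annotation <- function(chrom_lengths, n_genes,
                                mean_gene_length = 12000, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  if (any(chrom_lengths <= 0)) stop_bad_arg("chromosome lengths must be positive")
  withr_seed(seed)
  chrom_lengths <- as.numeric(chrom_lengths)
  chroms <- names(chrom_lengths) %||% paste0("chr", seq_along(chrom_lengths))
  # genes per chromosome proportional to length
  n_per <- diff(round(cumsum(c(0, chrom_lengths)) / sum(chrom_lengths) * n_genes))
  rows <- purrr::map(seq_along(chroms), function(ci) {
    k <- n_per[ci]
    if (k == 0L) return(NULL)
    len <- chrom_lengths[ci]
    spans <- pmax(200, round(stats::rexp(k, 1 / mean_gene_length)))
    if (sum(spans) + k > len) {
      stop_bad_arg("genes cannot fit in the genome: increase chromosome lengths")
    }
    slack <- len - sum(spans) - k          # room available for gaps
    gaps <- if (k > 0) diff(c(0, sort(sample.int(slack + 1, k) - 1L))) else integer()
    start <- cumsum(gaps + 1) + c(0, cumsum(spans))[seq_len(k)]
    tibble(chrom = chroms[ci], start = start, end = start + spans - 1)
  })
  ann <- dplyr::bind_rows(rows)
  ann$gene_id <- sprintf("gene%04d", seq_len(nrow(ann)))
  ann[, c("gene_id", "chrom", "start", "end")]
}

#' Simulate a pathway (gene-set) collection
#'
#' Each pathway draws a random subset of the annotated genes and is labeled
#' with one of the four enrichment categories (cellular processes, nervous
#' system, digestive system, environment adaptation).
#'
#' @param annotation Tibble from [simulate_annotation()].
#' @param n_pathways Number of pathways.
#' @param size_range Min/max genes per pathway.
#' @param categories Category labels to cycle through.
#' @param seed Integer seed.
#' @return Tibble: `pathway_id`, `category`, `gene_id` (one row per member).
#' @export
simulate_gene_sets <- function(annotation, n_pathways, size_range = c(8L, 40L),
                               categories = pathway_categories, seed = 1L) {
  n_pathways <- check_count(n_pathways, "n_pathways")
  withr_seed(seed)
  sizes <- sample(seq.int(size_range[1], size_range[2]), n_pathways,
                  replace = TRUE)
  sizes <- pmin(sizes, nrow(annotation))
  cats <- rep_len(categories, n_pathways)
  purrr::map_dfr(seq_len(n_pathways), function(i) {
    tibble(pathway_id = sprintf("path%03d", i), category = cats[i],
           gene_id = sort(sample(annotation$gene_id, sizes[i])))
  })
}

#' Simulate a confidence-scored interaction edge table
#'
#' Undirected edges with Beta-distributed confidence scores in \[0,1\]; no
#' self-loops.  When `within_sets` is supplied, a fraction of the edges is
#' drawn between members of the same gene set (proteins of one pathway
#' interact far more often than random pairs, as in curated interaction
#' databases); the rest connect random gene pairs.  Duplicate pairs may
#' occur and are resolved at network construction (max confidence).
#'
#' @param gene_ids Genes eligible as nodes.
#' @param n_edges Number of edges to draw.
#' @param conf_shape Beta shape parameters (length 2) for confidences;
#'   the default Beta(4, 2) puts substantial mass above the 0.7 filter.
#' @param within_sets Optional long-form gene-set tibble (`pathway_id`,
#'   `gene_id`) guiding within-pathway edge placement.
#' @param within_fraction Fraction of edges drawn within gene sets when
#'   `within_sets` is given (default 0.7).
#' @param seed Integer seed.
#' @return Tibble: `gene_a`, `gene_b`, `confidence`.
#' @export
simulate_ppi_edges <- function(gene_ids, n_edges, conf_shape = c(4, 2),
                               within_sets = NULL, within_fraction = 0.7,
                               seed = 1L) {
  n_edges <- check_count(n_edges, "n_edges")
  ng <- length(gene_ids)
  if (ng < 2L) stop_bad_arg("need at least two genes for edges")
  max_edges <- ng * (ng - 1) / 2
  if (n_edges > max_edges) stop_bad_arg("more edges requested than gene pairs")
  withr_seed(seed)
  n_within <- 0L
  within <- NULL
  if (!is.null(within_sets)) {
    members <- split(within_sets$gene_id, within_sets$pathway_id)
    members <- lapply(members, function(g) intersect(unique(g), gene_ids))
    members <- members[lengths(members) >= 2L]
    if (length(members) > 0L) {
      n_within <- round(check_prob(within_fraction, "within_fraction") * n_edges)
      pw <- sample(length(members), n_within, replace = TRUE)
      pairs <- vapply(pw, function(i) sample(members[[i]], 2L), character(2))
      within <- tibble(gene_a = pairs[1, ], gene_b = pairs[2, ])
    }
  }
  n_bg <- n_edges - n_within
  pair_idx <- sample(max_edges, n_bg)
  # unrank unordered pairs: idx = (b-1)(b-2)/2 + a with 1 <= a < b
  b <- ceiling((1 + sqrt(8 * pair_idx + 1)) / 2)
  b <- b - ((b - 1) * (b - 2) / 2 >= pair_idx)      # float-boundary guard
  b <- b + ((b - 1) * b / 2 < pair_idx)
  a <- pair_idx - (b - 1) * (b - 2) / 2
  background <- tibble(gene_a = gene_ids[a], gene_b = gene_ids[b])
  out <- dplyr::bind_rows(within, background)
  out$confidence <- round(rbeta(nrow(out), conf_shape[1], conf_shape[2]), 4)
  out
}

#' Simulate annotation, gene sets and interaction edges together
#'
#' @inheritParams simulate_annotation
#' @inheritParams simulate_gene_sets
#' @param n_edges Interaction edges to draw among all annotated genes.
#' @param mean_gene_length Average gene span in bp.
#' @return List with `annotation`, `gene_sets`, `ppi_edges`.
#' @export
simulate_annotation_and_sets <- function(chrom_lengths, n_genes, n_pathways,
                                         n_edges = 4L * n_genes,
                                         categories = pathway_categories,
                                         mean_gene_length = 12000,
                                         seed = 1L) {
  ann <- simulate_annotation(chrom_lengths, n_genes,
                             mean_gene_length = mean_gene_length, seed = seed)
  sets <- simulate_gene_sets(ann, n_pathways, categories = categories,
                             seed = seed + 1L)
  ppi <- simulate_ppi_edges(ann$gene_id, n_edges, within_sets = sets,
                            seed = seed + 2L)
  list(annotation = ann, gene_sets = sets, ppi_edges = ppi)
}
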