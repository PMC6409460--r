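# End-to-end orchestration: simulate (or load) -> QC -> relationship
# matrices -> REML -> MME -> SNP effects & shares -> gene mapping ->
# enrichment -> PPI network, with TSV stage outputs and a JSON manifest.

#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Defaults describe the desk-scale synthetic study: ~550 animals over
#' three generations from two founder breed pools, a gene-centric panel of
#' 2,500 SNP on two chromosomes, three correlated traits, 2,400 genes, 24
#' pathways in four categories, and a confidence-scored interaction table.
#'
#' @param n_founders,n_generations,n_per_generation Pedigree shape.
#' @param founder_h_split Fraction of founders from the H pool (others O).
#' @param n_snp,chrom_lengths Genotype panel shape.
#' @param missing_rate Missing-call rate before QC.
#' @param genotyped_fraction Fraction of animals genotyped (sampled by
#'   seed); 1 = all.
#' @param n_hys Herd-year-season classes.
#' @param n_qtl,qtl_var_frac QTL count and the fraction of the additive
#'   variance they carry (the remainder is polygenic).
#' @param n_causal_pathways Number of pathways whose member genes host the
#'   QTL (the planted enrichment signal).
#' @param n_genes,n_pathways,n_ppi_edges Annotation / gene-set / edge counts.
#' @param genic_fraction Fraction of SNP placed inside genes (gene-centric
#'   panel; see [gene_centric_map()]).
#' @param min_call_rate,min_maf QC thresholds.
#' @param var_threshold Per-SNP variance-share selection threshold (%).
#' @param gene_window SNP-to-gene window in bp.
#' @param enrich_alpha Family-wise enrichment significance level.
#' @param ppi_threshold Strict PPI confidence threshold.
#' @param blend_alpha Weight on G in [blend_G()].
#' @param tune_method `"mean_match"` ([tune_G_to_A22()]) or `"none"`.
#' @param reml_max_iter,reml_tol REML controls.
#' @param pooled_query Use the union of the three per-trait gene lists as
#'   the enrichment query (the tables pool traits); otherwise the first
#'   trait's list.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return A validated `ssgwas_config` list.
#' @export
pipeline_config <- function(n_founders = 100L, n_generations = 3L,
                            n_per_generation = 150L, founder_h_split = 0.6,
                            n_snp = 2500L,
                            chrom_lengths = c(chr1 = 120e6, chr2 = 100e6),
                            missing_rate = 0.02, genotyped_fraction = 0.7,
                            n_hys = 5L, n_qtl = 60L, qtl_var_frac = 0.7,
                            n_causal_pathways = 2L,
                            n_genes = 2400L, n_pathways = 24L,
                            n_ppi_edges = 8000L, genic_fraction = 0.35,
                            min_call_rate = 0.90, min_maf = 0.01,
                            var_threshold = 0.001, gene_window = 2500,
                            enrich_alpha = 0.05, ppi_threshold = 0.7,
                            blend_alpha = 0.95,
                            tune_method = c("mean_match", "none"),
                            reml_max_iter = 200L, reml_tol = 1e-8,
                            pooled_query = TRUE, seed = 1L) {
  cfg <- list(
    n_founders = check_count(n_founders, "n_founders", 2L),
    n_generations = check_count(n_generations, "n_generations"),
    n_per_generation = check_count(n_per_generation, "n_per_generation"),
    founder_h_split = check_prob(founder_h_split, "founder_h_split"),
    n_snp = check_count(n_snp, "n_snp"),
    chrom_lengths = chrom_lengths,
    missing_rate = check_prob(missing_rate, "missing_rate"),
    genotyped_fraction = check_prob(genotyped_fraction, "genotyped_fraction",
                                    open_left = TRUE),
    n_hys = check_count(n_hys, "n_hys"),
    n_qtl = check_count(n_qtl, "n_qtl", 0L),
    n_causal_pathways = check_count(n_causal_pathways, "n_causal_pathways", 0L),
    qtl_var_frac = check_prob(qtl_var_frac, "qtl_var_frac"),
    n_genes = check_count(n_genes, "n_genes"),
    n_pathways = check_count(n_pathways, "n_pathways"),
    n_ppi_edges = check_count(n_ppi_edges, "n_ppi_edges"),
    genic_fraction = check_prob(genic_fraction, "genic_fraction"),
    min_call_rate = check_prob(min_call_rate, "min_call_rate"),
    min_maf = check_prob(min_maf, "min_maf"),
    var_threshold = as.numeric(var_threshold),
    gene_window = as.numeric(gene_window),
    enrich_alpha = check_prob(enrich_alpha, "enrich_alpha", open_left = TRUE),
    ppi_threshold = check_prob(ppi_threshold, "ppi_threshold"),
    blend_alpha = as.numeric(blend_alpha),
    tune_method = match.arg(tune_method),
    reml_max_iter = check_count(reml_max_iter, "reml_max_iter"),
    reml_tol = as.numeric(reml_tol),
    pooled_query = isTRUE(pooled_query),
    seed = check_count(seed, "seed", 0L)
  )
  if (cfg$var_threshold < 0) stop_bad_arg("var_threshold must be >= 0")
  if (cfg$blend_alpha <= 0 || cfg$blend_alpha > 1) {
    stop_bad_arg("blend_alpha must lie in (0,1]")
  }
  structure(cfg, class = "ssgwas_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config `ssgwas_config` object.
#' @return `read_config()` returns the validated config; `write_config()`
#'   the path, invisibly.  Configs round-trip unchanged.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$chrom_lengths <- unlist(vals$chrom_lengths)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  # yaml drops names of atomic vectors; keep chromosome names via a map
  vals$chrom_lengths <- as.list(vals$chrom_lengths)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> QC -> relationship matrices -> AI-REML -> MME ->
#' SNP effects and variance shares -> gene mapping -> enrichment -> PPI
#' network, writing every stage output as headered TSV/CSV plus a JSON
#' manifest (config hash, seed, per-stage row counts).  Deterministic for
#' a fixed config.
#'
#' @param config [pipeline_config()] object.
#' @param out_dir Output directory (created if needed); NULL = no files.
#' @return List of in-memory stage results (`data`, `qc`, `relmat`, `reml`,
#'   `mme`, `effects`, `mapping`, `enrichment`, `network`, `summary`,
#'   `manifest`), invisibly returned artifacts written under `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "ssgwas_config"))
  seed <- config$seed

  # --- simulate ------------------------------------------------------------
  ped <- simulate_pedigree(config$n_founders, config$n_generations,
                           config$n_per_generation, seed = seed)
  founders <- ped$animal[ped$sire == 0L]
  n_h <- round(config$founder_h_split * length(founders))
  founder_h <- setNames(c(rep(1, n_h), rep(0, length(founders) - n_h)),
                        founders)
  breed <- assign_breed_fractions(ped, founder_h)
  ann_sets <- simulate_annotation_and_sets(config$chrom_lengths,
                                           config$n_genes, config$n_pathways,
                                           config$n_ppi_edges,
                                           seed = seed + 2L)
  plan <- plan_causal_qtl(config, ann_sets, seed = seed + 3L)
  map <- gene_centric_map(config$n_snp, config$chrom_lengths,
                          ann_sets$annotation, config$genic_fraction,
                          seed = seed + 6L, tag_intervals = plan$tags)
  # candidate-gene tag markers are kept at moderate frequencies in both
  # founder pools so the planted QTL segregate at usable MAF
  withr_seed(seed + 7L)
  is_tag <- map$snp_id %in% plan$tag_ids(map)
  freq_h <- runif(config$n_snp, 0.02, 0.98)
  freq_o <- runif(config$n_snp, 0.02, 0.98)
  freq_h[is_tag] <- runif(sum(is_tag), 0.30, 0.70)
  freq_o[is_tag] <- runif(sum(is_tag), 0.30, 0.70)
  # a small fraction of assays genotype poorly: their call rate falls below
  # the QC threshold, so the QC stage has real work to do
  miss <- rep(config$missing_rate, config$n_snp)
  bad_assay <- !is_tag & runif(config$n_snp) < 0.03
  miss[bad_assay] <- 0.15
  geno_all <- simulate_genotypes(ped, breed, config$n_snp,
                                 config$chrom_lengths,
                                 freq_h = freq_h, freq_o = freq_o,
                                 missing_rate = miss,
                                 seed = seed + 1L, map = map)
  truth <- make_pipeline_truth(config, geno_all, plan, seed = seed + 3L)
  phen <- simulate_phenotypes(ped, breed, geno_all, truth,
                              n_hys = config$n_hys, seed = seed + 4L)

  withr_seed(seed + 5L)
  n_geno <- max(2L, round(config$genotyped_fraction * nrow(ped)))
  genotyped <- if (config$genotyped_fraction >= 1) ped$animal else
    sort(sample(ped$animal, n_geno))

  # --- QC and relationship matrices ---------------------------------------
  geno_g <- snp_geno(geno_all$codes[as.character(genotyped), , drop = FALSE],
                     geno_all$map)
  geno_qc <- qc_genotypes(geno_g, config$min_call_rate, config$min_maf)
  p <- compute_allele_freqs(geno_qc)
  A <- build_A(ped)
  blocks <- extract_A_blocks(A, genotyped)
  G <- build_G(geno_qc, p)
  A22 <- blocks$A22[rownames(G), colnames(G), drop = FALSE]
  G_t <- if (config$tune_method == "mean_match") tune_G_to_A22(G, A22) else G
  G_b <- blend_G(G_t, A22, config$blend_alpha)
  H <- build_H_inv(A, G_b, genotyped)

  # --- mixed model ---------------------------------------------------------
  design <- build_design(phen$records, ped, breed, traits = truth$traits)
  vc <- reml_ai(design, H_inv = H, max_iter = config$reml_max_iter,
                tol = config$reml_tol)
  mme <- solve_mme(design, H, vc)

  # --- SNP effects and shares ----------------------------------------------
  gebv_g <- dplyr::filter(mme$gebv, .data$animal %in% genotyped)
  effects <- backsolve_effects(gebv_g, geno_qc, G_b, p)
  sigma2_a <- setNames(diag(vc$Va), vc$traits)
  effects <- variance_share(effects, sigma2_a)

  # --- gene mapping --------------------------------------------------------
  selected <- purrr::map(setNames(vc$traits, vc$traits),
                         ~ filter_by_variance(effects, .x, config$var_threshold))
  sel_union <- unique(unlist(selected))
  assignment <- assign_to_genes(effects[effects$snp_id %in% sel_union,
                                        c("snp_id", "chrom", "pos")],
                                ann_sets$annotation, window = config$gene_window)
  eligible <- dplyr::filter(assignment, .data$eligible)
  gene_lists <- purrr::map(selected, function(snps) {
    unique(eligible$gene_id[eligible$snp_id %in% snps])
  })
  overlap <- trait_overlap(gene_lists)

  # --- enrichment ----------------------------------------------------------
  query <- if (config$pooled_query) unique(unlist(gene_lists)) else
    gene_lists[[1]]
  enr <- enrich(query, ann_sets$gene_sets, alpha = config$enrich_alpha)
  sig <- dplyr::filter(enr, .data$significant)
  gene_stats <- gene_predicted_value(eligible, effects)
  agg <- if (nrow(sig) > 0L) aggregate_pathway_stats(sig, gene_stats) else
    list(pathways = sig, categories = tibble(), total = tibble(n_genes = 0))

  # --- PPI network ---------------------------------------------------------
  enriched_genes <- unique(unlist(sig$hit_genes)) %||% character(0)
  net <- filter_ppi_edges(ann_sets$ppi_edges, config$ppi_threshold,
                          nodes = enriched_genes)
  deg <- degree_stats(net)
  net_summary <- if (length(net$nodes) > 0L && nrow(sig) > 0L) {
    network_gene_summary(net, gene_stats, sig)
  } else list(nodes = tibble(), totals = tibble(),
              ratio_to_pathway_totals = numeric())

  summary <- tibble(
    n_animals = nrow(ped), n_genotyped = length(genotyped),
    n_snp_input = config$n_snp, n_snp_qc = ncol(geno_qc$codes),
    n_snp_selected = length(sel_union),
    n_genes_mapped = length(unique(eligible$gene_id)),
    n_pathways_tested = nrow(enr), n_pathways_significant = nrow(sig),
    n_enriched_genes = length(enriched_genes),
    n_network_nodes = length(net$nodes), n_network_edges = nrow(net$edges),
    frac_degree_ge2 = deg$summary$frac_degree_ge2
  )

  res <- list(config = config, ped = ped, breed = breed, geno = geno_all,
              annotation = ann_sets$annotation, gene_sets = ann_sets$gene_sets,
              ppi_edges = ann_sets$ppi_edges, truth = truth,
              records = phen$records, bv = phen$bv, genotyped = genotyped,
              geno_qc = geno_qc, p = p, A = A, G_b = G_b, H = H,
              reml = vc, mme = mme, effects = effects,
              selected = selected, assignment = assignment,
              gene_lists = gene_lists, overlap = overlap,
              enrichment = enr, significant = sig, gene_stats = gene_stats,
              aggregated = agg, network = net, degree = deg,
              network_summary = net_summary, summary = summary)
  if (!is.null(out_dir)) {
    res$manifest <- write_pipeline_outputs(res, out_dir)
  }
  res
}

plan_causal_qtl <- function(config, ann_sets, seed) {
  withr_seed(seed)
  if (config$n_qtl == 0L || config$n_causal_pathways == 0L) {
    return(list(causal_pathways = character(), tags = NULL,
                tag_ids = function(map) character()))
  }
  # causal pathways: the largest gene sets (broad coverage maximizes the
  # planted over-representation signal)
  sizes <- dplyr::count(ann_sets$gene_sets, .data$pathway_id, sort = TRUE)
  causal <- utils::head(sizes$pathway_id,
                        min(config$n_causal_pathways, nrow(sizes)))
  causal_genes <- unique(
    ann_sets$gene_sets$gene_id[ann_sets$gene_sets$pathway_id %in% causal])
  host <- sample(causal_genes, min(config$n_qtl, length(causal_genes)))
  ann_c <- ann_sets$annotation[match(host, ann_sets$annotation$gene_id), ]
  # one tag marker placed inside each QTL-hosting gene (candidate-gene
  # markers, as on trait-targeted commercial panels)
  tags <- tibble(chrom = ann_c$chrom,
                 pos = floor(ann_c$start +
                               runif(nrow(ann_c)) *
                                 (ann_c$end - ann_c$start + 1)),
                 gene_id = ann_c$gene_id)
  list(causal_pathways = causal, tags = tags,
       tag_ids = function(map) {
         map$snp_id[paste(map$chrom, map$pos) %in%
                      paste(tags$chrom, tags$pos)]
       })
}

make_pipeline_truth <- function(config, geno, plan, seed) {
  withr_seed(seed)
  Va <- default_Va(); Ve <- default_Ve()
  if (config$n_qtl == 0L || is.null(plan$tags)) {
    return(sim_truth(Va = Va, Ve = Ve))
  }
  qtl_ids <- sort(plan$tag_ids(geno$map))
  n_qtl <- length(qtl_ids)
  # equal-variance QTL architecture: each QTL contributes
  # qtl_var_frac/n_qtl of every trait's additive variance
  # (magnitude fixed by its realized 2p(1-p); signs correlated like Va)
  p_qtl <- colMeans(geno$codes[, qtl_ids, drop = FALSE], na.rm = TRUE) / 2
  het2 <- pmax(2 * p_qtl * (1 - p_qtl), 1e-6)
  target <- config$qtl_var_frac * diag(Va) / n_qtl
  sgn <- sign(matrix(rnorm(n_qtl * nrow(Va)), n_qtl) %*%
                t(psd_factor(stats::cov2cor(Va))))
  qtl_eff <- sgn * outer(1 / sqrt(het2), sqrt(target))
  truth <- sim_truth(Va = (1 - config$qtl_var_frac) * Va, Ve = Ve,
                     qtl_ids = qtl_ids, qtl_effects = qtl_eff)
  truth$causal_pathways <- plan$causal_pathways
  truth
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_pedigree(res$ped, fp("pedigree.csv"), res$breed)
  write_genotypes(res$geno, fp("genotypes.tsv"))
  write_phenotypes(res$records, fp("phenotypes.csv"))
  write_annotation(res$annotation, fp("annotation.tsv"))
  write_gmt(res$gene_sets, fp("gene_sets.gmt"))
  write_ppi_edges(res$ppi_edges, fp("ppi_edges.tsv"))
  vc_tbl <- tidy(res$reml)
  readr::write_tsv(vc_tbl, fp("variance_components.tsv"))
  readr::write_tsv(res$mme$gebv, fp("gebv.tsv"))
  readr::write_tsv(res$effects, fp("snp_effects.tsv"))
  readr::write_tsv(res$assignment, fp("assignments.tsv"))
  readr::write_tsv(res$gene_stats, fp("gene_stats.tsv"))
  enr_flat <- dplyr::mutate(res$enrichment, hit_genes = purrr::map_chr(
    .data$hit_genes, paste, collapse = ","))
  readr::write_tsv(enr_flat, fp("enrichment.tsv"))
  readr::write_tsv(res$network$edges, fp("network_edges.tsv"))
  if (nrow(res$network_summary$nodes) > 0L) {
    readr::write_tsv(res$network_summary$nodes, fp("network_nodes.tsv"))
  } else {
    readr::write_tsv(tibble(gene_id = character(), degree = integer()),
                     fp("network_nodes.tsv"))
  }
  readr::write_tsv(res$summary, fp("summary.tsv"))
  files <- c("pedigree.csv", "genotypes.tsv", "phenotypes.csv",
             "annotation.tsv", "gene_sets.gmt", "ppi_edges.tsv",
             "variance_components.tsv", "gebv.tsv", "snp_effects.tsv",
             "assignments.tsv", "gene_stats.tsv", "enrichment.tsv",
             "network_edges.tsv", "network_nodes.tsv", "summary.tsv")
  manifest <- list(
    config_hash = rlang::hash(unclass(res$config)),
    seed = res$config$seed,
    files = setNames(as.list(vapply(files, function(f) {
      length(readr::read_lines(fp(f))) - 1L
    }, integer(1))), files),
    summary = as.list(res$summary)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}
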