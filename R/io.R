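# Plain-text readers and writers for the pipeline's interchange formats:
# pedigree CSV, genotype TSV (one row per SNP), phenotype CSV, gene
# annotation TSV / BED, GMT gene sets, PPI edge TSV, and labeled
# relationship-matrix TSV (lower triangle).

#' @name ssgwas_io
#' @rdname ssgwas_io
#' @title Read and write pipeline interchange files
#' @description
#' All formats are plain text.  Pedigree CSV: `animal,sire,dam,h_fraction`.
#' Genotype TSV: one row per SNP (`chrom`, `pos`, `snp_id`, then one column
#' per animal; `NA` = missing call).  Phenotype CSV: `animal,hys` plus one
#' column per trait.  Annotation TSV: `chrom`, `start`, `end`, `gene_id`
#' (1-based inclusive); BED input (0-based half-open) is converted on read.
#' GMT: `pathway_id` TAB category TAB gene ids.  PPI TSV: `gene_a`,
#' `gene_b`, `confidence`.
#' @param path File path.
#' @return Readers return tibbles (or an [snp_geno()]); writers return
#'   `path` invisibly.
NULL

#' @rdname ssgwas_io
#' @param ped Pedigree tibble.
#' @param breed Optional breed-fraction tibble to include as `h_fraction`.
#' @export
write_pedigree <- function(ped, path, breed = NULL) {
  out <- ped[, c("animal", "sire", "dam")]
  if (!is.null(breed)) {
    out$h_fraction <- breed$h_fraction[match(ped$animal, breed$animal)]
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname ssgwas_io
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ped <- tibble(animal = as.integer(df$animal), sire = as.integer(df$sire),
                dam = as.integer(df$dam))
  validate_pedigree(ped)
  if ("h_fraction" %in% names(df)) {
    attr(ped, "breed") <- tibble(animal = ped$animal,
                                 h_fraction = df$h_fraction,
                                 o_fraction = 1 - df$h_fraction)
  }
  ped
}

#' @rdname ssgwas_io
#' @param geno [snp_geno()] object.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "snp_geno"))
  codes <- t(geno$codes)
  df <- dplyr::bind_cols(geno$map[, c("chrom", "pos", "snp_id")],
                         as_tibble(codes, .name_repair = "minimal"))
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname ssgwas_io
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  map <- tibble(snp_id = df$snp_id, chrom = df$chrom, pos = df$pos)
  codes <- t(as.matrix(df[, setdiff(names(df), c("chrom", "pos", "snp_id"))]))
  snp_geno(codes, map)
}

#' @rdname ssgwas_io
#' @param records Phenotype tibble (`animal`, `hys`, trait columns).
#' @export
write_phenotypes <- function(records, path) {
  readr::write_csv(records, path, na = "NA")
  invisible(path)
}

#' @rdname ssgwas_io
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname ssgwas_io
#' @param annotation Annotation tibble (1-based inclusive coordinates).
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[, c("chrom", "start", "end", "gene_id")], path)
  invisible(path)
}

#' @rdname ssgwas_io
#' @param format `"tsv"` (1-based inclusive) or `"bed"` (0-based half-open,
#'   converted to 1-based inclusive on read).
#' @export
read_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    out <- tibble(gene_id = df$gene_id, chrom = df$chrom,
                  start = df$start, end = df$end)
  } else {
    df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                          show_col_types = FALSE, comment = "#")
    out <- tibble(gene_id = df$name, chrom = df$chrom,
                  start = df$start + 1L, end = df$end)
  }
  if (any(out$start > out$end)) stop_bad_arg("annotation has start > end")
  if (anyDuplicated(out$gene_id)) stop_bad_arg("duplicate gene ids in annotation")
  out
}

#' @rdname ssgwas_io
#' @param gene_sets Long-form gene-set tibble (`pathway_id`, `category`,
#'   `gene_id`).
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    dplyr::group_by(.data$pathway_id, .data$category) |>
    dplyr::summarise(genes = paste(.data$gene_id, collapse = "\t"),
                     .groups = "drop") |>
    dplyr::arrange(.data$pathway_id)
  writeLines(sprintf("%s\t%s\t%s", lines$pathway_id, lines$category,
                     lines$genes), path)
  invisible(path)
}

#' @rdname ssgwas_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_bad_arg("GMT line with fewer than three fields")
    tibble(pathway_id = f[1], category = f[2], gene_id = f[-(1:2)])
  })
}

#' @rdname ssgwas_io
#' @param edges PPI edge tibble.
#' @export
write_ppi_edges <- function(edges, path) {
  readr::write_tsv(edges[, c("gene_a", "gene_b", "confidence")], path)
  invisible(path)
}

#' @rdname ssgwas_io
#' @export
read_ppi_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname ssgwas_io
#' @param m Symmetric relationship matrix with id dimnames.
#' @export
write_relmat <- function(m, path) {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- which(lower.tri(m, diag = TRUE), arr.ind = TRUE)
  df <- tibble(row_id = ids[idx[, 1]], col_id = ids[idx[, 2]],
               value = m[idx])
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname ssgwas_io
#' @export
read_relmat <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(row_id = "c", col_id = "c"))
  ids <- unique(c(df$row_id, df$col_id))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(df$row_id, ids); j <- match(df$col_id, ids)
  m[cbind(i, j)] <- df$value
  m[cbind(j, i)] <- df$value
  m
}
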