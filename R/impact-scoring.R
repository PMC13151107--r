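# Impact scoring: per-gene scaled CADD scores, lineage-averaged DepMap
# dependency, and the gene-level impact score (their product, zeroed for
# unexpressed genes) for one sample and one origin.

#' Gene-level CADD score
#'
#' The scaled average of the Phred-scaled CADD scores of the gene's
#' contributing variants: `sum(cadd) / (100 * N)`. With CADD bounded by 99
#' the score lies in `[0, 0.99]`.
#'
#' @param cadd_phreds Numeric vector of CADD Phred scores (>= 1 value, no
#'   missing entries: variants without CADD never reach scoring).
#' @return Scalar score.
#' @export
gene_cadd_score <- function(cadd_phreds) {
  if (!length(cadd_phreds)) stop("no contributing variants", call. = FALSE)
  if (anyNA(cadd_phreds)) stop("missing CADD among contributing variants",
                               call. = FALSE)
  sum(cadd_phreds) / (100 * length(cadd_phreds))
}

#' Read a gene x cell-line dependency matrix
#'
#' Tab-separated, genes in rows (first column gene symbol), cell lines in
#' columns; values are DepMap gene-dependency probabilities in `[0, 1]`
#' (1 = survival essential). Missing entries allowed (`NA`).
#'
#' @param path Path to the matrix.
#' @return Numeric matrix with gene rownames.
#' @export
read_dependency_matrix <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(tab[, -1, with = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("dependency scores must be probabilities in [0, 1]; rescale upstream",
         call. = FALSE)
  }
  m
}

#' Read a cell line -> lineage (cancer type) map
#'
#' Two tab-separated columns: cell line id, lineage label.
#'
#' @param path Path to the map.
#' @return Named character vector (names = cell lines).
#' @export
read_lineage_map <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(tab) < 2L) stop("lineage map needs 2 columns", call. = FALSE)
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Average dependency scores over a cancer-type lineage
#'
#' Per-gene arithmetic mean of the dependency probabilities over the cell
#' lines carrying the requested lineage label, missing entries excluded.
#' The pseudo-lineage `"pan-cancer"` averages over all cell lines and serves
#' as the fallback for samples without a matching cancer type. Genes with no
#' observed value in the lineage get score 0 and are flagged.
#'
#' @param dep_matrix Gene x cell-line matrix from [read_dependency_matrix()].
#' @param lineage_map Named lineage labels from [read_lineage_map()].
#' @param lineage Cancer-type label, or `"pan-cancer"`.
#' @return `data.table` with columns `gene`, `score`, `n_lines`, `flagged`
#'   (no data in lineage), plus attributes `lineage`, `n_cell_lines`.
#' @export
average_dependency <- function(dep_matrix, lineage_map, lineage = "pan-cancer") {
  cols <- if (identical(lineage, "pan-cancer")) colnames(dep_matrix) else {
    labs <- lineage_map[colnames(dep_matrix)]
    hit <- colnames(dep_matrix)[!is.na(labs) & labs == lineage]
    if (!length(hit)) {
      stop("unknown lineage '", lineage, "'; available: ",
           paste(sort(unique(stats::na.omit(lineage_map))), collapse = ", "),
           ", pan-cancer", call. = FALSE)
    }
    hit
  }
  sub <- dep_matrix[, cols, drop = FALSE]
  n_obs <- rowSums(!is.na(sub))
  score <- ifelse(n_obs > 0, rowMeans(sub, na.rm = TRUE), 0)
  out <- data.table::data.table(gene = rownames(dep_matrix),
                                score = as.numeric(score),
                                n_lines = as.integer(n_obs),
                                flagged = n_obs == 0L)
  data.table::setattr(out, "lineage", lineage)
  data.table::setattr(out, "n_cell_lines", length(cols))
  out[]
}

#' Read a precomputed two-column gene -> dependency score table
#'
#' Alternative to the full matrix: tab-separated columns gene, score (already
#' lineage-averaged probabilities in `[0, 1]`).
#'
#' @param path Path to the table.
#' @return `data.table` with `gene`, `score`, `n_lines = NA`, `flagged`.
#' @export
read_dependency_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(tab) < 2L) stop("dependency table needs 2 columns", call. = FALSE)
  score <- as.numeric(tab[[2L]])
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("dependency scores must be probabilities in [0, 1]", call. = FALSE)
  }
  data.table::data.table(gene = as.character(tab[[1L]]), score = score,
                         n_lines = NA_integer_, flagged = is.na(score))[]
}

#' Gene-level impact score
#'
#' The product of the scaled gene CADD score and the gene dependency score,
#' forced to 0 for unexpressed genes.
#'
#' @param gene_cadd,gene_depmap Numeric vectors (recycled as usual).
#' @param expressed Logical vector of expressed flags.
#' @return Numeric impact scores in `[0, 0.99]`.
#' @export
gene_impact <- function(gene_cadd, gene_depmap, expressed = TRUE) {
  ifelse(expressed, gene_cadd * gene_depmap, 0)
}

#' Build the gene impact table for one sample/origin
#'
#' Aggregates filtered, gene-assigned variants into per-gene scores. Variants
#' with no gene assignment are tallied but contribute to no gene. Only altered
#' genes are stored; unaltered universe genes are padded with impact 0 by the
#' enrichment module. Genes absent from the dependency table get dependency 0
#' and are flagged; genes absent from the expression data are treated as
#' expressed.
#'
#' @param variants Filtered annotated variant table (one origin).
#' @param dependency `data.table` with columns `gene`, `score` (from
#'   [average_dependency()] or [read_dependency_table()]).
#' @param expressed Named logical vector of expressed flags, or `NULL` for no
#'   expression gating.
#' @return `data.table` with columns `gene`, `n_variants`, `gene_cadd`,
#'   `gene_depmap`, `expressed`, `impact`; attribute `n_unassigned` counts
#'   variants without a gene.
#' @export
build_impact_table <- function(variants, dependency, expressed = NULL) {
  v <- data.table::as.data.table(variants)
  n_unassigned <- sum(is.na(v$gene))
  v <- v[!is.na(v$gene)]
  if (nrow(v) == 0L) {
    out <- data.table::data.table(gene = character(), n_variants = integer(),
                                  gene_cadd = numeric(), gene_depmap = numeric(),
                                  expressed = logical(), impact = numeric())
    data.table::setattr(out, "n_unassigned", n_unassigned)
    return(out)
  }
  gene <- NULL  # NSE note for R CMD check
  tab <- v[, list(n_variants = .N,
                  gene_cadd = gene_cadd_score(cadd_phred)), by = "gene"]
  dep_idx <- match(tab$gene, dependency$gene)
  tab[, "gene_depmap" := ifelse(is.na(dep_idx), 0,
                                dependency$score[dep_idx])]
  tab[, "dep_flagged" := is.na(dep_idx)]
  expr <- if (is.null(expressed)) rep(TRUE, nrow(tab)) else {
    e <- expressed[tab$gene]
    e[is.na(e)] <- TRUE  # absent from expression data: no evidence of silence
    unname(e)
  }
  tab[, "expressed" := expr]
  tab[, "impact" := gene_impact(tab$gene_cadd, tab$gene_depmap, tab$expressed)]
  data.table::setorderv(tab, "gene")
  out <- tab[, c("gene", "n_variants", "gene_cadd", "gene_depmap",
                 "expressed", "impact"), with = FALSE]
  data.table::setattr(out, "n_unassigned", n_unassigned)
  data.table::setattr(out, "n_dep_flagged", sum(tab$dep_flagged))
  out[]
}
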