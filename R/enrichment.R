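# Modified gene set enrichment: genes ranked by impact score, a running-sum
# enrichment statistic whose hit increments are impact_j / impact_total over
# ALL universe genes (deviating deliberately from classical GSEA), a
# gene-permutation null, BH adjustment, and the pathway disturbance score
# (NES x mean member impact).

#' Build the ranked gene universe for one sample/origin
#'
#' The universe is the expressed subset of the annotation gene space; genes
#' absent from the impact table get impact 0. Genes are ordered by impact
#' descending with ties broken by gene symbol ascending, so the ranking is
#' deterministic across platforms.
#'
#' @param impact_table Output of [build_impact_table()].
#' @param annotation_genes Character vector: the annotation space (e.g. the
#'   union of all gene-set members).
#' @param expressed Named logical vector of expressed flags, or `NULL`.
#'   Unexpressed genes are excluded from the universe entirely (they do not
#'   occupy ranks), matching a universe of expressed genes only.
#' @return Object of class `ranked_universe`: list with `gene` (ordered),
#'   `impact` (aligned), `n_total`, `impact_total`.
#' @export
build_universe <- function(impact_table, annotation_genes, expressed = NULL) {
  genes <- unique(as.character(annotation_genes))
  if (!length(genes)) stop("empty gene universe", call. = FALSE)
  if (!is.null(expressed)) {
    e <- expressed[genes]
    e[is.na(e)] <- TRUE
    genes <- genes[e]
    if (!length(genes)) stop("no expressed genes remain in the universe",
                             call. = FALSE)
  }
  imp <- numeric(length(genes))
  idx <- match(genes, impact_table$gene)
  hit <- !is.na(idx)
  imp[hit] <- impact_table$impact[idx[hit]]
  ord <- order(-imp, genes, method = "radix")
  structure(
    list(gene = genes[ord], impact = imp[ord],
         n_total = length(genes), impact_total = sum(imp)),
    class = "ranked_universe"
  )
}

#' @export
print.ranked_universe <- function(x, ...) {
  cat(sprintf("ranked universe: %d genes, total impact %.4f\n",
              x$n_total, x$impact_total))
  invisible(x)
}

# Full O(N) running-sum walk; returns the trace. Used for the user-facing
# enrichment_score() and as the reference path in tests.
.es_walk <- function(universe, member_mask) {
  n <- universe$n_total
  n_s <- sum(member_mask)
  p_hit <- cumsum(ifelse(member_mask, universe$impact, 0)) /
    universe$impact_total
  p_miss <- cumsum(!member_mask) / (n - n_s)
  data.table::data.table(rank = seq_len(n), gene = universe$gene,
                         hit = member_mask, p_hit = p_hit, p_miss = p_miss,
                         dev = p_hit - p_miss)
}

# Fast O(N_S) enrichment score from the sorted ranks of the member genes.
# Under the positive-scoring convention the running-sum deviation can only
# attain its maximum immediately after a hit, so it suffices to evaluate
#   H_j / impact_total - (r_j - j) / (N - N_S)
# at the j-th hit (rank r_j, cumulative hit impact H_j), floored at 0.
.es_from_ranks <- function(sorted_ranks, cum_impacts, n, n_s, impact_total) {
  dev <- cum_impacts / impact_total -
    (sorted_ranks - seq_len(n_s)) / (n - n_s)
  max(0, dev)
}

#' Enrichment score of a gene set on a ranked universe
#'
#' Walks the ranking accumulating `P_Hit(S, i)` (cumulative member impact over
#' the total impact of all universe genes) and `P_Miss(S, i)` (fraction of the
#' `N - N_S` non-members seen so far). Under the default positive-scoring
#' convention the ES is the maximum of the signed deviation
#' `P_Hit - P_Miss`, floored at 0, so depletion never scores as disturbance;
#' `score_type = "abs"` instead maximises the absolute deviation.
#'
#' @param universe A `ranked_universe`.
#' @param members Character vector of member genes (gene set S).
#' @param score_type `"pos"` (default) or `"abs"`.
#' @param keep_trace Return the running-sum trace as well?
#' @return List with `es`, `n_s`, and (if requested) `trace`.
#' @export
enrichment_score <- function(universe, members, score_type = c("pos", "abs"),
                             keep_trace = FALSE) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(universe, "ranked_universe"))
  mask <- universe$gene %in% members
  n_s <- sum(mask)
  if (n_s < 1L || n_s >= universe$n_total) {
    stop("gene set must satisfy 1 <= N_S < N after universe intersection",
         call. = FALSE)
  }
  if (universe$impact_total <= 0) {
    stop("impact_total is 0; no enrichment signal to score", call. = FALSE)
  }
  trace <- .es_walk(universe, mask)
  es <- if (score_type == "pos") max(0, max(trace$dev)) else max(abs(trace$dev))
  out <- list(es = es, n_s = n_s)
  if (keep_trace) out$trace <- trace
  out
}

# Draw `nperm` random size-k subsets of ranks 1..n and score each under the
# positive convention, fully vectorised. Candidate ranks are drawn with
# replacement and columns containing duplicates are redrawn, which is fast
# for k << n; falls back to per-column sampling otherwise.
.perm_es <- function(universe, n_s, nperm) {
  n <- universe$n_total
  it <- universe$impact_total
  col_id <- rep(seq_len(nperm), each = n_s)
  sort_cols <- function(m) {
    matrix(as.integer(m)[order(col_id, as.integer(m), method = "radix")],
           nrow = n_s)
  }
  if (n_s > n / 4) {
    ranks <- vapply(seq_len(nperm),
                    function(i) sort.int(sample.int(n, n_s)),
                    integer(n_s))
  } else {
    ranks <- matrix(sample.int(n, n_s * nperm, replace = TRUE),
                    nrow = n_s, ncol = nperm)
    for (tries in 1:100) {
      ranks <- sort_cols(ranks)
      bad <- if (n_s > 1L)
        which(colSums(ranks[-1L, , drop = FALSE] ==
                        ranks[-n_s, , drop = FALSE]) > 0L)
      else integer(0)
      if (!length(bad)) break
      ranks[, bad] <- matrix(sample.int(n, n_s * length(bad), replace = TRUE),
                             nrow = n_s)
    }
    if (n_s > 1L && any(colSums(ranks[-1L, , drop = FALSE] ==
                                  ranks[-n_s, , drop = FALSE]) > 0L)) {
      # extremely unlikely; resample offending columns exactly
      bad <- which(colSums(ranks[-1L, , drop = FALSE] ==
                             ranks[-n_s, , drop = FALSE]) > 0L)
      for (b in bad) ranks[, b] <- sort.int(sample.int(n, n_s))
    }
  }
  imp <- matrix(universe$impact[ranks], nrow = n_s)
  # column-wise cumulative hit impact via one global cumsum
  vec <- as.numeric(imp)
  cs <- cumsum(vec)
  offs <- c(0, cs[seq_len(nperm - 1L) * n_s])
  h <- cs - rep(offs, each = n_s)
  j <- rep.int(seq_len(n_s), nperm)
  dev <- h / it - (as.numeric(ranks) - j) / (n - n_s)
  dev_mat <- matrix(dev, nrow = n_s)
  es <- if (n_s == 1L) as.numeric(dev_mat) else {
    m <- t(dev_mat)
    m[cbind(seq_len(nperm), max.col(m, ties.method = "first"))]
  }
  pmax(es, 0)
}

#' Gene-permutation significance test for one pathway
#'
#' Draws `nperm` uniform random `N_S`-subsets of the universe, scores each on
#' the fixed ranking with the positive convention, and returns the plus-one
#' corrected empirical p-value `(1 + #{ES_perm >= ES_obs}) / (nperm + 1)` and
#' the null mean used for NES. Reproducible given `seed`.
#'
#' @param universe A `ranked_universe`.
#' @param members Member genes of pathway S.
#' @param nperm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `es_obs`, `pval`, `null_mean`, `n_s`, `nperm`, plus the
#'   tie decomposition `n_gt` / `n_eq` (permutation ES strictly greater than /
#'   equal to the observed ES), from which a randomized tie-broken p-value can
#'   be formed for calibration checks: the positive-scoring ES has an atom at
#'   0, so the plain plus-one p is conservative, not uniform, under a flat
#'   null.
#' @export
permutation_test <- function(universe, members, nperm = 1000L, seed = 1L) {
  nperm <- as.integer(nperm)
  if (nperm < 100L) stop("nperm must be >= 100", call. = FALSE)
  obs <- enrichment_score(universe, members, score_type = "pos")
  if (obs$n_s >= universe$n_total) stop("N_S must be < N", call. = FALSE)
  es_null <- .with_seed(seed, .perm_es(universe, obs$n_s, nperm))
  n_gt <- sum(es_null > obs$es)
  n_eq <- sum(es_null == obs$es)
  list(es_obs = obs$es,
       pval = (1 + n_gt + n_eq) / (nperm + 1),
       null_mean = mean(es_null),
       n_s = obs$n_s,
       nperm = nperm,
       n_gt = n_gt,
       n_eq = n_eq)
}

#' Normalise an enrichment score by its permutation null mean
#'
#' `NES = ES / mean(null ES)`. When the null mean is 0 and the observed ES is
#' 0 the NES is 0; a positive ES over a zero null mean is undefined and
#' returned as `NA` (the record should be flagged downstream).
#'
#' @param es_obs Observed ES (>= 0).
#' @param null_mean Mean of the permutation ES values (>= 0).
#' @return Scalar NES.
#' @export
normalize_es <- function(es_obs, null_mean) {
  if (null_mean < 0) stop("null_mean must be >= 0", call. = FALSE)
  if (null_mean == 0) {
    if (es_obs == 0) return(0)
    return(NA_real_)
  }
  es_obs / null_mean
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, applied within one
#' (sample, origin, annotation source) family.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Pathway disturbance score
#'
#' The per-sample pathway disturbance measure: NES multiplied by the average
#' gene-level impact score of the pathway members within the universe.
#'
#' @param nes Normalised enrichment score.
#' @param member_impacts Impact scores of the `n_s` member genes.
#' @param n_s Member count (defaults to `length(member_impacts)`).
#' @return Scalar disturbance score.
#' @export
pathway_dscore <- function(nes, member_impacts, n_s = length(member_impacts)) {
  if (n_s < 1L) stop("n_s must be >= 1", call. = FALSE)
  nes * sum(member_impacts) / n_s
}

#' Score every pathway of a collection for one sample/origin
#'
#' @param universe A `ranked_universe`.
#' @param gene_sets Named list of member gene vectors (see [read_gmt()]).
#' @param nperm Permutations per pathway.
#' @param seed Master seed; each pathway gets its own stream derived from
#'   `seed` and a hash of the pathway id, so results are order-independent.
#' @param padj_threshold Significance threshold on the BH-adjusted p (default
#'   0.25).
#' @param min_set_size Pathways with fewer members in the universe are
#'   skipped (default 2).
#' @param source Annotation source label (e.g. `"GO"`, `"KEGG"`).
#' @param origin Origin label carried into the output.
#' @return `data.table` with columns `pathway_id`, `name`, `source`, `origin`,
#'   `n_s`, `es`, `nes`, `pval`, `padj`, `mean_impact`, `dscore`,
#'   `significant`; skipped pathways in the `skipped` attribute.
#' @export
score_pathways <- function(universe, gene_sets, nperm = 1000L, seed = 1L,
                           padj_threshold = 0.25, min_set_size = 2L,
                           source = "GO", origin = "somatic") {
  stopifnot(inherits(universe, "ranked_universe"))
  ids <- names(gene_sets)
  if (is.null(ids)) stop("gene_sets must be a named list", call. = FALSE)
  descs <- attr(gene_sets, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(ids, ids)
  skipped <- character(0)
  rows <- vector("list", length(ids))
  gene_pos <- stats::setNames(seq_len(universe$n_total), universe$gene)
  for (k in seq_along(ids)) {
    id <- ids[k]
    pos <- gene_pos[unique(gene_sets[[k]])]
    pos <- unname(pos[!is.na(pos)])
    n_s <- length(pos)
    if (n_s < min_set_size || n_s >= universe$n_total) {
      skipped <- c(skipped, id)
      next
    }
    member_impacts <- universe$impact[pos]
    if (universe$impact_total <= 0) {
      rows[[k]] <- data.table::data.table(
        pathway_id = id, name = unname(descs[id]), source = source,
        origin = origin, n_s = n_s, es = 0, nes = 0, pval = 1,
        mean_impact = 0, dscore = 0)
      next
    }
    pt <- permutation_test(universe, universe$gene[pos], nperm = nperm,
                           seed = .derive_seed(seed, id))
    nes <- normalize_es(pt$es_obs, pt$null_mean)
    mi <- mean(member_impacts)
    rows[[k]] <- data.table::data.table(
      pathway_id = id, name = unname(descs[id]), source = source,
      origin = origin, n_s = n_s, es = pt$es_obs, nes = nes, pval = pt$pval,
      mean_impact = mi, dscore = if (is.na(nes)) NA_real_ else nes * mi)
  }
  out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out)) {
    out[, "padj" := bh_adjust(out$pval)]
    out[, "significant" := !is.na(out$padj) & out$padj < padj_threshold]
    data.table::setcolorder(out, c("pathway_id", "name", "source", "origin",
                                   "n_s", "es", "nes", "pval", "padj",
                                   "mean_impact", "dscore", "significant"))
    data.table::setorderv(out, "dscore", order = -1L, na.last = TRUE)
  } else {
    out <- data.table::data.table(
      pathway_id = character(), name = character(), source = character(),
      origin = character(), n_s = integer(), es = numeric(), nes = numeric(),
      pval = numeric(), padj = numeric(), mean_impact = numeric(),
      dscore = numeric(), significant = logical())
  }
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Read gene sets from a GMT file
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @param source Annotation source label attached as an attribute.
#' @return Named list of character vectors with attributes `descriptions`
#'   (named) and `source`.
#' @export
read_gmt <- function(path, source = "GO") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      warning("skipping GMT line with < 3 fields", call. = FALSE)
      next
    }
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
    descs[parts[1L]] <- parts[2L]
  }
  attr(sets, "descriptions") <- descs
  attr(sets, "source") <- source
  sets
}

#' Run the full single-sample pipeline for each origin
#'
#' Applies the origin-specific filter policy, builds the gene impact table,
#' optionally gates by expression, ranks the universe and scores every
#' pathway. Default permutation counts are 6000 for somatic and 1000 for
#' germline variants.
#'
#' @param variants Named list of annotated variant tables (names in
#'   `c("somatic", "germline")`), e.g. from [read_vcf()] + [annotate_variants()].
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param dependency Gene dependency table (`gene`, `score`).
#' @param expression Named numeric vector of raw counts, or `NULL`.
#' @param config A [run_config()] list; controls thresholds, permutation
#'   counts and the seed.
#' @return `data.table` of enrichment records, all origins stacked; per-origin
#'   filter tallies in the `tallies` attribute.
#' @export
run_sample <- function(variants, gene_sets, dependency, expression = NULL,
                       config = run_config()) {
  stopifnot(is.list(variants), length(variants) >= 1L)
  expressed <- expression_gate(expression, seed = config$seed)
  source <- attr(gene_sets, "source")
  if (is.null(source)) source <- "GO"
  annotation_genes <- unique(unlist(gene_sets, use.names = FALSE))
  res <- list()
  tallies <- list()
  for (origin in names(variants)) {
    policy <- filter_policy(origin,
                            max_gnomad_af = if (origin == "germline")
                              config$gnomad_cutoff else NA,
                            min_cadd = config$cadd_cutoff)
    kept <- apply_filters(variants[[origin]], policy)
    tallies[[origin]] <- attr(kept, "filter_tally")
    impact <- build_impact_table(kept, dependency, expressed)
    if (nrow(impact) == 0L || sum(impact$impact) == 0) next
    universe <- build_universe(impact, annotation_genes, expressed)
    nperm <- if (origin == "somatic") config$nperm_somatic else
      config$nperm_germline
    res[[origin]] <- score_pathways(
      universe, gene_sets, nperm = nperm,
      seed = .derive_seed(config$seed, origin),
      padj_threshold = config$padj_threshold,
      min_set_size = config$min_set_size,
      source = source, origin = origin)
  }
  out <- if (length(res)) data.table::rbindlist(res) else
    data.table::data.table(
      pathway_id = character(), name = character(), source = character(),
      origin = character(), n_s = integer(), es = numeric(), nes = numeric(),
      pval = numeric(), padj = numeric(), mean_impact = numeric(),
      dscore = numeric(), significant = logical())
  data.table::setattr(out, "tallies", tallies)
  out[]
}
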