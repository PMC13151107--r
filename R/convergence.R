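# Phenotypic convergence: different member genes of the same pathway altered
# in different individuals. Quantified per pathway as the number of sample
# pairs sharing gene-level alterations, against a size-matched random
# gene-set null, plus cohort-level pathway alteration-frequency tables.

#' Build a binary sample x gene alteration matrix
#'
#' "Altered" means the gene carries at least one variant passing the
#' origin-specific filter policy in that sample.
#'
#' @param sample_genes Named list: per sample, the character vector of altered
#'   genes (e.g. `unique(filtered$gene)`).
#' @return Binary integer matrix, samples in rows, genes in columns.
#' @export
build_alteration_matrix <- function(sample_genes) {
  stopifnot(is.list(sample_genes), length(sample_genes) >= 1L)
  if (is.null(names(sample_genes))) {
    names(sample_genes) <- paste0("sample", seq_along(sample_genes))
  }
  genes <- sort(unique(unlist(sample_genes, use.names = FALSE)))
  m <- matrix(0L, nrow = length(sample_genes), ncol = length(genes),
              dimnames = list(names(sample_genes), genes))
  for (i in seq_along(sample_genes)) {
    m[i, unique(sample_genes[[i]])] <- 1L
  }
  m
}

#' Raw convergence score of a pathway
#'
#' `C(S) = sum over member genes g of k_g (k_g - 1) / 2`, where `k_g` is the
#' number of samples in which g is altered: the total number of sample pairs
#' sharing an alteration in a member gene.
#'
#' @param matrix Binary alteration matrix (samples x genes).
#' @param members Member genes of pathway S.
#' @return Non-negative integer count.
#' @export
convergence_raw <- function(matrix, members) {
  hit <- intersect(colnames(matrix), members)
  if (!length(hit)) {
    warning("gene set does not intersect the alteration matrix", call. = FALSE)
    return(0L)
  }
  k <- colSums(matrix[, hit, drop = FALSE])
  as.integer(sum(k * (k - 1) / 2))
}

#' Normalised convergence score
#'
#' The raw pair count divided by the number of member genes and by the total
#' number of possible sample pairs: `c_raw / (n_s * m (m - 1) / 2)`.
#'
#' @param c_raw Raw convergence count.
#' @param n_s Number of genes in the pathway.
#' @param m Number of samples (>= 2).
#' @return Normalised score in `[0, 1]` when every member gene is assessable.
#' @export
convergence_normalized <- function(c_raw, n_s, m) {
  if (n_s < 1L) stop("n_s must be >= 1", call. = FALSE)
  if (m < 2L) stop("convergence needs at least 2 samples", call. = FALSE)
  c_raw / (n_s * m * (m - 1) / 2)
}

#' Convergence significance against a random gene-set null
#'
#' Draws `n_random` gene sets of size `n_s` uniformly from the matrix's gene
#' universe (the genes assessable in the cohort), scores each with
#' [convergence_raw()] using the observed per-gene alteration counts, and
#' returns `z = (c_obs - mean) / sd` plus the plus-one corrected empirical
#' p-value.
#'
#' @param matrix Binary alteration matrix.
#' @param members Member genes of pathway S.
#' @param n_random Number of random sets (default 1000).
#' @param seed Integer seed.
#' @return List with `c_raw`, `c_norm`, `z`, `p_emp`, `n_random`; `z` is `NA`
#'   (flagged) when the null variance is 0.
#' @export
convergence_null <- function(matrix, members, n_random = 1000L, seed = 1L) {
  m <- nrow(matrix)
  if (m < 2L) stop("convergence needs at least 2 samples", call. = FALSE)
  universe <- colnames(matrix)
  hit <- intersect(universe, members)
  n_s <- length(hit)
  if (n_s < 1L) stop("gene set does not intersect the alteration matrix",
                     call. = FALSE)
  if (n_s >= length(universe)) {
    stop("gene universe must be larger than the pathway", call. = FALSE)
  }
  k <- colSums(matrix)
  pairs <- k * (k - 1) / 2
  c_obs <- sum(pairs[hit])
  c_null <- .with_seed(seed, vapply(seq_len(n_random), function(i) {
    sum(pairs[sample.int(length(universe), n_s)])
  }, numeric(1)))
  sd_null <- stats::sd(c_null)
  z <- if (is.na(sd_null) || sd_null == 0) NA_real_ else
    (c_obs - mean(c_null)) / sd_null
  list(c_raw = as.integer(c_obs),
       c_norm = convergence_normalized(c_obs, n_s, m),
       z = z,
       p_emp = (1 + sum(c_null >= c_obs)) / (n_random + 1),
       n_random = as.integer(n_random))
}

#' Cohort-level pathway alteration-frequency table
#'
#' For each pathway, the fraction of samples in which it is significant
#' (BH-adjusted p below the threshold), per origin, plus "both" (significant
#' for both origins in the same sample), and the frequency bin
#' `{<25%, 25-50%, 50-75%, >=75%}` per column.
#'
#' @param records List of per-sample enrichment record tables (the output of
#'   [run_sample()]; each may stack several origins). All tables must come
#'   from the same annotation source.
#' @param padj_threshold Significance threshold (default 0.25).
#' @return `data.table` with columns `pathway_id`, `name`,
#'   `freq_somatic`, `freq_germline`, `freq_both` and matching `bin_*`
#'   columns; attribute `n_samples`.
#' @export
cohort_frequency <- function(records, padj_threshold = 0.25) {
  stopifnot(is.list(records), length(records) >= 1L)
  sources <- unique(unlist(lapply(records, function(r) unique(r$source))))
  if (length(sources) > 1L) {
    stop("mixed annotation sources in one cohort call: ",
         paste(sources, collapse = ", "), call. = FALSE)
  }
  m <- length(records)
  all_ids <- unique(unlist(lapply(records, function(r) r$pathway_id)))
  names_map <- character(0)
  for (r in records) names_map[r$pathway_id] <- r$name
  count <- function(origin_sel) {
    cnt <- stats::setNames(integer(length(all_ids)), all_ids)
    for (r in records) {
      sig <- r[!is.na(r$padj) & r$padj < padj_threshold &
                 r$origin %in% origin_sel]
      ids <- if (length(origin_sel) == 1L) unique(sig$pathway_id) else {
        # "both": significant for every requested origin in this sample
        tab <- table(unique(sig[, c("pathway_id", "origin"), with = FALSE])$pathway_id)
        names(tab)[tab == length(origin_sel)]
      }
      cnt[ids] <- cnt[ids] + 1L
    }
    cnt / m
  }
  bin_of <- function(f) {
    cut(f, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
        labels = c("<25%", "25-50%", "50-75%", ">=75%"), right = FALSE)
  }
  fs <- count("somatic")
  fg <- count("germline")
  fb <- count(c("somatic", "germline"))
  out <- data.table::data.table(
    pathway_id = all_ids,
    name = unname(names_map[all_ids]),
    freq_somatic = unname(fs), freq_germline = unname(fg),
    freq_both = unname(fb),
    bin_somatic = bin_of(unname(fs)),
    bin_germline = bin_of(unname(fg)),
    bin_both = bin_of(unname(fb)))
  data.table::setorderv(out, "freq_somatic", order = -1L)
  data.table::setattr(out, "n_samples", m)
  out[]
}
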