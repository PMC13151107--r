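# Shared builders and independent brute-force oracles. The oracles are kept
# deliberately naive (explicit loops, no shared code with the package paths
# they check).

# Ranked universe from a named impact vector.
toy_universe <- function(impacts) {
  build_universe(
    data.table::data.table(gene = names(impacts), impact = unname(impacts)),
    names(impacts))
}

# Brute-force running-sum enrichment score: re-sorts, walks rank by rank.
oracle_es <- function(genes, impacts, members, type = "pos") {
  ord <- order(-impacts, genes, method = "radix")
  g <- genes[ord]
  imp <- impacts[ord]
  n <- length(g)
  hit <- g %in% members
  n_s <- sum(hit)
  total <- sum(imp)
  p_hit <- 0
  p_miss <- 0
  best <- -Inf
  for (i in seq_len(n)) {
    if (hit[i]) p_hit <- p_hit + imp[i] / total
    else p_miss <- p_miss + 1 / (n - n_s)
    d <- p_hit - p_miss
    best <- max(best, if (type == "pos") d else abs(d))
  }
  if (type == "pos") max(0, best) else best
}

# Brute-force convergence: enumerate every sample pair and member gene.
oracle_convergence <- function(mat, members) {
  hit <- intersect(colnames(mat), members)
  m <- nrow(mat)
  count <- 0L
  for (g in hit) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (mat[i, g] == 1L && mat[j, g] == 1L) count <- count + 1L
      }
    }
  }
  count
}

# Minimal VCF writer for hand-constructed records.
write_toy_vcf <- function(path, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"))
  writeLines(c(header, rows), path)
  path
}

# Tab-separated lookup table for a set of variants.
write_toy_lookup <- function(path, chrom, pos, ref, alt, value) {
  data.table::fwrite(
    data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           value = value),
    path, sep = "\t", quote = FALSE)
  path
}
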