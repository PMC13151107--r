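# Variant layer: read, normalize, filter and annotate variants from VCF files
# into the per-sample, per-origin variant sets that feed gene-level scoring.

#' Construct a variant filter policy
#'
#' A filter policy bundles the depth, allele-frequency and deleteriousness
#' thresholds applied to annotated variants of one origin. Defaults follow the
#' published filters: both origins require alt allele depth (AD) >= 5; somatic
#' variants require VAF > 5% with no population-frequency restriction;
#' germline variants require VAF > 20%, gnomAD population allele frequency
#' <= 0.001 and CADD >= 15. The CADD cutoff is user-configurable for both
#' origins (default 15).
#'
#' @param origin `"somatic"` or `"germline"`.
#' @param min_ad Minimum alt-supporting read count (inclusive).
#' @param min_vaf Variant allele frequency threshold; retention requires
#'   `vaf > min_vaf` (strict, matching "VAF > 5%").
#' @param max_gnomad_af Maximum population allele frequency (inclusive), or
#'   `NA` for no restriction. Variants absent from the population table are
#'   treated as rare (pass) and tallied.
#' @param min_cadd Minimum Phred-scaled CADD score (inclusive). Variants with
#'   missing CADD fail whenever `min_cadd > 0`.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(origin = c("somatic", "germline"),
                          min_ad = 5L,
                          min_vaf = NULL,
                          max_gnomad_af = NULL,
                          min_cadd = 15) {
  origin <- match.arg(origin)
  if (is.null(min_vaf)) min_vaf <- if (origin == "somatic") 0.05 else 0.20
  if (is.null(max_gnomad_af)) {
    max_gnomad_af <- if (origin == "somatic") NA_real_ else 0.001
  }
  .assert_scalar_number(min_ad, "min_ad", min = 0)
  .assert_scalar_number(min_vaf, "min_vaf", min = 0, max = 1)
  if (!is.na(max_gnomad_af)) {
    .assert_scalar_number(max_gnomad_af, "max_gnomad_af", min = 0, max = 1)
  }
  .assert_scalar_number(min_cadd, "min_cadd", min = 0, max = 99)
  structure(
    list(origin = origin, min_ad = as.integer(min_ad), min_vaf = min_vaf,
         max_gnomad_af = max_gnomad_af, min_cadd = min_cadd),
    class = "filter_policy"
  )
}

# Parsimony-trim REF/ALT pairs: drop the shared suffix, then the shared
# prefix (advancing pos), so indel representation differences between VCF
# dialects and lookup tables do not break joins. True left-alignment needs
# the reference sequence and is out of scope; trimming alone makes the
# generated dialects and tables agree.
.normalize_alleles <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    # shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # shared prefix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

.variant_key <- function(chrom, pos, ref, alt) {
  n <- .normalize_alleles(pos, ref, alt)
  paste(chrom, n$pos, n$ref, n$alt, sep = ":")
}

#' Read a VCF file into an annotated-variant table
#'
#' Reads a (plain or bgzipped) VCF, splits multi-allelic records into one row
#' per alternate allele, and extracts AD/DP from the first sample column. VAF
#' is recomputed as `allele_depth / total_depth`; any AF FORMAT field in the
#' file is ignored so VAF semantics are uniform across callers. Records
#' without parseable depth fields are kept with missing depths and counted in
#' the `n_missing_depth` attribute.
#'
#' @param path Path to a VCF file.
#' @param origin Variant origin label, `"somatic"` or `"germline"`.
#' @return A `data.table` with columns `chrom`, `pos`, `ref`, `alt`, `vtype`
#'   (`"SNV"`/`"INDEL"`), `origin`, `allele_depth`, `total_depth`, `vaf`, and
#'   missing annotation columns `cadd_phred`, `gnomad_af`, `gene`.
#' @export
read_vcf <- function(path, origin = c("somatic", "germline")) {
  origin <- match.arg(origin)
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("failed to read VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(vcf) > 0L) vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) {
    out <- data.table::data.table(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), vtype = character(), origin = character(),
      allele_depth = integer(), total_depth = integer(), vaf = numeric(),
      cadd_phred = numeric(), gnomad_af = numeric(), gene = character())
    data.table::setattr(out, "n_missing_depth", 0L)
    return(out)
  }
  loc <- as.data.frame(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))

  ad <- rep(NA_integer_, n)
  dp <- rep(NA_integer_, n)
  g <- VariantAnnotation::geno(vcf)
  if ("AD" %in% names(g) && length(dim(g$AD)) == 3L && dim(g$AD)[3] >= 2L) {
    ad <- as.integer(g$AD[, 1L, 2L])  # first sample, alt slice after expand()
  }
  if ("DP" %in% names(g)) {
    dp <- as.integer(g$DP[, 1L])
  }
  no_dp <- is.na(dp) & !is.na(ad) & "AD" %in% names(g)
  if (any(no_dp)) {
    # fall back to the sum of allelic depths when DP is absent
    refad <- as.integer(g$AD[, 1L, 1L])
    dp[no_dp] <- refad[no_dp] + ad[no_dp]
  }
  vaf <- ifelse(!is.na(ad) & !is.na(dp) & dp > 0, ad / dp, NA_real_)
  n_missing <- sum(is.na(ad) | is.na(dp))
  if (n_missing > 0L) {
    warning(sprintf("%d of %d variant records in '%s' lack parseable AD/DP",
                    n_missing, n, basename(path)), call. = FALSE)
  }
  norm <- .normalize_alleles(as.integer(loc$start), ref, alt)
  out <- data.table::data.table(
    chrom = as.character(loc$seqnames),
    pos = norm$pos,
    ref = norm$ref,
    alt = norm$alt,
    vtype = ifelse(nchar(norm$ref) == 1L & nchar(norm$alt) == 1L,
                   "SNV", "INDEL"),
    origin = origin,
    allele_depth = ad,
    total_depth = dp,
    vaf = vaf,
    cadd_phred = NA_real_,
    gnomad_af = NA_real_,
    gene = NA_character_)
  data.table::setattr(out, "n_missing_depth", n_missing)
  out[]
}

#' Read a variant lookup table
#'
#' Lookup tables are tab-separated with a header and columns
#' `chrom, pos, ref, alt, value`; the value column carries the CADD Phred
#' score, the gnomAD allele frequency, or the gene symbol. Malformed rows
#' (wrong field count, unparseable position) are skipped with a warning.
#'
#' @param path Path to the table.
#' @param type `"numeric"` or `"character"` value column.
#' @return A `data.table` keyed by the normalized variant key.
#' @export
read_lookup_table <- function(path, type = c("numeric", "character")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("lookup table not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c(1, 3, 4)))
  if (ncol(tab) < 5L) stop("lookup table needs 5 columns (chrom, pos, ref, alt, value): ",
                           path, call. = FALSE)
  data.table::setnames(tab, 1:5, c("chrom", "pos", "ref", "alt", "value"))
  pos <- suppressWarnings(as.integer(tab$pos))
  bad <- is.na(pos) | is.na(tab$ref) | is.na(tab$alt) | tab$ref == "" | tab$alt == ""
  if (type == "numeric") {
    val <- suppressWarnings(as.numeric(tab$value))
    bad <- bad | is.na(val)
  } else {
    val <- as.character(tab$value)
    bad <- bad | is.na(val) | val == ""
  }
  if (any(bad)) {
    warning(sprintf("skipped %d malformed row(s) in '%s'", sum(bad),
                    basename(path)), call. = FALSE)
  }
  keep <- !bad
  out <- data.table::data.table(
    vkey = .variant_key(tab$chrom[keep], pos[keep], tab$ref[keep], tab$alt[keep]),
    value = val[keep])
  data.table::setkeyv(out, "vkey")
  out
}

#' Annotate variants with CADD, population frequency and gene assignment
#'
#' Joins on the parsimony-trimmed `(chrom, pos, ref, alt)` key. Variants
#' absent from a table keep a missing value in the corresponding column;
#' per-table miss counts are attached as the `annotation_misses` attribute.
#'
#' @param variants Output of [read_vcf()].
#' @param cadd_table,gnomad_table,gene_table Lookup tables from
#'   [read_lookup_table()] (`gene_table` with `type = "character"`), or `NULL`
#'   to leave that column missing.
#' @return The variant table with `cadd_phred`, `gnomad_af`, `gene` filled.
#' @export
annotate_variants <- function(variants, cadd_table = NULL, gnomad_table = NULL,
                              gene_table = NULL) {
  v <- data.table::as.data.table(variants)
  key <- .variant_key(v$chrom, v$pos, v$ref, v$alt)
  misses <- c(cadd = 0L, gnomad = 0L, gene = 0L)
  lookup <- function(tab) {
    idx <- match(key, tab$vkey)
    list(val = tab$value[idx], miss = sum(is.na(idx)))
  }
  if (!is.null(cadd_table)) {
    r <- lookup(cadd_table); v[, "cadd_phred" := as.numeric(r$val)]
    misses["cadd"] <- r$miss
  }
  if (!is.null(gnomad_table)) {
    r <- lookup(gnomad_table); v[, "gnomad_af" := as.numeric(r$val)]
    misses["gnomad"] <- r$miss
  }
  if (!is.null(gene_table)) {
    r <- lookup(gene_table); v[, "gene" := as.character(r$val)]
    misses["gene"] <- r$miss
  }
  data.table::setattr(v, "annotation_misses", misses)
  v[]
}

#' Filter annotated variants under a policy
#'
#' Retention requires `allele_depth >= min_ad`, `vaf > min_vaf`, population
#' allele frequency `<= max_gnomad_af` (missing gnomAD treated as rare:
#' passes), and `cadd_phred >= min_cadd` (missing CADD fails whenever
#' `min_cadd > 0`). Missing depth fields fail the depth criteria. Per-criterion
#' drop counts are attached as the `filter_tally` attribute.
#'
#' @param variants Annotated variant table.
#' @param policy A [filter_policy()].
#' @return The retained subset, same columns.
#' @export
apply_filters <- function(variants, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  v <- data.table::as.data.table(variants)
  if (nrow(v) && any(v$origin != policy$origin)) {
    stop("policy origin '", policy$origin,
         "' does not match variant origins", call. = FALSE)
  }
  pass_ad <- !is.na(v$allele_depth) & v$allele_depth >= policy$min_ad
  pass_vaf <- !is.na(v$vaf) & v$vaf > policy$min_vaf
  pass_af <- if (is.na(policy$max_gnomad_af)) rep(TRUE, nrow(v)) else
    (is.na(v$gnomad_af) | v$gnomad_af <= policy$max_gnomad_af)
  pass_cadd <- if (policy$min_cadd > 0)
    (!is.na(v$cadd_phred) & v$cadd_phred >= policy$min_cadd)
  else rep(TRUE, nrow(v))
  keep <- pass_ad & pass_vaf & pass_af & pass_cadd
  tally <- c(n_input = nrow(v),
             fail_ad = sum(!pass_ad),
             fail_vaf = sum(!pass_vaf),
             fail_gnomad = sum(!pass_af),
             fail_cadd = sum(!pass_cadd),
             gnomad_missing_passed = sum(is.na(v$gnomad_af) &
                                           !is.na(policy$max_gnomad_af)),
             n_retained = sum(keep))
  out <- v[keep]
  data.table::setattr(out, "filter_tally", tally)
  out[]
}

#' Write a tab-separated audit file of retained variants
#'
#' @param variants A variant table (typically post-filter).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_audit <- function(variants, path) {
  data.table::fwrite(data.table::as.data.table(variants), path, sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(path)
}
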