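# Variant layer: VCF reading, normalization, annotation joins, filter policy.

make_test_vcf <- function() {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(path, c(
    "chr1\t100\t.\tG\tA,T\t.\tPASS\t.\tGT:AD:DP\t0/1:3,7,2:12",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD:DP\t0/1:3,7:10",
    "chr1\t300\t.\tATT\tAT\t.\tPASS\t.\tGT:AD:DP\t0/1:4,6:10"))
  path
}

test_that("read_vcf splits multi-allelic records and recomputes VAF", {
  v <- read_vcf(make_test_vcf(), origin = "somatic")
  expect_equal(nrow(v), 4L)          # 2 alts + 1 SNV + 1 indel
  first <- v[v$pos == 100]
  expect_equal(nrow(first), 2L)
  expect_setequal(first$alt, c("A", "T"))
  expect_equal(first[first$alt == "A"]$allele_depth, 7L)
  expect_equal(first[first$alt == "A"]$total_depth, 12L)
  expect_equal(first[first$alt == "A"]$vaf, 7 / 12, tolerance = 1e-9)
  snv <- v[v$pos == 200]
  expect_equal(snv$vaf, 0.7)
  expect_equal(snv$vtype, "SNV")
  # indel ATT>AT is suffix-trimmed to AT>A at the same position
  indel <- v[v$vtype == "INDEL"]
  expect_equal(indel$ref, "AT")
  expect_equal(indel$alt, "A")
  expect_equal(indel$pos, 300L)
  expect_true(all(v$origin == "somatic"))
  expect_true(all(is.na(v$cadd_phred)))
})

test_that("empty VCF body yields an empty stream without error", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"), character(0))
  v <- read_vcf(path, "germline")
  expect_equal(nrow(v), 0L)
  expect_identical(attr(v, "n_missing_depth"), 0L)
})

test_that("unreadable VCF is a fatal error naming the path", {
  expect_error(read_vcf("/nonexistent/x.vcf", "somatic"), "x.vcf")
})

test_that("allele normalization trims shared prefixes and suffixes", {
  n <- pathdisturb:::.normalize_alleles(c(100L, 50L, 10L, 7L),
                                        c("ATT", "CTG", "G", "CAG"),
                                        c("AT", "CG", "A", "CG"))
  # suffix first, then prefix; alleles never empty (anchor base retained)
  expect_equal(n$ref, c("AT", "CT", "G", "CA"))
  expect_equal(n$alt, c("A", "C", "A", "C"))
  expect_equal(n$pos, c(100L, 50L, 10L, 7L))
  # SNV untouched
  expect_equal(pathdisturb:::.variant_key("chr1", 10L, "G", "A"),
               "chr1:10:G:A")
})

test_that("annotation joins fill values and tally misses", {
  v <- read_vcf(make_test_vcf(), "somatic")
  cadd <- read_lookup_table(
    write_toy_lookup(tempfile(), "chr1", c(100L, 100L, 200L),
                     c("G", "G", "C"), c("A", "T", "T"), c(22, 3, 17)),
    "numeric")
  gene <- read_lookup_table(
    write_toy_lookup(tempfile(), "chr1", 200L, "C", "T", "TP53"),
    "character")
  a <- annotate_variants(v, cadd_table = cadd, gene_table = gene)
  expect_equal(a[a$pos == 100 & a$alt == "A"]$cadd_phred, 22)
  expect_equal(a[a$pos == 200]$gene, "TP53")
  expect_true(is.na(a[a$vtype == "INDEL"]$cadd_phred))
  misses <- attr(a, "annotation_misses")
  expect_equal(unname(misses["cadd"]), 1L)   # the indel
  expect_equal(unname(misses["gene"]), 3L)
})

test_that("lookup join is robust to untrimmed indel representation", {
  # table stores the verbose ATT>AT form; reader emits trimmed AT>A
  v <- read_vcf(make_test_vcf(), "somatic")
  cadd <- read_lookup_table(
    write_toy_lookup(tempfile(), "chr1", 300L, "ATT", "AT", 33), "numeric")
  a <- annotate_variants(v, cadd_table = cadd)
  expect_equal(a[a$vtype == "INDEL"]$cadd_phred, 33)
})

test_that("malformed lookup rows are skipped with a warning", {
  path <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\tvalue",
               "chr1\t100\tG\tA\t22",
               "chr1\tnot_a_pos\tG\tA\t11",
               "chr1\t200\tC\tT\tnot_a_number"), path)
  expect_warning(tab <- read_lookup_table(path, "numeric"), "2 malformed")
  expect_equal(nrow(tab), 1L)
})

# one annotated variant per scenario row
policy_fixture <- function() {
  data.table::data.table(
    chrom = "chr1", pos = 1:6, ref = "G", alt = "A", vtype = "SNV",
    origin = "germline",
    allele_depth = c(6L, 6L, 6L, 6L, 4L, 10L),
    total_depth = c(40L, 20L, 20L, 20L, 20L, 20L),
    vaf = c(0.15, 0.3, 0.3, 0.3, 0.2, 0.5),
    cadd_phred = c(30, 30, 30, 14, 30, 20),
    gnomad_af = c(1e-4, 0.005, 1e-4, 1e-4, 1e-4, NA),
    gene = letters[1:6])
}

test_that("germline policy enforces the printed thresholds", {
  v <- policy_fixture()
  kept <- apply_filters(v, filter_policy("germline"))
  # row 1: VAF 0.15 <= 0.20 -> out; row 2: gnomAD 0.005 -> out;
  # row 4: CADD 14 -> out; row 5: AD 4 -> out; row 6: missing gnomAD passes
  expect_setequal(kept$gene, c("c", "f"))
  tally <- attr(kept, "filter_tally")
  expect_equal(unname(tally["n_retained"]), 2L)
  expect_equal(unname(tally["gnomad_missing_passed"]), 1L)
})

test_that("somatic policy has no AF restriction and VAF > 5%", {
  v <- data.table::data.table(
    chrom = "chr1", pos = 1:3, ref = "G", alt = "A", vtype = "SNV",
    origin = "somatic",
    allele_depth = c(5L, 5L, 5L), total_depth = c(100L, 100L, 100L),
    vaf = c(0.06, 0.05, 0.06), cadd_phred = c(22, 22, NA),
    gnomad_af = c(0.4, 0.4, 0.4), gene = c("a", "b", "c"))
  kept <- apply_filters(v, filter_policy("somatic"))
  # b fails VAF (strict >), c fails missing CADD with min_cadd > 0
  expect_equal(kept$gene, "a")
  kept0 <- apply_filters(v, filter_policy("somatic", min_cadd = 0))
  expect_setequal(kept0$gene, c("a", "c"))  # missing CADD passes at cutoff 0
})

test_that("filtering is idempotent and monotone in the thresholds", {
  set.seed(42)
  n <- 200L
  v <- data.table::data.table(
    chrom = "chr1", pos = seq_len(n), ref = "G", alt = "A", vtype = "SNV",
    origin = "germline",
    allele_depth = sample(0:30, n, TRUE), total_depth = 50L,
    vaf = runif(n), cadd_phred = runif(n, 0, 50),
    gnomad_af = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.01)),
    gene = sample(letters, n, TRUE))
  v$vaf <- v$allele_depth / v$total_depth
  base <- filter_policy("germline")
  once <- apply_filters(v, base)
  twice <- apply_filters(once, base)
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)
  for (i in 1:20) {
    loose <- filter_policy("germline",
                           min_ad = sample(0:10, 1), min_vaf = runif(1, 0, 0.5),
                           max_gnomad_af = runif(1, 0, 0.01),
                           min_cadd = runif(1, 0, 40))
    tight <- filter_policy("germline",
                           min_ad = loose$min_ad + sample(0:5, 1),
                           min_vaf = min(1, loose$min_vaf + runif(1, 0, 0.3)),
                           max_gnomad_af = loose$max_gnomad_af * runif(1),
                           min_cadd = min(99, loose$min_cadd + runif(1, 0, 30)))
    expect_lte(nrow(apply_filters(v, tight)), nrow(apply_filters(v, loose)))
  }
})

test_that("origin mismatch and negative thresholds are configuration errors", {
  v <- policy_fixture()
  expect_error(apply_filters(v, filter_policy("somatic")), "origin")
  expect_error(filter_policy("somatic", min_ad = -1), "min_ad")
  expect_error(filter_policy("somatic", min_vaf = 2), "min_vaf")
})

test_that("split-then-filter equals filter-then-split on multi-allelic input", {
  # multi-allelic site where only one alt passes; reading already splits, so
  # check that per-alt filtering of the split records matches a manual
  # per-allele walk of the raw record
  path <- write_toy_vcf(tempfile(fileext = ".vcf"),
                        "chr1\t100\t.\tG\tA,T\t.\tPASS\t.\tGT:AD:DP\t1/2:0,9,2:20")
  v <- read_vcf(path, "somatic")
  v$cadd_phred <- 30
  kept <- apply_filters(v, filter_policy("somatic"))
  manual <- data.frame(alt = c("A", "T"), ad = c(9L, 2L), dp = 20L)
  manual_keep <- manual$alt[manual$ad >= 5 & manual$ad / manual$dp > 0.05]
  expect_setequal(kept$alt, manual_keep)
})
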