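# Enrichment: ranked universe, running-sum ES, permutation null, NES, BH,
# pathway disturbance score.

test_that("build_universe pads, sorts and tie-breaks deterministically", {
  imp <- data.table::data.table(gene = c("z", "m", "a"),
                                impact = c(0.3, 0.5, 0.1))
  u <- build_universe(imp, c("a", "b", "m", "q", "z"))
  expect_equal(u$gene, c("m", "z", "a", "b", "q"))
  expect_equal(u$impact, c(0.5, 0.3, 0.1, 0, 0))
  expect_equal(u$n_total, 5L)
  expect_equal(u$impact_total, 0.9)
  # all-equal impacts: alphabetical order
  u2 <- build_universe(data.table::data.table(gene = c("c", "a", "b"),
                                              impact = c(1, 1, 1)),
                       c("c", "a", "b"))
  expect_equal(u2$gene, c("a", "b", "c"))
  expect_error(build_universe(imp, character(0)), "empty")
})

test_that("unexpressed genes are excluded from the universe, changing P_Miss", {
  imp <- data.table::data.table(gene = c("a", "b"), impact = c(0.5, 0.45))
  ann <- c("a", "b", "c", "d", "e")
  flags <- c(a = TRUE, b = TRUE, c = TRUE, d = FALSE, e = TRUE)
  u_excl <- build_universe(imp, ann, expressed = flags)
  expect_equal(u_excl$n_total, 4L)
  expect_false("d" %in% u_excl$gene)
  # exclusion vs impact-0 differ in the P_Miss denominator: brute-force both.
  # S chosen so the peak deviation occurs after a miss, where the 1/(N - N_S)
  # step size matters.
  u_zero <- build_universe(imp, ann)
  s <- c("b", "c")
  es_excl <- oracle_es(u_excl$gene, u_excl$impact, s)
  es_zero <- oracle_es(u_zero$gene, u_zero$impact, s)
  expect_equal(enrichment_score(u_excl, s)$es, es_excl)
  expect_equal(enrichment_score(u_zero, s)$es, es_zero)
  expect_false(isTRUE(all.equal(es_excl, es_zero)))
})

test_that("hand-walked ES examples", {
  # perfect enrichment
  u <- toy_universe(c(g1 = 1, g2 = 0, g3 = 0, g4 = 0))
  expect_equal(enrichment_score(u, "g1")$es, 1)
  # printed-formula walk: impacts .5/.3/.2/0/0, S = ranks {1, 3}
  u <- toy_universe(c(g1 = 0.5, g2 = 0.3, g3 = 0.2, g4 = 0, g5 = 0))
  r <- enrichment_score(u, c("g1", "g3"), keep_trace = TRUE)
  expect_equal(r$trace$dev, c(0.5, 0.5 - 1/3, 0.7 - 1/3, 0.7 - 2/3, -0.3),
               tolerance = 1e-12)
  expect_equal(r$es, 0.5)
  # bottom-ranked zero-impact member: positive convention gives 0, abs gives 1
  u <- toy_universe(c(g1 = 1, g2 = 1, g3 = 1, g4 = 0))
  expect_equal(enrichment_score(u, "g4", score_type = "pos")$es, 0)
  expect_equal(enrichment_score(u, "g4", score_type = "abs")$es, 1)
})

test_that("walk ES equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    genes <- sprintf("g%02d", seq_len(n))
    impacts <- round(runif(n, 0, 0.99), 3) *
      rbinom(n, 1, 0.7)                    # include zero-impact tails and ties
    if (sum(impacts) == 0) impacts[1] <- 0.5
    names(impacts) <- genes
    u <- toy_universe(impacts)
    s <- sample(genes, sample(1:min(10, n - 1), 1))
    for (type in c("pos", "abs")) {
      expect_equal(enrichment_score(u, s, score_type = type)$es,
                   oracle_es(genes, unname(impacts), s, type),
                   tolerance = 1e-12)
    }
  }
})

test_that("running-sum conservation: P_Hit(N) = member share, P_Miss(N) = 1", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    impacts <- stats::setNames(runif(n, 0, 1), sprintf("g%02d", seq_len(n)))
    u <- toy_universe(impacts)
    s <- sample(names(impacts), sample(2:5, 1))
    tr <- enrichment_score(u, s, keep_trace = TRUE)$trace
    expect_equal(tr$p_miss[n], 1, tolerance = 1e-12)
    expect_equal(tr$p_hit[n], sum(impacts[s]) / sum(impacts),
                 tolerance = 1e-12)
  }
})

test_that("permutation p-value floor, degenerate null, reproducibility", {
  set.seed(1)
  impacts <- stats::setNames(c(0.9, 0.8, 0.7, runif(47, 0, 0.05)),
                             sprintf("g%02d", 1:50))
  u <- toy_universe(impacts)
  top <- c("g01", "g02", "g03")
  r <- permutation_test(u, top, nperm = 200, seed = 5)
  # the dominant member set strictly beats every other subset: plus-one floor
  expect_equal(r$pval, 1 / 201)
  expect_equal(r, permutation_test(u, top, nperm = 200, seed = 5))
  # degenerate ceiling: members at the very bottom of the ranking score 0
  # under the positive convention, so no permutation can score lower
  bottom <- u$gene[c(u$n_total - 1L, u$n_total)]
  r_bottom <- permutation_test(u, bottom, nperm = 150, seed = 2)
  expect_equal(r_bottom$pval, 1)
  expect_error(permutation_test(u, "g01", nperm = 50), "nperm")
})

test_that("vectorised permutation ES matches per-draw brute force", {
  set.seed(13)
  impacts <- stats::setNames(c(runif(12), rep(0, 8)), sprintf("g%02d", 1:20))
  u <- toy_universe(impacts)
  for (n_s in c(1L, 3L, 7L, 15L)) {  # includes the dense n_s > n/4 branch
    es_fast <- pathdisturb:::.with_seed(31L,
      pathdisturb:::.perm_es(u, n_s, 1000L))
    # same subsets cannot be replayed (different RNG consumption), so check
    # agreement in distribution against a naive per-draw oracle
    es_slow <- replicate(1000, {
      s <- sample(u$gene, n_s)
      oracle_es(u$gene, u$impact, s)
    })
    expect_gt(suppressWarnings(stats::ks.test(es_fast, es_slow)$p.value),
              1e-3)
    # exact check: fast path on known ranks
    ranks <- sort(sample.int(u$n_total, n_s))
    es_known <- pathdisturb:::.es_from_ranks(
      ranks, cumsum(u$impact[ranks]), u$n_total, n_s, u$impact_total)
    expect_equal(es_known,
                 max(0, oracle_es(u$gene, u$impact, u$gene[ranks])),
                 tolerance = 1e-12)
  }
})

test_that("normalize_es handles ratios and degenerate null means", {
  expect_equal(normalize_es(0.5, 0.25), 2)
  expect_equal(normalize_es(0, 0.4), 0)
  expect_equal(normalize_es(0.3, 0.3), 1)
  expect_equal(normalize_es(0, 0), 0)
  expect_true(is.na(normalize_es(0.2, 0)))
  expect_error(normalize_es(0.2, -1), "null_mean")
})

test_that("BH adjustment matches the closed forms", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("pathway disturbance score is NES x mean member impact", {
  expect_equal(pathway_dscore(2, c(0.2, 0)), 0.2)
  expect_equal(pathway_dscore(3, c(0, 0, 0)), 0)
  expect_equal(pathway_dscore(1, 0.99), 0.99)
  expect_error(pathway_dscore(1, numeric(0)), "n_s")
})

test_that("score_pathways emits consistent records and skips tiny sets", {
  set.seed(21)
  impacts <- stats::setNames(c(sort(runif(10, 0.1, 0.9), TRUE), rep(0, 30)),
                             sprintf("g%02d", 1:40))
  u <- toy_universe(impacts)
  sets <- list(big = names(impacts)[c(1, 2, 3, 11)],
               singleton = names(impacts)[5],
               alien = c("x1", "x2"),
               cold = names(impacts)[30:35])
  attr(sets, "source") <- "GO"
  rec <- score_pathways(u, sets, nperm = 300, seed = 9)
  expect_setequal(rec$pathway_id, c("big", "cold"))
  expect_setequal(attr(rec, "skipped"), c("singleton", "alien"))
  # identity: dscore = nes * mean member impact, padj >= pval, floor holds
  expect_equal(rec$dscore, rec$nes * rec$mean_impact, tolerance = 1e-12)
  expect_true(all(rec$padj >= rec$pval - 1e-12))
  expect_true(all(rec$pval >= 1 / 301))
  # order-independence: per-pathway seed streams
  rec_rev <- score_pathways(u, rev(sets), nperm = 300, seed = 9)
  expect_equal(rec[order(rec$pathway_id)]$pval,
               rec_rev[order(rec_rev$pathway_id)]$pval)
})

test_that("doubling nperm keeps ES/NES direction, pval within MC error", {
  set.seed(77)
  impacts <- stats::setNames(c(runif(15, 0, 0.9), rep(0, 25)),
                             sprintf("g%02d", 1:40))
  u <- toy_universe(impacts)
  s <- names(impacts)[c(1, 2, 3, 20)]
  r1 <- permutation_test(u, s, nperm = 1000, seed = 4)
  r2 <- permutation_test(u, s, nperm = 2000, seed = 4)
  expect_identical(r1$es_obs, r2$es_obs)
  expect_equal(sign(r1$null_mean), sign(r2$null_mean))
  mc <- 4 * sqrt(r1$pval * (1 - r1$pval) / 1000)
  expect_lt(abs(r1$pval - r2$pval), mc + 2e-3)
})

test_that("run_sample: zero passing variants exits cleanly", {
  v <- data.table::data.table(
    chrom = "chr1", pos = 1L, ref = "G", alt = "A", vtype = "SNV",
    origin = "somatic", allele_depth = 1L, total_depth = 100L, vaf = 0.01,
    cadd_phred = 5, gnomad_af = NA_real_, gene = "a")
  sets <- list(p1 = c("a", "b"), p2 = c("b", "c"))
  dep <- data.table::data.table(gene = c("a", "b", "c"), score = 0.5)
  out <- run_sample(list(somatic = v), sets, dep,
                    config = run_config(nperm_somatic = 100,
                                        nperm_germline = 100))
  expect_equal(nrow(out), 0L)
  expect_named(attr(out, "tallies"), "somatic")
})

test_that("gmt round trip", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3", "g4"))
  attr(sets, "descriptions") <- c(A = "first", B = "second")
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path, source = "KEGG")
  expect_equal(back$A, sets$A)
  expect_equal(back$B, sets$B)
  expect_equal(attr(back, "descriptions")[["A"]], "first")
  expect_equal(attr(back, "source"), "KEGG")
})
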