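# Synthetic data generator: fully self-consistent VCFs, lookup tables,
# dependency scores, expression counts, GMT sets and toy ontology/relation
# graphs with controllable signal, so every stage is testable without
# downloads. Ground truth (which pathways are disturbed / convergent) is
# returned alongside the files.

#' Specification for synthetic fixtures
#'
#' Defaults describe the stated testing world: signal variants carry CADD
#' Phred scores Uniform(15, 40) (bracketing the >= 15 deleteriousness
#' threshold), background variants Uniform(0, 10); expression values follow
#' the two-component log2 mixture Normal(0.5, 0.3) / Normal(8, 1) used by the
#' expression-gate tests; 90% of the sample's impact mass is concentrated in
#' the designated disturbed pathway(s).
#'
#' @param n_genes Number of genes in the synthetic genome.
#' @param n_pathways Number of gene sets.
#' @param pathway_size Two-element range of set sizes.
#' @param n_disturbed Number of designated disturbed pathways.
#' @param signal_frac Fraction of total impact mass placed in the designated
#'   pathways.
#' @param n_signal_genes Altered genes inside each designated pathway.
#' @param n_background_genes Altered genes outside the designated pathways.
#' @param n_noise_variants Sub-threshold variants (CADD < 10) scattered
#'   anywhere, exercising the filter cascade.
#' @param expr_low,expr_high Mean and sd of the low/high log2 expression
#'   components.
#' @param expr_frac_low Fraction of genes drawn from the low (unexpressed)
#'   component.
#' @param m_samples Cohort size for [make_cohort()].
#' @param n_convergent Designated convergent pathways for [make_cohort()].
#' @param p_alter_member,p_alter_background Per-sample alteration
#'   probabilities for convergent-pathway member genes vs background genes.
#' @param n_terms Ontology terms for [make_toy_ontology()].
#' @param seed Master seed; every generator is deterministic given it.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 2000L, n_pathways = 50L,
                         pathway_size = c(10L, 50L), n_disturbed = 1L,
                         signal_frac = 0.9, n_signal_genes = 10L,
                         n_background_genes = 30L, n_noise_variants = 50L,
                         expr_low = c(mean = 0.5, sd = 0.3),
                         expr_high = c(mean = 8, sd = 1),
                         expr_frac_low = 0.3,
                         m_samples = 20L, n_convergent = 1L,
                         p_alter_member = 0.35, p_alter_background = 0.05,
                         n_terms = 30L, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_pathways = as.integer(n_pathways),
               pathway_size = as.integer(pathway_size),
               n_disturbed = as.integer(n_disturbed),
               signal_frac = signal_frac,
               n_signal_genes = as.integer(n_signal_genes),
               n_background_genes = as.integer(n_background_genes),
               n_noise_variants = as.integer(n_noise_variants),
               expr_low = expr_low, expr_high = expr_high,
               expr_frac_low = expr_frac_low,
               m_samples = as.integer(m_samples),
               n_convergent = as.integer(n_convergent),
               p_alter_member = p_alter_member,
               p_alter_background = p_alter_background,
               n_terms = as.integer(n_terms),
               seed = as.integer(seed))
  if (any(unlist(spec[c("n_genes", "n_pathways", "m_samples", "n_terms")]) < 1L)) {
    stop("all fixture counts must be positive", call. = FALSE)
  }
  if (max(spec$pathway_size) > spec$n_genes) {
    stop("pathway size exceeds the number of genes", call. = FALSE)
  }
  if (spec$n_disturbed > spec$n_pathways ||
      spec$n_convergent > spec$n_pathways) {
    stop("designated pathways must be a subset of generated pathways",
         call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

.gene_names <- function(n) sprintf("g%05d", seq_len(n))

# Genes tile chr1 in 1 kb windows; variant positions land inside the window.
.gene_window <- function(gene_idx) 1000L * gene_idx

.draw_pathways <- function(spec) {
  genes <- .gene_names(spec$n_genes)
  sizes <- sample(seq(spec$pathway_size[1L], spec$pathway_size[2L]),
                  spec$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("PW%04d", seq_len(spec$n_pathways))
  attr(sets, "descriptions") <- stats::setNames(
    sprintf("synthetic pathway %d", seq_len(spec$n_pathways)), names(sets))
  attr(sets, "source") <- "GO"
  sets
}

.write_vcf <- function(dt, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"))
  body <- if (nrow(dt)) {
    dt <- dt[order(dt$pos)]
    sprintf("chr1\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
            dt$pos, dt$ref, dt$alt, dt$total_depth - dt$allele_depth,
            dt$allele_depth, dt$total_depth)
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

# Draw one variant per requested gene: position inside the gene window,
# random SNV alleles, depths giving a VAF that passes (or fails) the policy.
.draw_variants <- function(gene_idx, cadd, gnomad_af, vaf_range) {
  n <- length(gene_idx)
  if (!n) {
    return(data.table::data.table(
      pos = integer(), ref = character(), alt = character(),
      allele_depth = integer(), total_depth = integer(),
      cadd = numeric(), gnomad_af = numeric(), gene_idx = integer()))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  dp <- sample(30:100, n, replace = TRUE)
  vaf <- stats::runif(n, vaf_range[1L], vaf_range[2L])
  ad <- pmax(5L, as.integer(round(dp * vaf)))
  data.table::data.table(
    pos = .gene_window(gene_idx) + sample.int(999L, n, replace = TRUE),
    ref = ref, alt = alt, allele_depth = ad, total_depth = dp,
    cadd = cadd, gnomad_af = gnomad_af, gene_idx = gene_idx)
}

#' Generate one synthetic sample
#'
#' Writes somatic and germline VCFs, an expression count table, CADD / gnomAD
#' / gene lookup tables, a dependency score table and a GMT file into `dir`.
#' Variants in the designated disturbed pathway(s) get high CADD (>= 15) and
#' high dependency genes; background passing variants are down-weighted so the
#' designated pathways hold `signal_frac` of the total impact mass exactly.
#' Germline variants intended to pass carry gnomAD AF <= 0.001. Output is
#' byte-identical for a given seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths), `gene_sets`, `truth`
#'   (disturbed pathway ids), `genes` (all gene symbols).
#' @export
make_sample <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .with_seed(spec$seed, {
    gene_sets <- .draw_pathways(spec)
    truth <- names(gene_sets)[seq_len(spec$n_disturbed)]
    genes <- .gene_names(spec$n_genes)
    disturbed_genes <- unique(unlist(gene_sets[truth], use.names = FALSE))
    other_genes <- setdiff(genes, disturbed_genes)

    n_sig <- min(spec$n_signal_genes, length(disturbed_genes))
    sig_genes <- sample(disturbed_genes, n_sig)
    bg_genes <- sample(other_genes, min(spec$n_background_genes,
                                        length(other_genes)))

    # dependency: high for signal genes, mid-range elsewhere; the background
    # is rescaled afterwards so the designated pathways hold signal_frac of
    # the impact mass
    dep <- stats::setNames(stats::runif(spec$n_genes, 0.05, 0.6), genes)
    dep[sig_genes] <- stats::runif(n_sig, 0.7, 1.0)

    per_origin <- function(origin) {
      vaf_range <- if (origin == "somatic") c(0.2, 0.6) else c(0.3, 0.7)
      sig <- .draw_variants(match(sig_genes, genes),
                            cadd = stats::runif(n_sig, 15, 40),
                            gnomad_af = stats::runif(n_sig, 0, 0.001),
                            vaf_range = vaf_range)
      bg <- .draw_variants(match(bg_genes, genes),
                           cadd = stats::runif(length(bg_genes), 15, 40),
                           gnomad_af = stats::runif(length(bg_genes), 0, 0.001),
                           vaf_range = vaf_range)
      noise_genes <- sample.int(spec$n_genes, spec$n_noise_variants,
                                replace = TRUE)
      noise <- .draw_variants(noise_genes,
                              cadd = stats::runif(spec$n_noise_variants, 0, 10),
                              gnomad_af = stats::runif(spec$n_noise_variants,
                                                       0, 0.5),
                              vaf_range = vaf_range)
      data.table::rbindlist(list(sig, bg, noise))
    }
    somatic <- per_origin("somatic")
    germline <- per_origin("germline")

    # rescale background dependency for the exact impact-mass split:
    # impact mass = sum_g geneCADD_g * dep_g over passing altered genes
    mass <- function(v, genes_sel) {
      v <- v[v$cadd >= 15 & v$gene_idx %in% match(genes_sel, genes)]
      if (!nrow(v)) return(0)
      agg <- v[, list(gc = sum(cadd) / (100 * .N)), by = "gene_idx"]
      sum(agg$gc * dep[genes[agg$gene_idx]])
    }
    all_v <- data.table::rbindlist(list(somatic, germline))
    sig_mass <- mass(all_v, sig_genes)
    bg_mass <- mass(all_v, bg_genes)
    if (bg_mass > 0 && sig_mass > 0 && spec$signal_frac < 1) {
      target_bg <- sig_mass * (1 - spec$signal_frac) / spec$signal_frac
      dep[bg_genes] <- pmin(1, dep[bg_genes] * target_bg / bg_mass)
    }

    # expression: altered signal/background genes always from the high
    # component (the gate must not erase the engineered signal); the rest
    # follow the stated two-component mixture
    low <- stats::rbinom(spec$n_genes, 1L, spec$expr_frac_low) == 1L
    low[match(c(sig_genes, bg_genes), genes)] <- FALSE
    lg <- ifelse(low,
                 stats::rnorm(spec$n_genes, spec$expr_low["mean"],
                              spec$expr_low["sd"]),
                 stats::rnorm(spec$n_genes, spec$expr_high["mean"],
                              spec$expr_high["sd"]))
    counts <- pmax(0, round(2^lg - 1))

    variants <- data.table::rbindlist(
      list(somatic = somatic, germline = germline), idcol = "origin")
    paths <- c(
      somatic_vcf = file.path(dir, "somatic.vcf"),
      germline_vcf = file.path(dir, "germline.vcf"),
      expression = file.path(dir, "expression.tsv"),
      cadd = file.path(dir, "cadd.tsv"),
      gnomad = file.path(dir, "gnomad.tsv"),
      genes = file.path(dir, "genes.tsv"),
      depmap = file.path(dir, "depmap.tsv"),
      gmt = file.path(dir, "genesets.gmt"))
    .write_vcf(somatic, paths["somatic_vcf"])
    .write_vcf(germline, paths["germline_vcf"])
    data.table::fwrite(data.table::data.table(gene = genes, S1 = counts),
                       paths["expression"], sep = "\t", quote = FALSE)
    lk <- unique(variants[, c("pos", "ref", "alt", "cadd", "gnomad_af",
                              "gene_idx"), with = FALSE],
                 by = c("pos", "ref", "alt"))
    write_lookup <- function(value, path) {
      data.table::fwrite(
        data.table::data.table(chrom = "chr1", pos = lk$pos, ref = lk$ref,
                               alt = lk$alt, value = value),
        path, sep = "\t", quote = FALSE)
    }
    write_lookup(lk$cadd, paths["cadd"])
    write_lookup(lk$gnomad_af, paths["gnomad"])
    write_lookup(genes[lk$gene_idx], paths["genes"])
    data.table::fwrite(data.table::data.table(gene = genes,
                                              score = unname(dep)),
                       paths["depmap"], sep = "\t", quote = FALSE)
    write_gmt(gene_sets, paths["gmt"])
    list(paths = paths, gene_sets = gene_sets, truth = truth, genes = genes)
  })
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list with optional `descriptions` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  descs <- attr(gene_sets, "descriptions")
  if (is.null(descs)) descs <- stats::setNames(names(gene_sets),
                                               names(gene_sets))
  lines <- vapply(names(gene_sets), function(id) {
    paste(c(id, descs[id], gene_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic cohort with engineered phenotypic convergence
#'
#' Each sample alters a random subset of the designated convergent pathway's
#' member genes (probability `p_alter_member` per gene) — so different
#' samples hit different members — while background genes are altered with
#' the lower `p_alter_background`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `sample_genes` (per-sample altered gene vectors),
#'   `matrix` (binary alteration matrix), `gene_sets`, `truth` (convergent
#'   pathway ids).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$m_samples < 2L) stop("cohort needs M >= 2 samples", call. = FALSE)
  .with_seed(spec$seed + 1L, {
    gene_sets <- .draw_pathways(spec)
    truth <- names(gene_sets)[seq_len(spec$n_convergent)]
    genes <- .gene_names(spec$n_genes)
    member <- genes %in% unlist(gene_sets[truth], use.names = FALSE)
    p <- ifelse(member, spec$p_alter_member, spec$p_alter_background)
    sample_genes <- lapply(seq_len(spec$m_samples), function(i) {
      genes[stats::runif(spec$n_genes) < p]
    })
    names(sample_genes) <- sprintf("S%03d", seq_len(spec$m_samples))
    list(sample_genes = sample_genes,
         matrix = build_alteration_matrix(sample_genes),
         gene_sets = gene_sets, truth = truth)
  })
}

#' Generate a toy ontology: OBO file, nested GMT, KEGG edge list
#'
#' Builds a rooted DAG of `n_terms` terms where each non-root term has 1-2
#' parents among earlier terms with mixed relation types; member genes nest
#' (child genes are a subset of each parent's genes). Also emits a KEGG-style
#' undirected edge list over the same term ids.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return List with `paths`, `gene_sets`, `root`, `edges` (the OBO DAG as a
#'   from/to/relation table).
#' @export
make_toy_ontology <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .with_seed(spec$seed + 2L, {
    n <- spec$n_terms
    # first id is the biological-process root expected by parse_obo()
    ids <- c("GO:0008150", sprintf("GO:%07d", seq_len(n)[-1L]))
    root <- ids[1L]
    genes <- .gene_names(spec$n_genes)
    # top-down nested gene sets: root gets a large pool, children subsets
    sets <- vector("list", n)
    names(sets) <- ids
    sets[[root]] <- sample(genes, min(spec$n_genes,
                                      max(spec$pathway_size) * 4L))
    parents <- vector("list", n)
    relations <- vector("list", n)
    edges <- list()
    for (i in 2:n) {
      np <- sample(1:min(2L, i - 1L), 1L)
      par <- sample(seq_len(i - 1L), np)
      rel <- sample(.go_relations, np, replace = TRUE,
                    prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
      parents[[i]] <- ids[par]
      relations[[i]] <- rel
      pool <- Reduce(intersect, sets[par])
      if (length(pool) < 2L) pool <- sets[[par[1L]]]
      sz <- max(2L, min(length(pool),
                        sample(spec$pathway_size[1L]:spec$pathway_size[2L], 1L)))
      sets[[i]] <- sample(pool, sz)
      edges[[i]] <- data.table::data.table(from = ids[i], to = ids[par],
                                           relation = rel)
    }
    edge_tab <- data.table::rbindlist(edges)
    attr(sets, "descriptions") <- stats::setNames(
      sprintf("toy term %d", seq_len(n)), ids)
    attr(sets, "source") <- "GO"

    obo_path <- file.path(dir, "toy.obo")
    gmt_path <- file.path(dir, "toy.gmt")
    kegg_path <- file.path(dir, "toy_kegg_edges.tsv")
    stanza <- function(i) {
      out <- c("[Term]", paste0("id: ", ids[i]),
               paste0("name: toy term ", i),
               "namespace: biological_process")
      for (j in seq_along(parents[[i]])) {
        out <- c(out, if (relations[[i]][j] == "is_a")
          paste0("is_a: ", parents[[i]][j], " ! toy")
          else paste0("relationship: ", relations[[i]][j], " ",
                      parents[[i]][j], " ! toy"))
      }
      c(out, "")
    }
    writeLines(c("format-version: 1.4", "",
                 unlist(lapply(seq_len(n), stanza))), obo_path)
    write_gmt(sets, gmt_path)
    ke <- unique(data.table::data.table(
      from = sample(ids, n * 2L, replace = TRUE),
      to = sample(ids, n * 2L, replace = TRUE)))
    ke <- ke[ke$from != ke$to]
    data.table::fwrite(ke, kegg_path, sep = "\t", quote = FALSE)
    list(paths = c(obo = obo_path, gmt = gmt_path, kegg = kegg_path),
         gene_sets = sets, root = root, edges = edge_tab)
  })
}
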