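small_config <- function(...) {
  scenario_config(
    genome = list(n_chrom = 1L, chrom_length = 200000L,
                  n_runs_per_chrom = 3L, n_run_len = c(40L, 120L)),
    genes = list(n_genes = 80L, max_exons = 5L,
                 exon_len = c(meanlog = log(200), sdlog = 0.4),
                 intron_len = c(meanlog = log(120), sdlog = 0.4),
                 gap_len = c(meanlog = log(600), sdlog = 0.6)),
    pseudogenes = list(n = 20L, len = c(meanlog = log(300), sdlog = 0.4)),
    transcription = modifyList(scenario_config()$transcription,
                               list(n_exon_tr = 50L, n_intron_tr = 20L,
                                    n_pseudo_tr = 15L, n_itr = 50L)),
    ...)
}

test_that("generated annotation satisfies its invariants and is reproducible", {
  cfg <- small_config()
  a1 <- generate_annotation(cfg, seed = 9)
  ann <- a1$annotation
  expect_s3_class(ann, "annotation_set")
  sl <- ann$seqlengths
  expect_true(all(end(ann$exons) <= sl[as.character(seqnames(ann$exons))]))
  # exons of one gene pairwise disjoint (constructor enforces; re-check)
  by_gene <- split(ranges(ann$exons), mcols(ann$exons)$gene_id)
  expect_true(all(vapply(by_gene, isDisjoint, logical(1))))
  # N runs in the sequence match the unmappable annotation
  expect_identical(find_unmappable(a1$genome), ann$unmappable)
  # pseudogenes never overlap gene bodies
  expect_false(any(overlapsAny(ann$pseudogenes, gene_bodies(ann))))
  # byte-identical regeneration under the same seed
  a2 <- generate_annotation(cfg, seed = 9)
  expect_identical(a1$genome, a2$genome)
  expect_identical(start(a1$annotation$exons), start(a2$annotation$exons))
})

test_that("planted region classes agree with the classifier", {
  cfg <- small_config()
  ann <- generate_annotation(cfg, seed = 10)
  tr <- generate_transcription(ann, cfg, seed = 10)
  got <- classify_regions(tr$regions, ann$annotation)
  expect_identical(got, tr$truth$class)
})

test_that("ITR fragments are shorter and narrower than exon fragments", {
  cfg <- small_config()
  ann <- generate_annotation(cfg, seed = 11)
  tr <- generate_transcription(ann, cfg, seed = 11)
  w <- width(tr$regions)
  cls <- tr$truth$class
  expect_lt(median(w[cls == "intergenic"]), median(w[cls == "exon"]))
  b <- expression_breadth(tr$profiles)
  expect_lt(median(b[cls == "intergenic"]), median(b[cls == "exon"]))
  lvl <- apply(tr$profiles$fpkm, 1, max)
  expect_lt(median(lvl[cls == "intergenic"]), median(lvl[cls == "exon"]))
})

test_that("per-dataset fragments merge back into the planted regions", {
  cfg <- small_config()
  ann <- generate_annotation(cfg, seed = 12)
  tr <- generate_transcription(ann, cfg, seed = 12)
  merged <- merge_fragments(tr$fragments)
  expressed <- tr$regions[rowSums(tr$profiles$presence) > 0]
  expect_equal(length(merged), length(expressed))
  expect_equal(start(merged), start(sort(expressed)))
  # identical matrices under the same seed
  tr2 <- generate_transcription(ann, cfg, seed = 12)
  expect_identical(tr$profiles$fpkm, tr2$profiles$fpkm)
})

test_that("match tables plant the configured conserved fraction", {
  truth <- data.frame(region_id = sprintf("r%04d", 1:800),
                      class = "intergenic")
  cfg <- scenario_config()
  m <- generate_match_tables(truth, cfg, seed = 13)
  frac <- mean(m$query$conserved_truth)
  p <- cfg$conservation$conserved_fraction["intergenic"]
  ci <- qbinom(c(0.005, 0.995), 800, p) / 800
  expect_true(frac >= ci[1] && frac <= ci[2])
  # p_c = 0 plants nothing
  cfg0 <- scenario_config(
    conservation = modifyList(cfg$conservation,
                              list(conserved_fraction = c(
                                exon = 0, intron = 0, pseudogene = 0,
                                intergenic = 0))))
  m0 <- generate_match_tables(truth, cfg0, seed = 13)
  expect_false(any(m0$query$conserved_truth))
  # all-recent duplicate mixture keeps K below the ancient range
  cfg_r <- scenario_config(
    conservation = modifyList(cfg$conservation, list(ancient_weight = 0)))
  mr <- generate_match_tables(truth, cfg_r, seed = 13)
  expect_true(all(mr$duplicates$K < 0.3))
})

test_that("methylation counts express the GBM-truth design", {
  cfg <- scenario_config()
  ids <- sprintf("r%03d", 1:150)
  gbm_true <- rep(c(TRUE, FALSE), c(30, 120))
  me <- generate_methylation(ids, cfg, seed = 14, gbm_true = gbm_true)
  expect_equal(sort(unique(me$counts$context)), c("CG", "CHG", "CHH"))
  lev <- methylation_level(me$counts$meth, me$counts$total, me$counts$sites)
  cg <- me$counts$context == "CG"
  is_g <- me$gbm_truth[me$counts$region_id]
  expect_gt(mean(lev[cg & is_g], na.rm = TRUE), 0.7)
  expect_lt(mean(lev[cg & !is_g], na.rm = TRUE), 0.55)
  # low-coverage cells propagate as missing levels
  expect_true(anyNA(lev))
})

test_that("peak generation honors extreme overlap probabilities", {
  regions <- GRanges("chr1", IRanges(seq(1000, 40000, by = 1000),
                                     width = 500))
  names(regions) <- sprintf("r%02d", seq_along(regions))
  mcols(regions)$region_class <- "exon"
  cfg1 <- scenario_config(peaks = list(
    act_p = c(exon = 1, intron = 1, pseudogene = 1, intergenic = 1),
    rep_p = c(exon = 0, intron = 0, pseudogene = 0, intergenic = 0)))
  pk <- generate_peaks(regions, cfg1, seed = 15)
  cf <- chromatin_features(regions, pk, rep(0, length(regions)))
  act_cols <- paste0("hist_cov_", names(which(histone_mark_classes() ==
                                                "activation")))
  rep_cols <- paste0("hist_cov_", names(which(histone_mark_classes() ==
                                                "repression")))
  expect_true(all(cf[, act_cols] > 0))
  expect_true(all(cf[, rep_cols] == 0))
})

test_that("zero effect sizes make the benchmark classes indistinguishable", {
  lab <- two_class_labels(80, 80, prefix = "z")
  cfg0 <- scenario_config()
  cfg0$features$effect_scale <- 0
  ft0 <- generate_feature_table(lab, cfg0, seed = 16)$features
  # standardized class difference on key separating features stays small
  d <- vapply(c("expr_max", "cons_logE", "expr_breadth"), function(f) {
    a <- ft0[[f]][lab == "phenotype_exon"]
    b <- ft0[[f]][lab != "phenotype_exon"]
    abs(mean(a) - mean(b)) / stats::sd(c(a, b))
  }, numeric(1))
  expect_true(all(d < 0.35))
  # full effects separate clearly
  ft1 <- generate_feature_table(lab, scenario_config(), seed = 16)$features
  d1 <- abs(mean(ft1$expr_breadth[lab == "phenotype_exon"]) -
              mean(ft1$expr_breadth[lab != "phenotype_exon"])) /
    stats::sd(ft1$expr_breadth)
  expect_gt(d1, 0.8)
})

test_that("scenario files round-trip through the plain-text formats", {
  cfg <- small_config()
  sim <- list(annotation = generate_annotation(cfg, 17))
  ann <- sim$annotation$annotation
  dir <- withr::local_tempdir()
  write_gff3_annotation(ann, file.path(dir, "a.gff3"))
  back <- read_gff3_annotation(file.path(dir, "a.gff3"))
  expect_identical(back$seqlengths, ann$seqlengths)
  expect_equal(start(back$exons), start(ann$exons))
  expect_equal(mcols(back$exons)$gene_id, mcols(ann$exons)$gene_id)
  expect_equal(start(back$pseudogenes), start(ann$pseudogenes))

  gr <- GRanges("chr1", IRanges(c(100, 500, 950), c(200, 900, 990)),
                strand = c("+", "-", "*"))   # "*" round-trips through "."
  mcols(gr)$name <- c("x", "y", "z")
  write_bed(gr, file.path(dir, "x.bed"))
  rb <- read_bed(file.path(dir, "x.bed"))
  expect_equal(start(rb), start(gr))
  expect_equal(end(rb), end(gr))
  expect_equal(as.character(strand(rb)), as.character(strand(gr)))
})
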