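test_that("the feature registry has exactly 44 stable names", {
  reg <- feature_registry()
  expect_equal(length(reg), 44L)
  expect_equal(sum(startsWith(reg, "expr_")), 12L)
  expect_equal(sum(startsWith(reg, "cons_")), 3L)
  expect_equal(sum(startsWith(reg, "hist_")) + sum(reg == "mnase_depth"), 13L)
  expect_equal(sum(startsWith(reg, "meth_")) + sum(startsWith(reg, "gbm_")),
               16L)
  expect_identical(reg, feature_registry())
  expect_false(anyDuplicated(reg) > 0)
})

test_that("transcription features summarize levels, median and breadth", {
  layout <- rice_dataset_layout()
  ds <- names(layout$dataset_tissue)
  fpkm <- matrix(0, 2, length(ds), dimnames = list(c("a", "b"), ds))
  fpkm["a", "anther"] <- 2
  fpkm["a", c("leaf_r1", "leaf_r2")] <- c(3, 5)
  pr <- expression_profiles(fpkm)
  tf <- transcription_features(pr)
  expect_equal(ncol(tf), 12L)
  expect_equal(tf["a", "expr_anther"], 2)
  expect_equal(tf["a", "expr_leaf"], 4)      # replicate average
  expect_equal(tf["a", "expr_max"], 5)
  expect_equal(tf["a", "expr_median_expressed"], 3)
  expect_equal(tf["a", "expr_breadth"], 2)
  # expressed nowhere: all zero
  expect_true(all(tf["b", ] == 0))
})

test_that("conservation features apply the E-value cap and CNB rules", {
  cf <- conservation_features(
    best_evalue = c(0, NA, 1e-30),
    cnb_overlap = c(0, 500, 250),
    region_length = c(1000, 1000, 500),
    scores = list(numeric(0), c(0.2, 0.8, 0.9), rep(0.5, 250)))
  expect_equal(unname(cf[, "cons_logE"]), c(180, 0, 30))
  expect_equal(unname(cf[, "cons_cnb_prop"]), c(0, 0.5, 0.5))
  expect_equal(unname(cf[, "cons_phastcons"]), c(0, 0.8, 0.5))
  expect_error(conservation_features(1e-5, 0, 0, list(numeric(0))),
               "positive")
})

test_that("chromatin features measure per-mark coverage and mark counts", {
  regions <- GRanges("chr1", IRanges(c(1000, 5000), c(1999, 5999)))
  peaks <- lapply(histone_mark_classes(), function(x) GRanges())
  peaks$H3K4me3 <- GRanges("chr1", IRanges(900, 2100))   # covers region 1
  peaks$H3K27me3 <- GRanges("chr1", IRanges(1500, 1999)) # half of region 1
  cf <- chromatin_features(regions, peaks, mnase_depth = c(2.5, 0))
  expect_equal(unname(cf[, "hist_cov_H3K4me3"]), c(1, 0))
  expect_equal(unname(cf[, "hist_cov_H3K27me3"]), c(0.5, 0))
  expect_equal(unname(cf[, "hist_n_activation"]), c(1, 0))
  expect_equal(unname(cf[, "hist_n_repression"]), c(1, 0))
  expect_equal(unname(cf[, "mnase_depth"]), c(2.5, 0))
})

test_that("a depth track is averaged over region bases", {
  region <- GRanges("chr1", IRanges(1001, 2000))
  track <- GRanges("chr1", IRanges(c(1001, 1501), c(1500, 2000)),
                   score = c(4, 2))
  cf <- chromatin_features(region,
                           lapply(histone_mark_classes(), function(x)
                             GRanges()),
                           mnase_depth = track)
  expect_equal(unname(cf[, "mnase_depth"]), 3)
})

test_that("methylation levels require 5 reads across 5 sites", {
  expect_equal(methylation_level(8, 10, 6), 0.8)
  expect_true(is.na(methylation_level(3, 4, 6)))
  expect_true(is.na(methylation_level(8, 10, 4)))
  expect_equal(methylation_level(c(8, 3), c(10, 4), c(6, 6)),
               c(0.8, NA))
})

test_that("GBM calls need CG enrichment without CHG/CHH enrichment", {
  bg <- c(CG = 0.05, CHG = 0.02, CHH = 0.02)
  mk <- function(meth, id = "r1") data.frame(
    region_id = id, tissue = "leaf", context = c("CG", "CHG", "CHH"),
    meth = meth, total = c(100, 50, 100), sites = 10)
  # CG strongly enriched, CHG/CHH at background -> GBM
  out <- gbm_call(mk(c(95, 0, 1)), bg)
  expect_equal(out$gbm, 1)
  # direct binomial-tail oracle for the single-region family
  p_cg <- pbinom(94, 100, 0.05, lower.tail = FALSE)
  expect_true(p_cg < 0.05)
  # everything enriched -> not GBM
  out2 <- gbm_call(mk(c(95, 40, 60)), bg)
  expect_equal(out2$gbm, 0)
  # CG coverage below minimums -> missing call
  low <- data.frame(region_id = "r1", tissue = "leaf",
                    context = c("CG", "CHG", "CHH"),
                    meth = c(2, 0, 0), total = c(3, 50, 50), sites = 10)
  expect_true(is.na(gbm_call(low, bg)$gbm))
})

test_that("background-rate regions are flagged GBM at most at the FDR", {
  set.seed(41)
  n <- 300
  counts <- data.frame(
    region_id = rep(sprintf("r%03d", 1:n), each = 3),
    tissue = "leaf", context = rep(c("CG", "CHG", "CHH"), n),
    meth = NA, total = 80, sites = 10)
  bg <- c(CG = 0.4, CHG = 0.2, CHH = 0.05)
  counts$meth <- rbinom(nrow(counts), counts$total, bg[counts$context])
  out <- gbm_call(counts, bg)
  expect_lte(mean(out$gbm == 1, na.rm = TRUE), 0.05)
})

test_that("feature assembly enforces the registry exactly", {
  lab <- stats::setNames(rep(c("phenotype_exon", "transcribed_pseudogene"),
                             each = 30), sprintf("x%02d", 1:60))
  ft <- generate_feature_table(lab, scenario_config(), seed = 5)$features
  expect_identical(names(ft), feature_registry())
  # bounds: coverages and proportions in [0,1]; cons_logE in [0,180]
  covs <- ft[, grepl("hist_cov_|cons_cnb_prop|^meth_", names(ft))]
  expect_true(all(covs >= 0 & covs <= 1, na.rm = TRUE))
  expect_true(all(ft$cons_logE >= 0 & ft$cons_logE <= 180))
  # unknown features are rejected
  bad <- cbind(ft, extra_feature = 1)
  expect_error(do.call(assemble_feature_vector, list(bad)), "unknown")
  expect_error(assemble_feature_vector(ft[, -1]), "missing feature")
})
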