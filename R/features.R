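# The canonical registry of the 44 predictor features:
# 12 transcription, 3 sequence conservation, 13 chromatin, 16 DNA methylation.

feature_tissues <- function() c("embryo", "endosperm", "seed_5dap",
                                "seed_10dap", "leaf", "anther", "root",
                                "infl_early", "infl_emerging")

#' Histone marks used for the chromatin features
#'
#' Ten marks with the default 8 activation / 2 repression split.
#'
#' @return Named character vector: mark -> `"activation"`/`"repression"`.
#' @export
histone_mark_classes <- function() {
  c(H3K4me1 = "activation", H3K4me2 = "activation", H3K4me3 = "activation",
    H3K9ac = "activation", H3K14ac = "activation", H3K23ac = "activation",
    H3K27ac = "activation", H3K36me3 = "activation",
    H3K9me2 = "repression", H3K27me3 = "repression")
}

meth_tissues <- function() c("embryo", "endosperm", "leaf", "panicle")
meth_contexts <- function() c("CG", "CHG", "CHH")

#' The 44-feature registry
#'
#' Canonical names and order of the 44 evolutionary and biochemical features:
#' 12 transcription (9 tissue expression levels, maximum level, median level
#' among expressed datasets, expression breadth), 3 sequence conservation
#' (-log10 best cross-species E-value, proportion overlapping a conserved
#' nucleotide block, median phastCons score over that overlap), 13 chromatin
#' (per-mark peak coverage for 10 histone marks, counts of activation and
#' repression marks with an overlapping peak, mean MNase read depth), and 16
#' DNA methylation (CG/CHG/CHH level in 4 tissues, plus a gene-body
#' methylation flag per tissue).
#'
#' @return Character vector of length 44.
#' @export
feature_registry <- function() {
  c(paste0("expr_", feature_tissues()),
    "expr_max", "expr_median_expressed", "expr_breadth",
    "cons_logE", "cons_cnb_prop", "cons_phastcons",
    paste0("hist_cov_", names(histone_mark_classes())),
    "hist_n_activation", "hist_n_repression", "mnase_depth",
    as.vector(t(outer(meth_tissues(), meth_contexts(),
                      function(t, c) paste0("meth_", t, "_", c)))),
    paste0("gbm_", meth_tissues()))
}

#' Transcription features (12)
#'
#' Nine per-tissue expression levels ([tissue_levels()] averaging rule), the
#' maximum FPKM over all datasets, the median FPKM among datasets where the
#' region is expressed (0 when expressed nowhere), and the expression breadth
#' over collapsed tissues.
#'
#' @param profiles an [expression_profiles()] object.
#' @return Numeric matrix, one row per region, 12 columns.
#' @export
transcription_features <- function(profiles) {
  tl <- tissue_levels(profiles)
  tis <- feature_tissues()
  miss <- setdiff(tis, colnames(tl))
  if (length(miss)) stop("missing tissues: ", paste(miss, collapse = ", "))
  fp <- profiles$fpkm
  pr <- profiles$presence
  med_expr <- vapply(seq_len(nrow(fp)), function(i) {
    v <- fp[i, pr[i, ]]
    if (length(v) == 0) 0 else median(v)
  }, numeric(1))
  out <- cbind(tl[, tis, drop = FALSE],
               expr_max = apply(fp, 1, max),
               expr_median_expressed = med_expr,
               expr_breadth = as.numeric(expression_breadth(profiles)))
  colnames(out)[seq_along(tis)] <- paste0("expr_", tis)
  out
}

#' Sequence-conservation features (3)
#'
#' `cons_logE`: -log10 of the minimum cross-species E-value (E = 0 capped at
#' 180; regions without a significant match score 0). `cons_cnb_prop`:
#' proportion of the region overlapping a conserved nucleotide block.
#' `cons_phastcons`: median per-base phastCons score over the overlapping
#' bases (0 when there is no overlap).
#'
#' @param best_evalue numeric vector of best cross-species E-values (`NA` =
#'   no significant match).
#' @param cnb_overlap integer vector: bases overlapping a conserved block.
#' @param region_length integer vector of region lengths (> 0).
#' @param scores list of numeric vectors: per-base conservation scores over
#'   the overlapping bases (empty when no overlap).
#' @return Numeric matrix with columns `cons_logE`, `cons_cnb_prop`,
#'   `cons_phastcons`.
#' @export
conservation_features <- function(best_evalue, cnb_overlap, region_length,
                                  scores) {
  if (any(region_length <= 0)) stop("region_length must be positive")
  stopifnot(all(cnb_overlap >= 0), all(cnb_overlap <= region_length))
  phast <- vapply(seq_along(best_evalue), function(i)
    if (cnb_overlap[i] == 0 || length(scores[[i]]) == 0) 0
    else median(scores[[i]]), numeric(1))
  cbind(cons_logE = evalue_significance(best_evalue),
        cons_cnb_prop = cnb_overlap / region_length,
        cons_phastcons = phast)
}

#' Chromatin features (13)
#'
#' Fractional coverage of each region by the peaks of each of the 10 histone
#' marks, counts of activation- and repression-associated marks with at
#' least one overlapping peak, and the mean MNase-seq read depth across the
#' region.
#'
#' @param regions `GRanges` of regions.
#' @param peaks named list of `GRanges` (one element per histone mark; names
#'   must match `names(mark_classes)`).
#' @param mnase_depth numeric vector of per-region mean MNase read depth, or
#'   a `GRanges` depth track with a `score` column (mean over region bases,
#'   uncovered bases count 0).
#' @param mark_classes mark -> class map (default [histone_mark_classes()]).
#' @return Numeric matrix, one row per region, 13 columns.
#' @export
chromatin_features <- function(regions, peaks, mnase_depth,
                               mark_classes = histone_mark_classes()) {
  marks <- names(mark_classes)
  stopifnot(all(marks %in% names(peaks)))
  cov <- vapply(marks, function(mk) {
    pk <- reduce(peaks[[mk]], ignore.strand = TRUE)
    if (length(pk) == 0) return(rep(0, length(regions)))
    ov <- findOverlaps(regions, pk, ignore.strand = TRUE)
    w <- width(pintersect(regions[queryHits(ov)], pk[subjectHits(ov)]))
    out <- rep(0, length(regions))
    agg <- tapply(w, queryHits(ov), sum)
    out[as.integer(names(agg))] <- agg
    out / width(regions)
  }, numeric(length(regions)))
  if (length(regions) == 1) cov <- matrix(cov, nrow = 1,
                                          dimnames = list(NULL, marks))
  colnames(cov) <- paste0("hist_cov_", marks)
  act <- marks[mark_classes == "activation"]
  rep_ <- marks[mark_classes == "repression"]
  n_act <- rowSums(cov[, paste0("hist_cov_", act), drop = FALSE] > 0)
  n_rep <- rowSums(cov[, paste0("hist_cov_", rep_), drop = FALSE] > 0)
  if (is(mnase_depth, "GRanges")) {
    depth <- vapply(seq_along(regions), function(i) {
      ov <- findOverlaps(regions[i], mnase_depth, ignore.strand = TRUE)
      if (length(ov) == 0) return(0)
      seg <- pintersect(rep(regions[i], length(ov)),
                        mnase_depth[subjectHits(ov)])
      sum(width(seg) * mcols(mnase_depth)$score[subjectHits(ov)]) /
        width(regions[i])
    }, numeric(1))
  } else {
    stopifnot(length(mnase_depth) == length(regions))
    depth <- as.numeric(mnase_depth)
  }
  cbind(cov, hist_n_activation = n_act, hist_n_repression = n_rep,
        mnase_depth = depth)
}

#' Methylation level with coverage minimums
#'
#' Methylated reads divided by total reads at cytosine sites of one context,
#' reported only when at least `min_reads` reads over at least `min_sites`
#' cytosine sites support the estimate; otherwise missing (`NA`).
#'
#' @param meth,total,sites integer vectors: methylated read count, total
#'   read count, cytosine sites covered.
#' @param min_reads,min_sites coverage minimums (default 5 and 5).
#' @return Numeric vector of levels in [0, 1], `NA` where unsupported.
#' @export
methylation_level <- function(meth, total, sites,
                              min_reads = 5L, min_sites = 5L) {
  stopifnot(all(meth <= total, na.rm = TRUE), all(meth >= 0, na.rm = TRUE))
  ifelse(!is.na(total) & total >= min_reads & sites >= min_sites,
         meth / total, NA_real_)
}

#' Gene-body methylation calls
#'
#' A region is gene-body methylated (GBM) in a tissue when it is
#' significantly enriched in CG methylation relative to the genome background
#' and not significantly enriched in CHG or CHH. Enrichment per context is a
#' one-sided binomial test of the methylated-read count against the
#' background level, Benjamini-Hochberg adjusted across all regions within
#' each context x tissue family. The flag is missing wherever the CG
#' methylation level itself is missing (insufficient coverage).
#'
#' @param counts data.frame with columns `region_id`, `tissue`, `context`,
#'   `meth`, `total`, `sites`.
#' @param background named numeric vector of genome-background methylation
#'   levels per context (values in (0, 1)), or a tissue x context matrix.
#' @param fdr BH-adjusted significance cutoff (default 0.05).
#' @param min_reads,min_sites coverage minimums passed to
#'   [methylation_level()].
#' @return A data.frame `region_id` x `tissue` in long form with columns
#'   `region_id`, `tissue`, `gbm` (0/1/NA).
#' @export
gbm_call <- function(counts, background, fdr = 0.05,
                     min_reads = 5L, min_sites = 5L) {
  get_bg <- function(tissue, context) {
    bg <- if (is.matrix(background)) background[tissue, context]
          else background[[context]]
    if (is.na(bg) || bg <= 0 || bg >= 1)
      stop("background level must lie in (0,1)")
    bg
  }
  counts$level <- methylation_level(counts$meth, counts$total, counts$sites,
                                    min_reads, min_sites)
  counts$sig <- NA
  # BH within each context x tissue family, over regions with usable levels
  for (fam in split(seq_len(nrow(counts)),
                    list(counts$tissue, counts$context), drop = TRUE)) {
    usable <- fam[!is.na(counts$level[fam])]
    if (length(usable) == 0) next
    p <- pbinom(counts$meth[usable] - 1L, counts$total[usable],
                get_bg(counts$tissue[usable][1], counts$context[usable][1]),
                lower.tail = FALSE)
    counts$sig[usable] <- p.adjust(p, method = "BH") <= fdr
  }
  keys <- unique(counts[, c("region_id", "tissue")])
  kstr <- paste(keys$region_id, keys$tissue)
  cstr <- paste(counts$region_id, counts$tissue)
  idx_ctx <- function(ctx) match(kstr, cstr[counts$context == ctx])
  row_ctx <- function(ctx) which(counts$context == ctx)[idx_ctx(ctx)]
  cg <- row_ctx("CG"); chg <- row_ctx("CHG"); chh <- row_ctx("CHH")
  enriched <- function(rows) !is.na(counts$sig[rows]) & counts$sig[rows]
  gbm <- as.numeric(!is.na(counts$sig[cg]) & counts$sig[cg] &
                      !enriched(chg) & !enriched(chh))
  gbm[is.na(counts$level[cg])] <- NA_real_
  gbm[is.na(cg)] <- NA_real_
  keys$gbm <- gbm
  keys
}

#' Assemble the 44-feature vector table
#'
#' Column-binds the feature blocks and checks the result against the
#' registry: exactly the 44 canonical names, in registry order, no unknown
#' or duplicated features. Missing methylation values propagate as `NA` for
#' downstream imputation.
#'
#' @param ... named numeric matrices or data.frames with equal row counts
#'   (region order must agree).
#' @return A data.frame with the 44 registry columns.
#' @export
assemble_feature_vector <- function(...) {
  parts <- list(...)
  tab <- do.call(cbind, lapply(parts, as.data.frame))
  reg <- feature_registry()
  if (anyDuplicated(names(tab)))
    stop("duplicate feature name(s): ",
         paste(unique(names(tab)[duplicated(names(tab))]), collapse = ", "))
  unknown <- setdiff(names(tab), reg)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(reg, names(tab))
  if (length(absent))
    stop("missing feature(s): ", paste(absent, collapse = ", "))
  tab[, reg]
}
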