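# Synthetic-data generators: every pipeline input with known ground truth.

#' Scenario configuration for the synthetic-data generators
#'
#' Default scenario: a ~1 Mbp genome (2 chromosomes) carrying ~500 genes,
#' 100 pseudogenes and 300 ITRs, profiled in 11 RNA-seq datasets over 9
#' tissues, with exon-like regions longer, higher-expressed and broader than
#' ITR-like regions, a 30% planted conserved fraction among ITRs, a
#' recent/ancient duplicate K mixture (means ~0.02 and ~0.7), a 300/300/30
#' benchmark (phenotype exon / transcribed pseudogene / transcribed miRNA)
#' and a designated gene-body-methylated subset. `effect_scale` rescales all
#' class differences (0 = indistinguishable classes).
#'
#' @param ... named overrides of any top-level default.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    genome = list(n_chrom = 2L, chrom_length = 500000L,
                  n_runs_per_chrom = 5L, n_run_len = c(40L, 200L)),
    genes = list(n_genes = 500L, max_exons = 8L,
                 exon_len = c(meanlog = log(250), sdlog = 0.5),
                 intron_len = c(meanlog = log(150), sdlog = 0.5),
                 gap_len = c(meanlog = log(600), sdlog = 0.7)),
    pseudogenes = list(n = 100L, len = c(meanlog = log(400), sdlog = 0.5)),
    layout = rice_dataset_layout(),
    transcription = list(
      n_exon_tr = 300L, n_intron_tr = 100L, n_pseudo_tr = 80L,
      n_itr = 300L,
      frag_len = list(exon = c(log(900), 0.4), intron = c(log(250), 0.4),
                      pseudogene = c(log(300), 0.4),
                      intergenic = c(log(250), 0.5)),
      level = list(exon = c(log(8), 1.0), intron = c(log(1.5), 1.0),
                   pseudogene = c(log(1.5), 1.0),
                   intergenic = c(log(2), 1.0)),
      breadth_p = c(exon = 0.65, intron = 0.20, pseudogene = 0.25,
                    intergenic = 0.20),
      extra_dataset_p = 0.7),
    conservation = list(
      n_null = 1000L,
      null_hit_prob = 0.3, null_s = c(offset = 5, rate = 0.4),
      planted_s = c(offset = 30, rate = 0.1),
      conserved_fraction = c(exon = 0.6, intron = 0.3, pseudogene = 0.2,
                             intergenic = 0.30),
      dup_fraction = 0.4, ancient_weight = 0.5,
      k_recent = c(meanlog = log(0.02), sdlog = 0.4),
      k_ancient = c(meanlog = log(0.7), sdlog = 0.2)),
    benchmark = list(n_phenotype_exon = 300L, n_pseudogene = 300L,
                     n_mirna = 30L),
    features = list(
      effect_scale = 1,
      level = list(phenotype_exon = c(log(8), 0.8),
                   transcribed_pseudogene = c(log(1.5), 0.8),
                   transcribed_miRNA = c(log(4), 0.8)),
      breadth_p = c(phenotype_exon = 0.65, transcribed_pseudogene = 0.20,
                    transcribed_miRNA = 0.40),
      cons_prob = c(phenotype_exon = 0.70, transcribed_pseudogene = 0.15,
                    transcribed_miRNA = 0.45),
      cons_s = list(phenotype_exon = c(20, 0.10),
                    transcribed_pseudogene = c(8, 0.30),
                    transcribed_miRNA = c(15, 0.15)),
      cnb_prob = c(phenotype_exon = 0.60, transcribed_pseudogene = 0.10,
                   transcribed_miRNA = 0.35),
      act_peak_p = c(phenotype_exon = 0.65, transcribed_pseudogene = 0.15,
                     transcribed_miRNA = 0.35),
      rep_peak_p = c(phenotype_exon = 0.08, transcribed_pseudogene = 0.30,
                     transcribed_miRNA = 0.15),
      mnase = list(phenotype_exon = c(log(2), 0.4),
                   transcribed_pseudogene = c(log(4), 0.4),
                   transcribed_miRNA = c(log(2.5), 0.4)),
      gbm_true_fraction = c(phenotype_exon = 0.5,
                            transcribed_pseudogene = 0.05,
                            transcribed_miRNA = 0.10),
      missingness = 0.10),
    methylation = list(
      background = c(CG = 0.40, CHG = 0.20, CHH = 0.05),
      gbm_cg_level = 0.85,
      te_like = c(CG = 0.60, CHG = 0.50, CHH = 0.30),
      mean_reads = 60, mean_sites = 12, lowcov_reads = 2,
      lowcov_fraction = 0.05,
      gbm_true_fraction = 0.2),
    peaks = list(
      act_p = c(exon = 0.60, intron = 0.35, pseudogene = 0.20,
                intergenic = 0.15),
      rep_p = c(exon = 0.05, intron = 0.10, pseudogene = 0.30,
                intergenic = 0.25)),
    synteny = list(n_anchors = 12L, anchor_len = 2000L, gap_len = 8000L,
                   n_regions = 50L, retention = 0.3,
                   expressed_fraction = 0.5))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "scenario_config"
  cfg
}

# Interpolate a class-specific parameter toward the pooled mean:
# scale 1 keeps full class differences, scale 0 removes them.
scale_effect <- function(value, pooled, scale) pooled + scale * (value - pooled)

#' Generate a synthetic annotation and genome
#'
#' Places genes (with exon/intron structure), pseudogenes and N runs along
#' random nucleotide chromosomes. All annotation-set invariants hold by
#' construction.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return A list with elements `annotation` ([annotation_set()]) and
#'   `genome` (named character vector of sequences).
#' @export
generate_annotation <- function(config = scenario_config(), seed = 1L) {
  set.seed(derive_seed(seed, "annotation"))
  g <- config$genome
  gn <- config$genes
  chroms <- paste0("chr", seq_len(g$n_chrom))
  sl <- stats::setNames(rep(g$chrom_length, g$n_chrom), chroms)

  exon_rows <- list()
  pseudo_rows <- list()
  genes_per_chrom <- rep_len(ceiling(gn$n_genes / g$n_chrom), g$n_chrom)
  gene_i <- 0L
  for (ci in seq_len(g$n_chrom)) {
    pos <- 1L
    placed <- 0L
    while (placed < genes_per_chrom[ci] && gene_i < gn$n_genes) {
      pos <- pos + as.integer(rlnorm(1, gn$gap_len["meanlog"],
                                     gn$gap_len["sdlog"])) + 1L
      n_ex <- sample.int(gn$max_exons, 1L,
                         prob = 0.6^seq_len(gn$max_exons))
      ex_len <- pmax(30L, as.integer(rlnorm(n_ex, gn$exon_len["meanlog"],
                                            gn$exon_len["sdlog"])))
      in_len <- if (n_ex > 1)
        pmax(20L, as.integer(rlnorm(n_ex - 1, gn$intron_len["meanlog"],
                                    gn$intron_len["sdlog"])))
      else integer(0)
      if (pos + sum(ex_len) + sum(in_len) > sl[ci]) break
      gene_i <- gene_i + 1L
      starts <- pos + cumsum(c(0L, head(ex_len, -1) + in_len))
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        chrom = chroms[ci], start = starts, end = starts + ex_len - 1L,
        strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("gene_%04d", gene_i))
      pos <- pos + sum(ex_len) + sum(in_len)
      placed <- placed + 1L
    }
  }
  ex_df <- do.call(rbind, exon_rows)
  exons <- df_to_granges(ex_df)

  # pseudogenes and N runs go into the space outside gene bodies;
  # free tracts are kept as plain vectors and split as intervals land
  gene_rng <- unlist(range(split(ranges(exons),
                                 paste(seqnames(exons),
                                       mcols(exons)$gene_id))))
  gene_chr <- sub(" .*", "", names(gene_rng))
  occupied <- reduce(GRanges(gene_chr, gene_rng), ignore.strand = TRUE)
  free0 <- setdiff(GRanges(chroms, IRanges(1L, sl)), occupied,
                   ignore.strand = TRUE)
  tracts <- data.frame(chrom = as.character(seqnames(free0)),
                       start = start(free0), end = end(free0))
  place_in_free <- function(n, lens) {
    out_chr <- character(0); out_s <- integer(0); out_e <- integer(0)
    for (i in seq_len(n)) {
      w <- tracts$end - tracts$start + 1L
      fit <- which(w >= lens[i] + 2L)
      if (length(fit) == 0) break
      t_idx <- fit[sample.int(length(fit), 1L,
                              prob = w[fit] - lens[i] - 1L)]
      s <- tracts$start[t_idx] +
        sample.int(w[t_idx] - lens[i] - 1L, 1L)
      e <- s + lens[i] - 1L
      out_chr <- c(out_chr, tracts$chrom[t_idx])
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      # split the tract around the placed interval
      right <- data.frame(chrom = tracts$chrom[t_idx], start = e + 1L,
                          end = tracts$end[t_idx])
      split_t <- tracts
      split_t$end[t_idx] <- s - 1L
      tracts <<- rbind(split_t, right)
    }
    sort(GRanges(out_chr, IRanges(out_s, out_e)))
  }
  ps_len <- pmax(100L, as.integer(rlnorm(config$pseudogenes$n,
                                         config$pseudogenes$len["meanlog"],
                                         config$pseudogenes$len["sdlog"])))
  pseudogenes <- place_in_free(config$pseudogenes$n, ps_len)
  n_total <- g$n_runs_per_chrom * g$n_chrom
  n_lens <- as.integer(runif(n_total, g$n_run_len[1], g$n_run_len[2]))
  n_runs <- place_in_free(n_total, n_lens)

  genome <- vapply(chroms, function(chr) {
    s <- sample(c("A", "C", "G", "T"), sl[chr], replace = TRUE)
    runs <- n_runs[seqnames(n_runs) == chr]
    for (i in seq_along(runs))
      s[start(runs)[i]:end(runs)[i]] <- "N"
    paste(s, collapse = "")
  }, character(1))

  annotation <- annotation_set(sl, exons, pseudogenes,
                               unmappable = find_unmappable(genome))
  list(annotation = annotation, genome = genome)
}

# Random sub-interval of length len inside [lo, hi]; shrinks len to fit.
sub_interval <- function(lo, hi, len) {
  len <- min(len, hi - lo + 1L)
  s <- lo + sample.int(hi - lo + 1L - len + 1L, 1L) - 1L
  c(s, s + len - 1L)
}

#' Generate transcribed regions, fragments and the FPKM matrix
#'
#' Plants transcribed regions of all four classes (exon, intron, pseudogene,
#' intergenic) with class-dependent length, expression-level and breadth
#' distributions, and emits per-dataset fragments, the FPKM matrix, presence
#' flags and the planted class truth.
#'
#' @param ann result of [generate_annotation()].
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return A list: `regions` (named `GRanges` with `region_class` truth),
#'   `fragments` (named list of per-dataset `GRanges`), `profiles`
#'   ([expression_profiles()]), `truth` (data.frame `region_id`, `class`,
#'   `breadth`).
#' @export
generate_transcription <- function(ann, config = scenario_config(),
                                   seed = 1L) {
  set.seed(derive_seed(seed, "transcription"))
  tc <- config$transcription
  annotation <- ann$annotation
  exons <- annotation$exons
  introns <- intron_ranges(annotation)
  draw_len <- function(class, n)
    pmax(50L, as.integer(rlnorm(n, tc$frag_len[[class]][1],
                                tc$frag_len[[class]][2])))

  pick_within <- function(pool, n, class) {
    pool <- pool[width(pool) >= 60L]
    idx <- sample(seq_along(pool), min(n, length(pool)))
    lens <- pmin(draw_len(class, length(idx)), width(pool)[idx])
    off <- floor(runif(length(idx)) * (width(pool)[idx] - lens + 1L))
    s <- start(pool)[idx] + as.integer(off)
    GRanges(seqnames(pool)[idx], IRanges(s, width = lens))
  }

  gene_ids <- unique(mcols(exons)$gene_id)
  ex_genes <- sample(gene_ids, min(tc$n_exon_tr, length(gene_ids)))
  # exon fragments start inside an exon (guaranteeing exon class) but may
  # run on across the gene body, as assembled transcripts do
  gb <- gene_bodies(annotation)
  gb_end <- stats::setNames(end(gb), mcols(gb)$gene_id)
  ex_tr <- unlist(GRangesList(lapply(ex_genes, function(g) {
    gx <- exons[mcols(exons)$gene_id == g]
    anchor <- gx[which.min(start(gx))]
    s <- start(anchor) + sample.int(max(1L, width(anchor) %/% 3L), 1L) - 1L
    e <- min(s + draw_len("exon", 1L) - 1L, gb_end[[g]])
    GRanges(seqnames(anchor), IRanges(s, e))
  })), use.names = FALSE)
  # intron fragments come from genes without an exon fragment so the two
  # sets of planted regions never share a base
  in_pool <- introns[!(mcols(introns)$gene_id %in% ex_genes)]
  in_tr <- pick_within(in_pool, tc$n_intron_tr, "intron")
  ps_tr <- pick_within(annotation$pseudogenes, tc$n_pseudo_tr, "pseudogene")
  itr <- sample_random_intergenic(
    annotation, draw_len("intergenic", tc$n_itr),
    transcribed = c(ex_tr, in_tr, ps_tr), genome = ann$genome,
    seed = derive_seed(seed, "itr_placement"))

  regions <- c(ex_tr, in_tr, ps_tr, itr)
  cls <- c(rep("exon", length(ex_tr)), rep("intron", length(in_tr)),
           rep("pseudogene", length(ps_tr)),
           rep("intergenic", length(itr)))
  ord <- order(as.factor(seqnames(regions)), start(regions))
  regions <- regions[ord]
  cls <- cls[ord]
  mcols(regions)$region_class <- cls
  names(regions) <- sprintf("region_%05d", seq_along(regions))

  layout <- config$layout
  datasets <- names(layout$dataset_tissue)
  groups <- unique(layout$tissue_group)
  n <- length(regions)
  breadth <- 1L + rbinom(n, length(groups) - 1L,
                         tc$breadth_p[cls])
  presence <- matrix(FALSE, n, length(datasets),
                     dimnames = list(names(regions), datasets))
  ds_group <- layout$tissue_group[layout$dataset_tissue[datasets]]
  for (i in seq_len(n)) {
    gsel <- sample(groups, breadth[i])
    for (gp in gsel) {
      ds <- datasets[ds_group == gp]
      on <- runif(length(ds)) < tc$extra_dataset_p
      if (!any(on)) on[sample.int(length(ds), 1L)] <- TRUE
      presence[i, ds] <- on
    }
  }
  fpkm <- matrix(0, n, length(datasets),
                 dimnames = dimnames(presence))
  for (i in seq_len(n)) {
    k <- sum(presence[i, ])
    if (k > 0)
      fpkm[i, presence[i, ]] <- rlnorm(k, tc$level[[cls[i]]][1],
                                       tc$level[[cls[i]]][2])
  }
  profiles <- expression_profiles(fpkm, presence, layout)
  fragments <- lapply(stats::setNames(datasets, datasets), function(ds)
    regions[presence[, ds]])
  list(regions = regions, fragments = fragments, profiles = profiles,
       truth = data.frame(region_id = names(regions), class = cls,
                          breadth = breadth))
}

draw_null_evalues <- function(n, cons) {
  has_hit <- runif(n) < cons$null_hit_prob
  s <- ifelse(has_hit,
              cons$null_s["offset"] + rexp(n, cons$null_s["rate"]), NA)
  ifelse(is.na(s), NA, 10^(-s))
}

#' Generate within- and cross-species match tables
#'
#' A planted fraction of each region class receives cross-species hits with
#' significance drawn far above the null distribution; all other regions and
#' the null calibration set draw from the null match process (a mixture of
#' hitless sequences and weak spurious hits). Within-species duplicate K
#' values follow the configured recent/ancient mixture.
#'
#' @param truth data.frame with `region_id` and `class` columns (as from
#'   [generate_transcription()]).
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return A list: `null_best` (E-values of the null set, `NA` = hitless),
#'   `query` (data.frame `region_id`, `class`, `best_evalue`,
#'   `conserved_truth`), `duplicates` (data.frame `region_id`, `K`,
#'   `recent_truth`).
#' @export
generate_match_tables <- function(truth, config = scenario_config(),
                                  seed = 1L) {
  set.seed(derive_seed(seed, "matches"))
  cons <- config$conservation
  null_best <- draw_null_evalues(cons$n_null, cons)
  n <- nrow(truth)
  p_c <- cons$conserved_fraction[truth$class]
  planted <- runif(n) < p_c
  e <- draw_null_evalues(n, cons)
  s_planted <- cons$planted_s["offset"] + rexp(n, cons$planted_s["rate"])
  e[planted] <- 10^(-s_planted[planted])
  dup <- runif(n) < cons$dup_fraction
  recent <- runif(n) >= cons$ancient_weight
  K <- ifelse(recent,
              rlnorm(n, cons$k_recent["meanlog"], cons$k_recent["sdlog"]),
              rlnorm(n, cons$k_ancient["meanlog"], cons$k_ancient["sdlog"]))
  list(null_best = null_best,
       query = data.frame(region_id = truth$region_id, class = truth$class,
                          best_evalue = e, conserved_truth = planted),
       duplicates = data.frame(region_id = truth$region_id[dup],
                               K = K[dup], recent_truth = recent[dup]))
}

#' Generate methylation read counts with a designated GBM-true subset
#'
#' GBM-true regions draw CG methylation well above the genome background and
#' CHG/CHH at background; all other regions draw every context at
#' background. A configured fraction of region x tissue x context cells gets
#' read counts below the coverage minimums.
#'
#' @param region_ids character vector of region ids.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @param gbm_true optional logical vector designating the GBM subset
#'   (default: random subset of size `gbm_true_fraction`).
#' @return A list: `counts` (long data.frame `region_id`, `tissue`,
#'   `context`, `meth`, `total`, `sites`), `background` (named levels),
#'   `gbm_truth` (named logical).
#' @export
generate_methylation <- function(region_ids, config = scenario_config(),
                                 seed = 1L, gbm_true = NULL) {
  set.seed(derive_seed(seed, "methylation"))
  mc <- config$methylation
  n <- length(region_ids)
  if (is.null(gbm_true))
    gbm_true <- runif(n) < mc$gbm_true_fraction
  grid <- expand.grid(region_id = region_ids, tissue = meth_tissues(),
                      context = meth_contexts(), stringsAsFactors = FALSE)
  lev <- mc$background[grid$context]
  is_gbm <- gbm_true[match(grid$region_id, region_ids)]
  lev[is_gbm & grid$context == "CG"] <- mc$gbm_cg_level
  lowcov <- runif(nrow(grid)) < mc$lowcov_fraction
  total <- rpois(nrow(grid), ifelse(lowcov, mc$lowcov_reads, mc$mean_reads))
  sites <- pmax(1L, rpois(nrow(grid),
                          ifelse(lowcov, 2, mc$mean_sites)))
  grid$meth <- rbinom(nrow(grid), total, lev)
  grid$total <- total
  grid$sites <- sites
  list(counts = grid, background = mc$background,
       gbm_truth = stats::setNames(gbm_true, region_ids))
}

#' Generate histone-mark peak sets
#'
#' Ten marks (8 activation, 2 repression) with class-dependent per-region
#' overlap probabilities; a covered region receives a peak spanning a random
#' 50-100% stretch of it.
#'
#' @param regions named `GRanges` with a `region_class` metadata column.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return A named list of `GRanges` (one per mark).
#' @export
generate_peaks <- function(regions, config = scenario_config(), seed = 1L) {
  set.seed(derive_seed(seed, "peaks"))
  marks <- histone_mark_classes()
  cls <- mcols(regions)$region_class
  out <- lapply(names(marks), function(mk) {
    p <- if (marks[mk] == "activation") config$peaks$act_p[cls]
         else config$peaks$rep_p[cls]
    hit <- runif(length(regions)) < p
    if (!any(hit)) return(GRanges())
    covered <- regions[hit]
    frac <- runif(sum(hit), 0.5, 1)
    w <- pmax(1L, as.integer(width(covered) * frac))
    s <- start(covered) +
      vapply(width(covered) - w + 1L, function(m) sample.int(m, 1L) - 1L,
             integer(1))
    reduce(GRanges(seqnames(covered), IRanges(s, width = w)),
           ignore.strand = TRUE)
  })
  names(out) <- names(marks)
  out
}

#' Generate a benchmark feature table with known class structure
#'
#' Draws the 44 features from class-conditional distributions: phenotype
#' exons high on expression, conservation and activation chromatin; expressed
#' pseudogenes low on those and high on repressive chromatin, nucleosome
#' density and non-CG methylation; transcribed miRNAs intermediate on
#' expression and conservation. Methylation features carry missing values at
#' the configured rate. `effect_scale = 0` collapses every class difference.
#'
#' @param labels named character vector: region id -> class (the three
#'   benchmark classes).
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return A list: `features` (data.frame, 44 registry columns, rownames =
#'   region ids, `NA` allowed in methylation columns), `labels` (the input),
#'   `gbm_truth` (named logical).
#' @export
generate_feature_table <- function(labels, config = scenario_config(),
                                   seed = 1L) {
  set.seed(derive_seed(seed, "features"))
  fc <- config$features
  es <- fc$effect_scale
  ids <- names(labels)
  cls <- as.character(labels)
  n <- length(ids)
  classes <- c("phenotype_exon", "transcribed_pseudogene",
               "transcribed_miRNA")
  stopifnot(all(cls %in% classes))

  pool <- function(v) mean(unlist(v))
  par2 <- function(lst, what, i) {
    v <- lst[[cls[i]]][what]
    scale_effect(v, pool(lapply(lst, `[`, what)), es)
  }
  parv <- function(vec) scale_effect(vec[cls], mean(vec), es)

  # transcription: presence/fpkm matrix -> real transcription features
  layout <- config$layout
  datasets <- names(layout$dataset_tissue)
  groups <- unique(layout$tissue_group)
  ds_group <- layout$tissue_group[layout$dataset_tissue[datasets]]
  breadth <- 1L + rbinom(n, length(groups) - 1L, parv(fc$breadth_p))
  presence <- matrix(FALSE, n, length(datasets),
                     dimnames = list(ids, datasets))
  fpkm <- matrix(0, n, length(datasets), dimnames = dimnames(presence))
  for (i in seq_len(n)) {
    gsel <- sample(groups, breadth[i])
    for (gp in gsel) {
      ds <- datasets[ds_group == gp]
      on <- runif(length(ds)) < 0.7
      if (!any(on)) on[sample.int(length(ds), 1L)] <- TRUE
      presence[i, ds] <- on
    }
    k <- sum(presence[i, ])
    fpkm[i, presence[i, ]] <- rlnorm(k, par2(fc$level, 1, i),
                                     fc$level[[cls[i]]][2])
  }
  trans <- transcription_features(
    expression_profiles(fpkm, presence, layout))

  # conservation
  has_hit <- runif(n) < parv(fc$cons_prob)
  s <- vapply(seq_len(n), function(i)
    par2(fc$cons_s, 1, i) + rexp(1, fc$cons_s[[cls[i]]][2]), numeric(1))
  best_e <- ifelse(has_hit, 10^(-pmin(s, 180)), NA)
  has_cnb <- runif(n) < parv(fc$cnb_prob)
  region_len <- rep(1000L, n)
  cnb_prop <- ifelse(has_cnb, stats::rbeta(n, 2, 3), 0)
  cnb_overlap <- as.integer(round(cnb_prop * region_len))
  has_cnb <- cnb_overlap > 0
  phast_shape <- c(phenotype_exon = 6, transcribed_pseudogene = 2.5,
                   transcribed_miRNA = 4.5)
  scores <- lapply(seq_len(n), function(i) {
    if (!has_cnb[i]) return(numeric(0))
    stats::rbeta(cnb_overlap[i], scale_effect(phast_shape[cls[i]],
                                              mean(phast_shape), es), 2.5)
  })
  consf <- conservation_features(best_e, cnb_overlap, region_len, scores)

  # chromatin
  marks <- histone_mark_classes()
  cov <- vapply(names(marks), function(mk) {
    p <- if (marks[mk] == "activation") parv(fc$act_peak_p)
         else parv(fc$rep_peak_p)
    ifelse(runif(n) < p, stats::rbeta(n, 2, 2), 0)
  }, numeric(n))
  colnames(cov) <- paste0("hist_cov_", names(marks))
  n_act <- rowSums(cov[, paste0("hist_cov_",
                                names(marks)[marks == "activation"]),
                       drop = FALSE] > 0)
  n_rep <- rowSums(cov[, paste0("hist_cov_",
                                names(marks)[marks == "repression"]),
                       drop = FALSE] > 0)
  mnase <- vapply(seq_len(n), function(i)
    rlnorm(1, par2(fc$mnase, 1, i), fc$mnase[[cls[i]]][2]), numeric(1))
  chrom <- cbind(cov, hist_n_activation = n_act, hist_n_repression = n_rep,
                 mnase_depth = mnase)

  # methylation: counts -> levels + BH-calibrated GBM flags via gbm_call
  gbm_true <- runif(n) < parv(fc$gbm_true_fraction)
  mcfg <- config$methylation
  meth_sim <- generate_methylation(ids, config,
                                   seed = derive_seed(seed, "bench_meth"),
                                   gbm_true = gbm_true)
  counts <- meth_sim$counts
  # pseudogenes lean TE-like: elevated CHG/CHH for the non-GBM pseudogenes
  te_sel <- !gbm_true[match(counts$region_id, ids)] &
    cls[match(counts$region_id, ids)] == "transcribed_pseudogene"
  te_lev <- scale_effect(mcfg$te_like[counts$context],
                         mcfg$background[counts$context], es)
  counts$meth[te_sel] <- rbinom(sum(te_sel), counts$total[te_sel],
                                te_lev[te_sel])
  lev_mat <- matrix(NA_real_, n, 12,
                    dimnames = list(ids, as.vector(t(outer(
                      meth_tissues(), meth_contexts(),
                      function(t, c) paste0("meth_", t, "_", c))))))
  lv <- methylation_level(counts$meth, counts$total, counts$sites)
  lev_mat[cbind(match(counts$region_id, ids),
                match(paste0("meth_", counts$tissue, "_", counts$context),
                      colnames(lev_mat)))] <- lv
  gbm <- gbm_call(counts, meth_sim$background)
  gbm_mat <- matrix(NA_real_, n, 4,
                    dimnames = list(ids, paste0("gbm_", meth_tissues())))
  gbm_mat[cbind(match(gbm$region_id, ids),
                match(paste0("gbm_", gbm$tissue), colnames(gbm_mat)))] <-
    gbm$gbm
  extra_na <- matrix(runif(n * 12) < fc$missingness, n, 12)
  lev_mat[extra_na] <- NA_real_

  feats <- assemble_feature_vector(trans, consf, chrom, lev_mat, gbm_mat)
  rownames(feats) <- ids
  list(features = feats, labels = labels,
       gbm_truth = stats::setNames(gbm_true, ids))
}

#' Generate synthetic syntenic blocks with planted duplicates
#'
#' Builds a within-species syntenic block pair (genome A and its duplicated
#' segment B), places intergenic regions in the inter-anchor gaps of genome
#' A, and plants matches inside the corresponding anchor-circumscribed
#' intervals on genome B for a configured retention fraction; a configured
#' fraction of retained partners is overlapped by a transcribed region.
#' Distractor matches falling on anchor partners are added for
#' non-retained regions so interval exclusivity is exercised.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @param species species label for the block (default `"rice"`).
#' @return A list: `block` ([syntenic_block()]), `regions` (named `GRanges`,
#'   class `intergenic`), `matches` (data.frame), `transcribed_b`
#'   (`GRanges`), `truth` (data.frame `region_id`, `duplicated`,
#'   `expressed`).
#' @export
generate_synteny <- function(config = scenario_config(), seed = 1L,
                             species = "rice") {
  set.seed(derive_seed(seed, "synteny"))
  sy <- config$synteny
  step <- sy$anchor_len + sy$gap_len
  a_start <- 1000L + (seq_len(sy$n_anchors) - 1L) * step
  b_start <- 2000000L + (seq_len(sy$n_anchors) - 1L) * step
  anchors <- data.frame(
    gene_a = sprintf("geneA_%02d", seq_len(sy$n_anchors)),
    chrom_a = "chr1", start_a = a_start,
    end_a = a_start + sy$anchor_len - 1L,
    gene_b = sprintf("geneB_%02d", seq_len(sy$n_anchors)),
    chrom_b = "chr1", start_b = b_start,
    end_b = b_start + sy$anchor_len - 1L,
    ks = rlnorm(sy$n_anchors, config$conservation$k_ancient["meanlog"],
                config$conservation$k_ancient["sdlog"]))
  block <- syntenic_block(anchors, species)

  n_gaps <- sy$n_anchors - 1L
  gap_idx <- sample.int(n_gaps, sy$n_regions, replace = TRUE)
  lo <- anchors$end_a[gap_idx] + 50L
  hi <- anchors$start_a[gap_idx + 1L] - 50L
  s <- lo + as.integer(floor(runif(sy$n_regions) * (hi - lo + 1L - 400L)))
  regions <- GRanges("chr1", IRanges(s, width = 400L))
  names(regions) <- sprintf("synreg_%03d", seq_len(sy$n_regions))
  mcols(regions)$region_class <- "intergenic"

  retained <- runif(sy$n_regions) < sy$retention
  expressed <- retained & runif(sy$n_regions) < sy$expressed_fraction
  # non-overlapping partner slots within each inter-anchor gap on genome B,
  # so one partner's transcription never spills onto another's locus
  slot_in_gap <- stats::ave(seq_len(sy$n_regions), gap_idx,
                            FUN = seq_along)
  rows <- list()
  tr_b <- GRanges()
  for (i in seq_len(sy$n_regions)) {
    k <- gap_idx[i]
    if (retained[i]) {
      lo <- anchors$end_b[k] + 10L + (slot_in_gap[i] - 1L) * 400L
      hi <- lo + 380L
      if (hi > anchors$start_b[k + 1L] - 10L)
        stop("gap too crowded for non-overlapping partner slots")
      iv <- c(lo, lo + 349L)
      rows[[length(rows) + 1]] <- data.frame(
        qseqid = names(regions)[i], sseqid = "chrB", schrom = "chr1",
        sstart = iv[1], send = iv[2], evalue = 1e-30, bitscore = 200,
        K = ifelse(runif(1) < config$conservation$ancient_weight,
                   rlnorm(1, config$conservation$k_ancient["meanlog"],
                          config$conservation$k_ancient["sdlog"]),
                   rlnorm(1, config$conservation$k_recent["meanlog"],
                          config$conservation$k_recent["sdlog"])))
      if (expressed[i])
        tr_b <- c(tr_b, GRanges("chr1", IRanges(iv[1] + 10L, iv[2] - 10L)))
    } else if (runif(1) < 0.3) {
      # distractor hit on an anchor partner: must never be returned
      rows[[length(rows) + 1]] <- data.frame(
        qseqid = names(regions)[i], sseqid = "chrB", schrom = "chr1",
        sstart = anchors$start_b[k], send = anchors$end_b[k],
        evalue = 1e-40, bitscore = 300, K = NA_real_)
    }
  }
  matches <- do.call(rbind, rows)
  list(block = block, regions = regions, matches = matches,
       transcribed_b = tr_b,
       truth = data.frame(region_id = names(regions),
                          duplicated = retained, expressed = expressed))
}

#' Run the full synthetic scenario
#'
#' Generates annotation, genome, transcription, match tables, methylation,
#' peaks, synteny fixtures and the benchmark feature table in one call, with
#' per-stage sub-seeds derived from a single master seed.
#'
#' @param config a [scenario_config()].
#' @param seed master integer seed.
#' @return A named list holding every generated component.
#' @export
simulate_scenario <- function(config = scenario_config(), seed = 1L) {
  ann <- generate_annotation(config, seed)
  tr <- generate_transcription(ann, config, seed)
  matches <- generate_match_tables(tr$truth, config, seed)
  meth <- generate_methylation(tr$truth$region_id, config, seed)
  peaks <- generate_peaks(tr$regions, config, seed)
  syn <- generate_synteny(config, seed)
  bench_labels <- stats::setNames(
    rep(c("phenotype_exon", "transcribed_pseudogene", "transcribed_miRNA"),
        c(config$benchmark$n_phenotype_exon, config$benchmark$n_pseudogene,
          config$benchmark$n_mirna)),
    sprintf("bench_%04d", seq_len(config$benchmark$n_phenotype_exon +
                                    config$benchmark$n_pseudogene +
                                    config$benchmark$n_mirna)))
  bench <- generate_feature_table(bench_labels, config, seed)
  list(config = config, annotation = ann$annotation, genome = ann$genome,
       transcription = tr, matches = matches, methylation = meth,
       peaks = peaks, synteny = syn, benchmark = bench)
}

#' Write a simulated scenario to plain-text files
#'
#' Writes the annotation (GFF3), genome (FASTA), per-dataset fragments
#' (BED), FPKM matrix, match/methylation tables and the planted truth as
#' TSV into `outdir`.
#'
#' @param sim result of [simulate_scenario()].
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_scenario <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  write_gff3_annotation(sim$annotation, p("annotation.gff3"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), p("genome.fasta"))
  for (ds in names(sim$transcription$fragments))
    write_bed(sim$transcription$fragments[[ds]],
              p(sprintf("fragments_%s.bed", ds)))
  wt <- function(x, f) write.table(x, p(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(data.frame(region_id = rownames(sim$transcription$profiles$fpkm),
                sim$transcription$profiles$fpkm, check.names = FALSE),
     "fpkm.tsv")
  wt(sim$matches$query, "cross_species_matches.tsv")
  wt(data.frame(evalue = sim$matches$null_best), "null_best_evalues.tsv")
  wt(sim$methylation$counts, "methylation_counts.tsv")
  wt(sim$transcription$truth, "truth_regions.tsv")
  wt(data.frame(region_id = names(sim$benchmark$labels),
                label = as.character(sim$benchmark$labels)),
     "truth_benchmark.tsv")
  invisible(outdir)
}
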