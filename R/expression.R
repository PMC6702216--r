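#' Default rice-style dataset/tissue layout
#'
#' Eleven RNA-seq datasets mapping to nine tissues (leaf and endosperm have
#' two replicate datasets each). For expression-breadth calculations the two
#' seed stages (5 and 10 days after pollination) collapse into a single
#' `seed` tissue and the two inflorescence stages into `inflorescence`,
#' giving seven breadth groups. The five tissues shared across species, used
#' for percent-commonality comparisons, are embryo, endosperm, seed, leaf and
#' anther.
#'
#' @return A list with elements `dataset_tissue` (named character: dataset ->
#'   tissue), `tissue_group` (named character: tissue -> breadth group) and
#'   `common_tissues` (character vector of 5).
#' @export
rice_dataset_layout <- function() {
  dataset_tissue <- c(
    embryo = "embryo",
    endosperm_r1 = "endosperm", endosperm_r2 = "endosperm",
    seed_5dap = "seed_5dap", seed_10dap = "seed_10dap",
    leaf_r1 = "leaf", leaf_r2 = "leaf",
    anther = "anther", root = "root",
    infl_early = "infl_early", infl_emerging = "infl_emerging")
  tissue_group <- c(
    embryo = "embryo", endosperm = "endosperm",
    seed_5dap = "seed", seed_10dap = "seed",
    leaf = "leaf", anther = "anther", root = "root",
    infl_early = "inflorescence", infl_emerging = "inflorescence")
  list(dataset_tissue = dataset_tissue, tissue_group = tissue_group,
       common_tissues = c("embryo", "endosperm", "seed", "leaf", "anther"))
}

#' Build per-region expression profiles
#'
#' Bundles a region x dataset FPKM matrix, the per-dataset presence calls,
#' and the dataset -> tissue and tissue -> breadth-group maps. When no
#' presence matrix is supplied, `fpkm > 0` is used as the presence proxy.
#'
#' @param fpkm numeric matrix, rows = regions (rownames required), columns =
#'   datasets (colnames required); values >= 0.
#' @param presence logical matrix of the same shape, or `NULL`.
#' @param layout a layout list as from [rice_dataset_layout()].
#' @return An object of class `expression_profiles`.
#' @export
expression_profiles <- function(fpkm, presence = NULL,
                                layout = rice_dataset_layout()) {
  stopifnot(is.matrix(fpkm), !is.null(rownames(fpkm)), !is.null(colnames(fpkm)),
            all(fpkm >= 0))
  if (is.null(presence)) presence <- fpkm > 0
  stopifnot(identical(dim(presence), dim(fpkm)))
  missing_ds <- setdiff(colnames(fpkm), names(layout$dataset_tissue))
  if (length(missing_ds))
    stop("datasets absent from layout: ", paste(missing_ds, collapse = ", "))
  fpkm[!presence] <- 0   # absent => level contributes 0
  obj <- list(fpkm = fpkm, presence = presence, layout = layout)
  class(obj) <- "expression_profiles"
  obj
}

#' @export
print.expression_profiles <- function(x, ...) {
  cat(sprintf("expression_profiles: %d regions x %d datasets (%d tissues)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              length(unique(x$layout$dataset_tissue[colnames(x$fpkm)]))))
  invisible(x)
}

#' Tissue-level expression
#'
#' Per-tissue expression level: the average FPKM when a region is expressed
#' in both replicate datasets of a tissue, the single FPKM when expressed in
#' one, and 0 when expressed in neither.
#'
#' @param profiles an [expression_profiles()] object.
#' @return Numeric matrix, rows = regions, columns = tissues.
#' @export
tissue_levels <- function(profiles) {
  tis <- profiles$layout$dataset_tissue[colnames(profiles$fpkm)]
  tissues <- unique(tis)
  out <- vapply(tissues, function(t) {
    idx <- which(tis == t)
    f <- profiles$fpkm[, idx, drop = FALSE]
    p <- profiles$presence[, idx, drop = FALSE]
    n <- rowSums(p)
    lvl <- rowSums(f * p) / pmax(n, 1L)
    lvl[n == 0] <- 0
    lvl
  }, numeric(nrow(profiles$fpkm)))
  rownames(out) <- rownames(profiles$fpkm)
  out
}

#' @rdname tissue_levels
#' @param region region id (rowname).
#' @param tissue tissue name.
#' @return `tissue_level()` returns a single numeric value.
#' @export
tissue_level <- function(profiles, region, tissue) {
  tl <- tissue_levels(profiles)
  if (!tissue %in% colnames(tl)) stop("unknown tissue: ", tissue)
  tl[region, tissue]
}

#' Expression breadth
#'
#' Number of distinct collapsed tissues (breadth groups) in which a region is
#' expressed; presence in at least one constituent dataset of a group counts.
#'
#' @param profiles an [expression_profiles()] object.
#' @return Named integer vector, one value per region.
#' @export
expression_breadth <- function(profiles) {
  tis <- profiles$layout$dataset_tissue[colnames(profiles$presence)]
  grp <- profiles$layout$tissue_group[tis]
  groups <- unique(grp)
  m <- vapply(groups, function(g)
    rowSums(profiles$presence[, grp == g, drop = FALSE]) > 0,
    logical(nrow(profiles$presence)))
  out <- as.integer(rowSums(m))
  names(out) <- rownames(profiles$presence)
  out
}

#' Expressed-tissue sets over the cross-species tissue universe
#'
#' For each region, the set of common tissues (default embryo, endosperm,
#' seed, leaf, anther) in which it is expressed; the two seed-stage datasets
#' collapse into `seed`.
#'
#' @param profiles an [expression_profiles()] object.
#' @return A named list of character vectors.
#' @export
expressed_tissue_sets <- function(profiles) {
  tis <- profiles$layout$dataset_tissue[colnames(profiles$presence)]
  grp <- profiles$layout$tissue_group[tis]
  universe <- profiles$layout$common_tissues
  lapply(stats::setNames(seq_len(nrow(profiles$presence)),
                         rownames(profiles$presence)), function(i) {
    g <- unique(grp[profiles$presence[i, ]])
    intersect(universe, g)
  })
}

#' Percent commonality of expressed tissues
#'
#' Shared expressed tissues between two regions divided by the total number
#' of expressed tissues (the union of the two sets), times 100. Symmetric and
#' bounded in [0, 100]; both regions must be expressed somewhere.
#'
#' @param tissues_a,tissues_b character vectors of expressed tissues.
#' @return Percent in [0, 100].
#' @export
percent_commonality <- function(tissues_a, tissues_b) {
  a <- unique(tissues_a)
  b <- unique(tissues_b)
  if (length(a) == 0 || length(b) == 0)
    stop("both regions must be expressed in at least one tissue")
  100 * length(intersect(a, b)) / length(union(a, b))
}

#' Breadth-matched exon-pair commonality control
#'
#' For each query pair of homologous regions with unordered expression
#' breadths (b1, b2), samples `per_query` homologous exon pairs with the same
#' unordered breadths (without replacement within a query) and returns their
#' percent-commonality values. Queries with no breadth-matched exon pair are
#' skipped with a warning.
#'
#' @param query_breadths two-column matrix/data.frame of query-pair breadths.
#' @param exon_pairs data.frame with list-columns `tissues_a`, `tissues_b`
#'   (expressed-tissue sets of each exon pair).
#' @param per_query exon pairs sampled per query (default 2).
#' @param seed integer seed.
#' @return Numeric vector of percent-commonality values.
#' @export
breadth_matched_exon_commonality <- function(query_breadths, exon_pairs,
                                             per_query = 2L, seed = 1L) {
  qb <- as.matrix(query_breadths)
  eb <- cbind(lengths(exon_pairs$tissues_a), lengths(exon_pairs$tissues_b))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  qkey <- key(qb)
  ekey <- key(eb)
  set.seed(seed)
  out <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(qb))) {
    pool <- which(ekey == qkey[i])
    if (length(pool) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    take <- pool[sample.int(length(pool), min(per_query, length(pool)))]
    out <- c(out, vapply(take, function(j)
      percent_commonality(exon_pairs$tissues_a[[j]],
                          exon_pairs$tissues_b[[j]]), numeric(1)))
  }
  if (n_skipped > 0)
    warning(n_skipped, " query pair(s) had no breadth-matched exon pair",
            call. = FALSE)
  out
}

#' Random expectation of percent commonality
#'
#' Draws `n` random tissue-set pairs matching an observed breadth pair, with
#' per-tissue selection probabilities proportional to `tissue_freqs`
#' (how often each tissue appears among regions with expression
#' conservation), and returns the percent commonality of each replicate.
#'
#' @param b1,b2 expression breadths of the pair (1..number of tissues).
#' @param tissue_freqs named positive weights over the tissue universe.
#' @param n number of random pairs (default 25).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
random_commonality <- function(b1, b2, tissue_freqs, n = 25L, seed = 1L) {
  tissues <- names(tissue_freqs)
  stopifnot(!is.null(tissues), all(tissue_freqs > 0))
  if (b1 < 1 || b2 < 1 || b1 > length(tissues) || b2 > length(tissues))
    stop("breadth outside the tissue universe")
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    a <- sample(tissues, b1, prob = tissue_freqs)
    b <- sample(tissues, b2, prob = tissue_freqs)
    percent_commonality(a, b)
  }, numeric(1))
}

#' Expression correlation of neighboring region pairs
#'
#' Computes Pearson correlations of tissue-level expression between
#' neighboring regions, categorized as within-gene (two regions of the same
#' gene), gene/gene (tandem, head-to-head or tail-to-tail by annotated
#' strand), gene/ITR and gene/pseudogene (split by whether the second region
#' lies up- or downstream of the gene), and ITR/ITR, binned by the distance
#' between the pair. Pairs where either profile has zero variance across
#' tissues are excluded. A random baseline draws up to `n_random` pairs of
#' the same category irrespective of distance.
#'
#' @param regions `GRanges` with metadata columns `region_class`
#'   (`exon`/`intron`/`pseudogene`/`intergenic`) and optional `gene_id`.
#'   Gene strand is taken from `strand(regions)`.
#' @param profiles an [expression_profiles()] object covering
#'   `names(regions)`.
#' @param distance_bins numeric breakpoints in bp (default
#'   `c(0, 500, 2000, 10000)`).
#' @param n_random random same-category pairs for the baseline (default
#'   10000).
#' @param seed integer seed.
#' @return A list with data.frames `observed` (`category`, `bin`, `n`,
#'   `median_pcc`) and `random` (`category`, `n`, `median_pcc`).
#' @export
neighbor_expression_correlation <- function(regions, profiles,
                                            distance_bins = c(0, 500, 2000, 10000),
                                            n_random = 10000L, seed = 1L) {
  tl <- tissue_levels(profiles)
  if (ncol(tl) < 2) stop("need expression in at least 2 tissues")
  ids <- names(regions)
  stopifnot(!is.null(ids), all(ids %in% rownames(tl)))
  tl <- tl[ids, , drop = FALSE]
  ok_var <- apply(tl, 1, function(v) stats::sd(v) > 0)
  cls <- mcols(regions)$region_class
  gene_id <- mcols(regions)$gene_id %||% rep(NA_character_, length(regions))

  categorize <- function(i, j) {
    ci <- cls[i]; cj <- cls[j]
    genic <- c("exon", "intron")
    if (ci %in% genic && cj %in% genic) {
      if (!is.na(gene_id[i]) && identical(gene_id[i], gene_id[j]))
        return("within_gene")
      si <- as.character(strand(regions)[i])
      sj <- as.character(strand(regions)[j])
      if (si == "*" || sj == "*" || si == sj) return("gene_gene_tandem")
      upstream <- if (start(regions)[i] <= start(regions)[j]) i else j
      return(if (as.character(strand(regions)[upstream]) == "-")
        "gene_gene_head_to_head" else "gene_gene_tail_to_tail")
    }
    pair_cat <- function(gi, oj, label) {
      side <- if (start(regions)[oj] < start(regions)[gi]) "up" else "down"
      paste0("gene_", label, "_", side)
    }
    if (ci %in% genic && cj == "intergenic") return(pair_cat(i, j, "itr"))
    if (cj %in% genic && ci == "intergenic") return(pair_cat(j, i, "itr"))
    if (ci %in% genic && cj == "pseudogene") return(pair_cat(i, j, "pseudogene"))
    if (cj %in% genic && ci == "pseudogene") return(pair_cat(j, i, "pseudogene"))
    if (ci == "intergenic" && cj == "intergenic") return("itr_itr")
    NA_character_
  }

  ord <- order(as.factor(seqnames(regions)), start(regions))
  pairs <- cbind(ord[-length(ord)], ord[-1])
  same_chr <- as.character(seqnames(regions))[pairs[, 1]] ==
    as.character(seqnames(regions))[pairs[, 2]]
  pairs <- pairs[same_chr, , drop = FALSE]

  rows <- list()
  cats <- character(nrow(pairs))
  dists <- numeric(nrow(pairs))
  pccs <- numeric(nrow(pairs))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!ok_var[i] || !ok_var[j]) next
    cat_k <- categorize(i, j)
    if (is.na(cat_k)) next
    d <- max(0, start(regions)[j] - end(regions)[i] - 1)
    if (d > max(distance_bins)) next
    cats[k] <- cat_k
    dists[k] <- d
    pccs[k] <- cor(tl[i, ], tl[j, ])
    keep[k] <- TRUE
  }
  observed <- if (any(keep)) {
    bin <- cut(dists[keep], breaks = c(distance_bins, Inf),
               include.lowest = TRUE, right = TRUE)
    agg <- aggregate(pccs[keep], list(category = cats[keep], bin = bin),
                     function(v) c(n = length(v), med = median(v)))
    data.frame(category = agg$category, bin = as.character(agg$bin),
               n = agg$x[, "n"], median_pcc = agg$x[, "med"])
  } else data.frame(category = character(0), bin = character(0),
                    n = integer(0), median_pcc = numeric(0))

  # random same-category baseline, distance-free
  set.seed(seed)
  rnd <- lapply(unique(cats[keep]), function(ct) {
    members <- which(ok_var)
    if (length(members) < 2) return(NULL)
    n_draw <- min(n_random, 5000L)
    ii <- sample(members, n_draw, replace = TRUE)
    jj <- sample(members, n_draw, replace = TRUE)
    sel <- ii != jj & vapply(seq_len(n_draw), function(k)
      identical(categorize(ii[k], jj[k]), ct), logical(1))
    if (!any(sel)) return(NULL)
    v <- vapply(which(sel), function(k) cor(tl[ii[k], ], tl[jj[k], ]),
                numeric(1))
    data.frame(category = ct, n = sum(sel), median_pcc = median(v))
  })
  random <- do.call(rbind, rnd[!vapply(rnd, is.null, logical(1))]) %||%
    data.frame(category = character(0), n = integer(0),
               median_pcc = numeric(0))
  list(observed = observed, random = random)
}
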