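#' Build a syntenic block
#'
#' A block of collinear anchor-gene pairs between two genomes (possibly the
#' same genome for within-species duplications), with the synonymous
#' substitution rate (Ks) of each anchor pair.
#'
#' @param anchors data.frame with columns `gene_a`, `chrom_a`, `start_a`,
#'   `end_a`, `gene_b`, `chrom_b`, `start_b`, `end_b`, `ks`; rows ordered
#'   along genome A.
#' @param species species whose genome carries the A side (used by the WGD
#'   assignment; `"maize"` triggers the recent-WGD rule).
#' @param block_id optional identifier.
#' @return An object of class `syntenic_block` with `median_ks` and
#'   `wgd_label` filled in.
#' @export
syntenic_block <- function(anchors, species, block_id = "block1") {
  need <- c("gene_a", "chrom_a", "start_a", "end_a",
            "gene_b", "chrom_b", "start_b", "end_b", "ks")
  stopifnot(all(need %in% names(anchors)), nrow(anchors) >= 1,
            all(anchors$ks >= 0))
  anchors <- anchors[order(anchors$start_a), , drop = FALSE]
  obj <- list(anchors = anchors, species = species, block_id = block_id,
              median_ks = median(anchors$ks))
  obj$wgd_label <- assign_wgd_label(obj$median_ks, species)
  class(obj) <- "syntenic_block"
  obj
}

#' @export
print.syntenic_block <- function(x, ...) {
  cat(sprintf("syntenic_block %s (%s): %d anchors, median Ks %.3f, WGD: %s\n",
              x$block_id, x$species, nrow(x$anchors), x$median_ks,
              x$wgd_label))
  invisible(x)
}

assign_wgd_label <- function(median_ks, species) {
  if (median_ks >= 0.7) "rho_sigma"
  else if (identical(species, "maize")) "maize_wgd"
  else "none"
}

#' Assign a syntenic block to a whole-genome duplication event
#'
#' Blocks with median anchor Ks >= 0.7 derive from the ancient rho/sigma
#' grass WGDs. Maize blocks with median Ks < 0.7 derive from the recent
#' (~12 MYA) maize WGD. Blocks below 0.7 in other species are of uncertain
#' origin and labeled `none`, which excludes them from WGD summaries.
#'
#' @param block a [syntenic_block()].
#' @return One of `"rho_sigma"`, `"maize_wgd"`, `"none"`.
#' @export
assign_wgd <- function(block) {
  stopifnot(inherits(block, "syntenic_block"))
  if (nrow(block$anchors) == 0 || all(is.na(block$anchors$ks)))
    stop("block has no anchor Ks values")
  assign_wgd_label(median(block$anchors$ks), block$species)
}

# Span of a block on genome A (first anchor start to last anchor end).
block_span_a <- function(block) {
  GRanges(block$anchors$chrom_a[1],
          IRanges(min(block$anchors$start_a), max(block$anchors$end_a)))
}

#' Identify the syntenic duplicate or ortholog of a region
#'
#' For exon and intron regions the syntenic partner is a match that overlaps
#' the partner of the anchor gene containing the region. For intergenic
#' regions (and random intergenic controls) the partner is a match that falls
#' strictly within the interval circumscribed by the partners of the two
#' anchor genes flanking the region. A region spanning an anchor boundary is
#' assigned to the inter-anchor interval holding the majority of its bases
#' (ties toward the upstream interval). The best match (minimum E-value) is
#' returned.
#'
#' @param region one-element `GRanges` on genome A, inside the block span.
#' @param region_class `"exon"`, `"intron"` or `"intergenic"`.
#' @param block a [syntenic_block()].
#' @param matches data.frame of match records with columns `qseqid`,
#'   `sseqid`, `schrom`, `sstart`, `send`, `evalue` (optionally `bitscore`,
#'   `K`); `qseqid` must contain `names(region)`.
#' @return The selected match row, or `NULL` when no match qualifies.
#' @export
syntenic_match <- function(region, region_class, block, matches) {
  stopifnot(inherits(block, "syntenic_block"), length(region) == 1)
  span <- block_span_a(block)
  if (!overlapsAny(region, span, ignore.strand = TRUE) ||
      start(region) < start(span) || end(region) > end(span))
    stop("region lies outside the block span on genome A")
  an <- block$anchors
  id <- names(region) %||% "query"
  m <- matches[matches$qseqid == id, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  m_gr <- GRanges(m$schrom, IRanges(m$sstart, m$send))

  if (region_class %in% c("exon", "intron")) {
    host <- which(an$start_a <= end(region) & an$end_a >= start(region))
    if (length(host) == 0) return(NULL)
    partner <- GRanges(an$chrom_b[host], IRanges(an$start_b[host],
                                                 an$end_b[host]))
    ok <- overlapsAny(m_gr, partner, ignore.strand = TRUE)
  } else {
    # flanking anchor pair by majority-base rule
    gaps_lo <- an$end_a[-nrow(an)] + 1L
    gaps_hi <- an$start_a[-1] - 1L
    if (length(gaps_lo) == 0) return(NULL)
    ov <- pmax(0, pmin(end(region), gaps_hi) - pmax(start(region), gaps_lo) + 1)
    if (all(ov == 0)) return(NULL)
    k <- which.max(ov)   # first maximum = upstream interval on ties
    # circumscribed interval on genome B: the open gap between the two
    # partner genes, whichever orientation the block takes on B
    b1 <- c(an$start_b[k], an$end_b[k])
    b2 <- c(an$start_b[k + 1], an$end_b[k + 1])
    if (!identical(an$chrom_b[k], an$chrom_b[k + 1])) return(NULL)
    lo <- min(max(b1), max(b2)) + 1L
    hi <- max(min(b1), min(b2)) - 1L
    if (lo > hi) return(NULL)
    target <- GRanges(an$chrom_b[k], IRanges(lo, hi))
    ok <- as.character(seqnames(m_gr)) == as.character(seqnames(target)) &
      start(m_gr) >= lo & end(m_gr) <= hi
  }
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  bs <- m$bitscore %||% rep(0, nrow(m))
  m[order(m$evalue, -bs, m$sseqid)[1], , drop = FALSE]
}

#' Syntenic duplicate retention and expression summary
#'
#' For each region class (and WGD label of the hosting block): the fraction
#' of regions with a syntenic duplicate, and among duplicates the fraction
#' whose partner locus is itself overlapped by a transcribed region, overall
#' and per substitution-rate (K) bin.
#'
#' @param regions `GRanges` (named) with a `region_class` metadata column;
#'   each region must fall within one of the supplied blocks.
#' @param blocks list of [syntenic_block()] objects.
#' @param matches match-record data.frame as in [syntenic_match()];
#'   an optional `K` column feeds the K-binned summary.
#' @param transcribed_b `GRanges` of transcribed regions on genome B.
#' @param k_breaks numeric breakpoints for K bins (default three equal-width
#'   bins over [0, 0.08]).
#' @return A list with data.frames `by_class` (`region_class`, `wgd_label`,
#'   `n`, `n_duplicated`, `prop_duplicated`, `n_expressed`,
#'   `prop_dup_expressed`) and `by_k_bin` (`region_class`, `k_bin`, `n`,
#'   `n_expressed`, `prop_expressed`).
#' @export
retention_summary <- function(regions, blocks, matches, transcribed_b,
                              k_breaks = seq(0, 0.08, length.out = 4)) {
  cls <- mcols(regions)$region_class
  stopifnot(!is.null(cls), !is.null(names(regions)))
  spans <- do.call(c, lapply(blocks, block_span_a))
  hit_block <- findOverlaps(regions, spans, type = "within",
                            ignore.strand = TRUE)
  blk_of <- rep(NA_integer_, length(regions))
  blk_of[queryHits(hit_block)] <- subjectHits(hit_block)

  rows <- lapply(seq_along(regions), function(i) {
    if (is.na(blk_of[i])) return(NULL)
    blk <- blocks[[blk_of[i]]]
    cl <- if (cls[i] %in% c("exon", "intron")) cls[i] else "intergenic"
    m <- syntenic_match(regions[i], cl, blk, matches)
    dup <- !is.null(m)
    expr <- FALSE
    kval <- NA_real_
    if (dup) {
      partner <- GRanges(m$schrom, IRanges(m$sstart, m$send))
      expr <- overlapsAny(partner, transcribed_b, ignore.strand = TRUE)
      kval <- m$K %||% NA_real_
    }
    data.frame(region_class = cls[i], wgd_label = blk$wgd_label,
               duplicated = dup, expressed = expr, K = kval)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab))
    return(list(by_class = data.frame(), by_k_bin = data.frame()))

  by_class <- do.call(rbind, lapply(
    split(tab, list(tab$region_class, tab$wgd_label), drop = TRUE),
    function(g) data.frame(
      region_class = g$region_class[1], wgd_label = g$wgd_label[1],
      n = nrow(g), n_duplicated = sum(g$duplicated),
      prop_duplicated = mean(g$duplicated),
      n_expressed = sum(g$expressed),
      prop_dup_expressed = if (any(g$duplicated))
        sum(g$expressed) / sum(g$duplicated) else NaN)))
  rownames(by_class) <- NULL

  dup_k <- tab[tab$duplicated & !is.na(tab$K), , drop = FALSE]
  by_k_bin <- if (nrow(dup_k)) {
    dup_k$k_bin <- as.character(cut(dup_k$K, breaks = k_breaks,
                                    include.lowest = TRUE))
    out <- do.call(rbind, lapply(
      split(dup_k, list(dup_k$region_class, dup_k$k_bin), drop = TRUE),
      function(g) data.frame(
        region_class = g$region_class[1], k_bin = g$k_bin[1], n = nrow(g),
        n_expressed = sum(g$expressed), prop_expressed = mean(g$expressed))))
    rownames(out) <- NULL
    out
  } else data.frame(region_class = character(0), k_bin = character(0),
                    n = integer(0), n_expressed = integer(0),
                    prop_expressed = numeric(0))
  list(by_class = by_class, by_k_bin = by_k_bin)
}
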