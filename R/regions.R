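#' Merge assembled transcript fragments across datasets
#'
#' Fragments from different RNA-seq datasets are merged when they share at
#' least one base. Bookended fragments (one ending where the next starts)
#' share no base and remain separate. Merging is strand-agnostic.
#'
#' @param fragments a `GRanges` of fragments, or a named list of `GRanges`
#'   (one element per dataset). For a plain `GRanges` an optional `dataset`
#'   metadata column records provenance.
#' @return A `GRanges` of merged, pairwise-disjoint regions. Metadata columns:
#'   `datasets` (a `CharacterList` of contributing dataset names) and
#'   `n_fragments` (number of input fragments merged). Regions are named
#'   `region_00001`, ... in sorted order.
#' @export
merge_fragments <- function(fragments) {
  if (is.list(fragments) && !is(fragments, "GRanges")) {
    nms <- names(fragments) %||% paste0("dataset", seq_along(fragments))
    frs <- lapply(seq_along(fragments), function(i) {
      g <- fragments[[i]]
      mcols(g) <- NULL
      if (length(g)) mcols(g)$dataset <- nms[i]
      g
    })
    fragments <- unlist(GRangesList(frs), use.names = FALSE)
  }
  if (length(fragments) == 0) {
    out <- GRanges()
    mcols(out)$datasets <- CharacterList()
    mcols(out)$n_fragments <- integer(0)
    return(out)
  }
  ds <- mcols(fragments)$dataset %||% rep(NA_character_, length(fragments))
  # min.gapwidth = 0 merges only fragments sharing >= 1 base
  merged <- reduce(fragments, min.gapwidth = 0L, with.revmap = TRUE,
                   ignore.strand = TRUE)
  rev <- mcols(merged)$revmap
  mcols(merged)$revmap <- NULL
  mcols(merged)$datasets <- CharacterList(
    lapply(rev, function(i) sort(unique(ds[i][!is.na(ds[i])]))))
  mcols(merged)$n_fragments <- lengths(rev)
  names(merged) <- sprintf("region_%05d", seq_along(merged))
  merged
}

#' Classify regions against annotation by priority
#'
#' Applies the priority system exon > intron > pseudogene: a region
#' overlapping any exon by at least one base is `exon`; otherwise a region
#' overlapping an intron is `intron`; otherwise pseudogene overlap gives
#' `pseudogene`; a region overlapping none of these is `intergenic` (an ITR
#' when transcribed).
#'
#' @param regions `GRanges` of regions to classify.
#' @param annotation an [annotation_set()].
#' @return A character vector of region classes, one per region.
#' @export
classify_regions <- function(regions, annotation) {
  if (length(regions) == 0) return(character(0))
  chr <- as.character(seqnames(regions))
  bad <- !(chr %in% names(annotation$seqlengths))
  if (any(bad))
    stop("unknown chromosome: ", paste(unique(chr[bad]), collapse = ", "))
  cls <- rep("intergenic", length(regions))
  hit <- function(what) overlapsAny(regions, what, ignore.strand = TRUE)
  cls[hit(annotation$pseudogenes)] <- "pseudogene"
  cls[hit(intron_ranges(annotation))] <- "intron"
  cls[hit(annotation$exons)] <- "exon"
  cls
}

#' Find likely-unmappable regions
#'
#' Regions with at least `min_run` contiguous ambiguous nucleotides (N) are
#' flagged as likely unmappable; the run length corresponds to typical
#' RNA-seq read length so reads cannot be placed there.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector of
#'   chromosome sequences over A, C, G, T, N (case-insensitive).
#' @param min_run minimum N-run length (default 40).
#' @return `GRanges` of maximal N runs with length >= `min_run`.
#' @export
find_unmappable <- function(genome, min_run = 40L) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  out <- lapply(names(genome), function(chr) {
    s <- toupper(genome[[chr]])
    if (grepl("[^ACGTN]", s))
      stop("non-nucleotide characters in sequence for ", chr)
    m <- gregexpr(sprintf("N{%d,}", min_run), s)[[1]]
    if (m[1] == -1) return(GRanges())
    GRanges(chr, IRanges(as.integer(m),
                         width = attr(m, "match.length")))
  })
  unlist(GRangesList(out), use.names = FALSE)
}

#' Sample random intergenic intervals
#'
#' Draws intervals with the requested lengths uniformly from intergenic space,
#' rejecting placements that overlap one another, transcribed regions, or
#' likely-unmappable regions. Sampled intervals containing any ambiguous
#' nucleotide are then dropped (a post-hoc filter that typically removes a few
#' percent), so the returned lengths are a sub-multiset of the request.
#'
#' @param annotation an [annotation_set()].
#' @param lengths integer vector of requested interval lengths (bp).
#' @param transcribed `GRanges` of transcribed regions to avoid.
#' @param genome optional chromosome sequences (for the N filter); `NULL`
#'   skips the filter.
#' @param seed integer seed for reproducibility.
#' @param max_retries placement attempts per length before failing.
#' @return `GRanges` of sampled intervals.
#' @export
sample_random_intergenic <- function(annotation, lengths, transcribed = GRanges(),
                                     genome = NULL, seed = 1L,
                                     max_retries = 10000L) {
  stopifnot(all(lengths > 0))
  if (length(lengths) == 0) return(GRanges())
  spaces <- annotation_spaces(annotation)
  allowed <- setdiff(spaces$intergenic,
                     reduce(transcribed, ignore.strand = TRUE),
                     ignore.strand = TRUE)
  if (total_width(allowed) == 0) stop("no intergenic space available")
  tr_chr <- as.character(seqnames(allowed))
  tr_start <- start(allowed)
  tr_width <- width(allowed)
  p_chr <- character(0)
  p_start <- integer(0)
  p_end <- integer(0)
  set.seed(seed)
  for (i in seq_along(lengths)) {
    L <- as.integer(lengths[i])
    fit <- which(tr_width >= L)
    if (length(fit) == 0)
      stop("no intergenic tract can hold an interval of length ", L)
    w <- tr_width[fit] - L + 1L
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      t_idx <- fit[sample.int(length(fit), 1L, prob = w)]
      s <- tr_start[t_idx] +
        sample.int(tr_width[t_idx] - L + 1L, 1L) - 1L
      e <- s + L - 1L
      clash <- p_chr == tr_chr[t_idx] & p_start <= e & p_end >= s
      if (!any(clash)) {
        p_chr <- c(p_chr, tr_chr[t_idx])
        p_start <- c(p_start, s)
        p_end <- c(p_end, e)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place random intergenic interval of length ", L,
           " after ", max_retries, " attempts")
  }
  out <- GRanges(p_chr, IRanges(p_start, p_end))
  if (!is.null(genome)) {
    if (is(genome, "DNAStringSet")) genome <- as.character(genome)
    has_n <- vapply(seq_along(out), function(i) {
      s <- substr(genome[[as.character(seqnames(out)[i])]],
                  start(out)[i], end(out)[i])
      grepl("N", s, ignore.case = TRUE)
    }, logical(1))
    out <- out[!has_n]
  }
  out
}

#' Distance to the nearest gene
#'
#' Returns 0 for regions overlapping a gene body, otherwise the number of
#' bases strictly between the region and the closest gene end (adjacent
#' intervals are 0 bp apart).
#'
#' @param regions `GRanges` of query regions.
#' @param genes `GRanges` of gene bodies.
#' @return Integer vector of distances (bp).
#' @export
nearest_gene_distance <- function(regions, genes) {
  if (length(genes) == 0) stop("no genes supplied")
  miss <- !(as.character(seqnames(regions)) %in%
              as.character(unique(seqnames(genes))))
  if (any(miss))
    stop("no gene on chromosome: ",
         paste(unique(as.character(seqnames(regions))[miss]), collapse = ", "))
  hits <- distanceToNearest(regions, genes, ignore.strand = TRUE)
  d <- rep(NA_integer_, length(regions))
  d[queryHits(hits)] <- mcols(hits)$distance
  d
}

#' Percent of annotated space covered by transcription
#'
#' For each annotation space (exon, intron, pseudogene, intergenic) the
#' percentage of its mappable bases covered by transcribed regions of the
#' matching class. Likely-unmappable bases are excluded from every
#' denominator. A space with zero mappable bases yields `NaN` (undefined),
#' not 0.
#'
#' @param transcribed `GRanges` of transcribed regions with a `region_class`
#'   metadata column (as from [classify_regions()]).
#' @param annotation an [annotation_set()].
#' @return A data.frame with columns `space`, `mappable_bp`, `covered_bp`,
#'   `percent`.
#' @export
space_coverage <- function(transcribed, annotation) {
  spaces <- annotation_spaces(annotation)
  cls <- mcols(transcribed)$region_class
  if (length(transcribed) && is.null(cls))
    stop("'transcribed' needs a region_class metadata column")
  out <- lapply(c("exon", "intron", "pseudogene", "intergenic"), function(sp) {
    denom <- total_width(spaces[[sp]])
    tr <- transcribed[which(cls == sp)]
    cov <- total_width(intersect(spaces[[sp]],
                                 reduce(tr, ignore.strand = TRUE),
                                 ignore.strand = TRUE))
    data.frame(space = sp, mappable_bp = denom, covered_bp = cov,
               percent = if (denom == 0) NaN else 100 * cov / denom)
  })
  do.call(rbind, out)
}

#' Fraction of gene-proximal ITRs bridged by multi-exon transcripts
#'
#' Among ITRs lying within `max_dist` bp of a gene, the fraction overlapped by
#' a multi-exon transcript chain that also overlaps a gene within `max_dist`
#' of that ITR — evidence that the intergenic fragment is a missing piece of
#' the neighboring gene rather than an independent unit.
#'
#' @param chains list of `GRanges`, each the ordered exons of one multi-exon
#'   transcript.
#' @param itrs `GRanges` of intergenic transcribed regions.
#' @param genes `GRanges` of gene bodies.
#' @param max_dist proximity cutoff in bp (default 500).
#' @return A single fraction in [0, 1]; 0 when there are no proximal ITRs or
#'   no chains.
#' @export
gene_bridging_fraction <- function(chains, itrs, genes, max_dist = 500L) {
  if (length(itrs) == 0) return(0)
  d <- suppressWarnings(distanceToNearest(itrs, genes, ignore.strand = TRUE))
  prox_idx <- queryHits(d)[mcols(d)$distance <= max_dist]
  if (length(prox_idx) == 0) return(0)
  if (length(chains) == 0) return(0)
  bridged <- vapply(prox_idx, function(i) {
    itr <- itrs[i]
    near_genes <- genes[overlapsAny(
      genes, resize(itr, width(itr) + 2L * max_dist, fix = "center"),
      ignore.strand = TRUE)]
    any(vapply(chains, function(ch)
      overlapsAny(itr, ch, ignore.strand = TRUE) &&
        any(overlapsAny(near_genes, ch, ignore.strand = TRUE)),
      logical(1)))
  }, logical(1))
  mean(bridged)
}
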