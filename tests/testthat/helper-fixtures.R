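suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# A tiny hand-built annotation: one 10 kb chromosome with two genes (one
# multi-exon), one pseudogene, and one unmappable stretch.
toy_annotation <- function() {
  exons <- GRanges("chr1", IRanges(c(1001, 1501, 3001), c(1200, 1700, 3400)),
                   strand = c("+", "+", "-"))
  mcols(exons)$gene_id <- c("g1", "g1", "g2")
  annotation_set(
    c(chr1 = 10000L), exons,
    pseudogenes = GRanges("chr1", IRanges(5001, 5400)),
    unmappable = GRanges("chr1", IRanges(8001, 8100)))
}

# Base-by-base classification oracle: label every base by priority and take
# the highest-priority label overlapped by the region.
oracle_classify <- function(region, annotation) {
  sl <- annotation$seqlengths
  chr <- as.character(seqnames(region))
  lab <- rep("intergenic", sl[[chr]])
  paint <- function(gr, value) {
    gr <- gr[as.character(seqnames(gr)) == chr]
    for (i in seq_along(gr)) lab[start(gr)[i]:end(gr)[i]] <<- value
  }
  paint(annotation$pseudogenes, "pseudogene")
  paint(intron_ranges(annotation), "intron")
  paint(annotation$exons, "exon")
  seen <- unique(lab[start(region):end(region)])
  for (v in c("exon", "intron", "pseudogene"))
    if (v %in% seen) return(v)
  "intergenic"
}

# Connected components of the >=1-shared-base overlap graph (brute force).
oracle_merge <- function(gr) {
  n <- length(gr)
  if (n == 0) return(gr)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- as.character(seqnames(gr)[i]) == as.character(seqnames(gr)[j])
    if (same && start(gr)[i] <= end(gr)[j] && end(gr)[i] >= start(gr)[j])
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(comp), function(cp) {
    m <- gr[comp == cp]
    GRanges(seqnames(m)[1], IRanges(min(start(m)), max(end(m))))
  })
  sort(unlist(GRangesList(out), use.names = FALSE))
}

# Exact expectation of percent commonality for uniform random tissue sets.
oracle_random_commonality <- function(b1, b2, n_tissues = 5) {
  sets <- function(b) combn(n_tissues, b, simplify = FALSE)
  vals <- unlist(lapply(sets(b1), function(a)
    vapply(sets(b2), function(b)
      100 * length(intersect(a, b)) / length(union(a, b)), numeric(1))))
  mean(vals)
}

two_class_labels <- function(n_pos, n_neg, prefix = "r") {
  stats::setNames(
    rep(c("phenotype_exon", "transcribed_pseudogene"), c(n_pos, n_neg)),
    sprintf("%s%04d", prefix, seq_len(n_pos + n_neg)))
}
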