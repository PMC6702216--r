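# Internal helpers shared across modules.

#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels
#' @importFrom methods is
#' @importFrom stats rnorm rlnorm rbinom rpois rexp runif
#'   p.adjust fisher.test pbinom glm binom.test predict coef
#'   aggregate na.omit rbeta approx lm binomial
#'   complete.cases wilcox.test setNames
#' @importFrom utils head read.delim write.table
NULL

# Ascending nearest-rank percentile: the value at rank ceiling(p/100 * n).
nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0, p >= 0, p <= 100)
  s <- sort(x)
  unname(s[max(1L, ceiling(p / 100 * length(s)))])
}

# Derive a reproducible 32-bit sub-seed from a master seed and a stage tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a data.frame with chrom/start/end (1-based closed) into GRanges.
df_to_granges <- function(df, seqlengths = NULL) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                strand = df$strand %||% "*")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  for (nm in extra) mcols(gr)[[nm]] <- df[[nm]]
  gr
}

total_width <- function(gr) sum(as.numeric(width(gr)))
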