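#' Read a BLAST tabular file
#'
#' Reads the 12-column tabular format (outfmt 6): qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' An optional 13th column is read as a per-base substitution rate `K`.
#'
#' @param path file path.
#' @return A data.frame of match records.
#' @export
read_blast_tab <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (ncol(df) < 12) stop("expected >= 12 tabular columns")
  names(df)[1:12] <- cols
  if (ncol(df) >= 13) names(df)[13] <- "K"
  df
}

# Significance transform: s = -log10(E); no hit -> 0; E = 0 -> capped at 180
# (the same cap applied to the conservation feature).
evalue_significance <- function(evalue) {
  s <- ifelse(is.na(evalue), 0, ifelse(evalue <= 0, 180, -log10(evalue)))
  pmin(s, 180)
}

#' Best match per query
#'
#' Selects the most significant match: minimum E-value, ties broken by
#' maximum bitscore, then lexicographically smallest subject id.
#'
#' @param matches data.frame with at least `qseqid`, `sseqid`, `evalue`
#'   columns (optionally `bitscore`).
#' @param query query id.
#' @return The selected row (one-row data.frame), or `NULL` when the query
#'   has no match.
#' @export
best_match <- function(matches, query) {
  m <- matches[matches$qseqid == query, , drop = FALSE]
  if (nrow(m) == 0) return(NULL)
  bs <- m$bitscore %||% rep(0, nrow(m))
  ord <- order(m$evalue, -bs, m$sseqid)
  m[ord[1], , drop = FALSE]
}

#' Empirical conservation threshold from a null set
#'
#' Derives the cross-species significance threshold from the best-hit
#' E-values of random, unexpressed (null) sequences. Each null best hit is
#' converted to a significance s = -log10(E) (no hit: s = 0); the threshold
#' is the ascending nearest-rank `percentile` of these significances. With
#' a mostly hitless null set the threshold collapses to s = 0, i.e. to the
#' search cutoff itself; a null set with many strong spurious hits yields a
#' more stringent threshold.
#'
#' @param null_best numeric vector of null best-hit E-values, `NA` for
#'   hitless sequences.
#' @param percentile percentile of the null significance distribution
#'   (default 95).
#' @return A list of class `conservation_threshold` with elements
#'   `significance` (the s threshold) and `evalue` (`10^-s`).
#' @export
empirical_conservation_threshold <- function(null_best, percentile = 95) {
  if (length(null_best) == 0) stop("null set must be non-empty")
  s <- evalue_significance(null_best)
  s_thr <- nearest_rank(s, percentile)
  structure(list(significance = s_thr, evalue = 10^(-s_thr)),
            class = "conservation_threshold")
}

#' @export
print.conservation_threshold <- function(x, ...) {
  cat(sprintf("conservation threshold: E < %.3g (significance > %.3f)\n",
              x$evalue, x$significance))
  invisible(x)
}

#' Call cross-species conservation
#'
#' A sequence is conserved when it has a cross-species match strictly more
#' significant than the empirical null threshold.
#'
#' @param query_best numeric vector of query best-hit E-values (`NA` = no
#'   hit).
#' @param threshold a [empirical_conservation_threshold()] result.
#' @return Logical vector.
#' @export
call_conserved <- function(query_best, threshold) {
  stopifnot(inherits(threshold, "conservation_threshold"))
  !is.na(query_best) & evalue_significance(query_best) > threshold$significance
}

#' Adjust a conserved proportion for the expected false-positive rate
#'
#' Because the threshold is the 95th percentile of the null distribution, 5%
#' of truly non-conserved sequences are expected to be called conserved; that
#' 5% is subtracted from the raw proportion (floored at 0).
#'
#' @param p_raw raw conserved proportion in [0, 1].
#' @return Adjusted proportion.
#' @export
adjust_conserved_proportion <- function(p_raw) {
  if (any(is.na(p_raw)) || any(p_raw < 0) || any(p_raw > 1))
    stop("p_raw must lie in [0, 1]")
  pmax(p_raw - 0.05, 0)
}

#' Per-base substitution rate between a query and its match
#'
#' Globally aligns the two sequences (EDNAFULL-like scoring: match 5,
#' mismatch -4, affine gaps with open 10 / extend 0.5, as in EMBOSS-Needle),
#' computes the proportion p of mismatching aligned non-gap columns, and
#' applies the Jukes-Cantor correction K = -(3/4) ln(1 - (4/3) p). The raw
#' p-distance is returned alongside so externally computed rates can be
#' substituted.
#'
#' @param query_seq,subject_seq nucleotide strings.
#' @return A list with elements `K` and `p`.
#' @export
estimate_substitution_rate <- function(query_seq, subject_seq) {
  stopifnot(nzchar(query_seq), nzchar(subject_seq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(query_seq)),
    Biostrings::DNAString(toupper(subject_seq)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  if (nm + nmm == 0) stop("empty alignment: no aligned non-gap columns")
  p <- nmm / (nm + nmm)
  if (p >= 0.75)
    stop("p-distance >= 0.75: Jukes-Cantor correction undefined")
  list(K = -0.75 * log(1 - 4 * p / 3), p = p)
}

#' Expression of conserved nucleotide blocks across species
#'
#' For blocks of nucleotides conserved across all species, counts in how many
#' species each block is overlapped by a transcribed region of the block's
#' class, stratified by class.
#'
#' @param blocks data.frame with columns `block_id`, `class`, and per species
#'   `<sp>_chrom`, `<sp>_start`, `<sp>_end` (1-based closed).
#' @param transcribed named list (one element per species) of `GRanges` with
#'   a `region_class` metadata column.
#' @return A data.frame with columns `class`, `n_species_expressed`, `n`;
#'   counts sum to `nrow(blocks)`.
#' @export
cnb_expression_summary <- function(blocks, transcribed) {
  species <- names(transcribed)
  stopifnot(length(species) > 0)
  n_expr <- rep(0L, nrow(blocks))
  for (sp in species) {
    gr <- GRanges(blocks[[paste0(sp, "_chrom")]],
                  IRanges(blocks[[paste0(sp, "_start")]],
                          blocks[[paste0(sp, "_end")]]))
    tr <- transcribed[[sp]]
    cls <- mcols(tr)$region_class %||% rep("", length(tr))
    hit <- vapply(seq_len(nrow(blocks)), function(i) {
      same <- tr[cls == blocks$class[i]]
      length(same) > 0 && overlapsAny(gr[i], same, ignore.strand = TRUE)
    }, logical(1))
    n_expr <- n_expr + hit
  }
  out <- as.data.frame(table(class = blocks$class,
                             n_species_expressed = factor(
                               n_expr, levels = 0:length(species))),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  out$n_species_expressed <- as.integer(as.character(out$n_species_expressed))
  out[order(out$class, out$n_species_expressed), ]
}
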