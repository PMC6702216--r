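#' Flag likely protein-coding regions
#'
#' A transcribed region is called likely protein-coding when it contains a
#' protein domain in any translated frame or has a significant translated
#' similarity match to a plant protein (BLASTX-style E-value below
#' `e_cutoff`).
#'
#' @param protein_evalue numeric vector of best translated-protein-match
#'   E-values (`NA` = no hit).
#' @param has_domain logical vector: protein domain present.
#' @param e_cutoff significance cutoff (default `1e-5`).
#' @return Logical vector.
#' @export
call_protein_coding <- function(protein_evalue, has_domain,
                                e_cutoff = 1e-5) {
  stopifnot(length(protein_evalue) == length(has_domain))
  has_domain | (!is.na(protein_evalue) & protein_evalue < e_cutoff)
}

#' Protein domains enriched among repeats
#'
#' One-sided Fisher's exact test (greater in repeats) for each protein domain
#' observed among benchmark interspersed repeats or exon transcribed regions,
#' with Benjamini-Hochberg adjustment across all tested domains. Domains with
#' adjusted p below `fdr` are repeat-associated.
#'
#' @param repeat_counts named integer vector: number of benchmark repeats
#'   containing each domain.
#' @param n_repeats number of benchmark repeats.
#' @param exon_counts named integer vector: number of exon transcribed
#'   regions containing each domain (domains absent from a group may be
#'   omitted).
#' @param n_exon_trs number of exon transcribed regions.
#' @param fdr adjusted-p cutoff (default 0.05).
#' @return Character vector of enriched domain identifiers (possibly empty).
#' @export
repeat_domain_enrichment <- function(repeat_counts, n_repeats,
                                     exon_counts, n_exon_trs, fdr = 0.05) {
  if (n_repeats <= 0 || n_exon_trs <= 0) stop("group sizes must be positive")
  domains <- union(names(repeat_counts), names(exon_counts))
  if (length(domains) == 0) return(character(0))
  a <- ifelse(is.na(repeat_counts[domains]), 0L, repeat_counts[domains])
  b <- ifelse(is.na(exon_counts[domains]), 0L, exon_counts[domains])
  if (any(a > n_repeats) || any(b > n_exon_trs))
    stop("domain counts exceed group sizes")
  p <- vapply(seq_along(domains), function(i)
    fisher.test(matrix(c(a[i], n_repeats - a[i], b[i], n_exon_trs - b[i]),
                       nrow = 2),
                alternative = "greater")$p.value, numeric(1))
  padj <- p.adjust(p, method = "BH")
  domains[padj < fdr]
}

#' Duplicate-count threshold by F-measure maximization
#'
#' Finds the duplicate-sequence count threshold t maximizing the F1 measure
#' of the rule "repetitive iff duplicate_count >= t", with benchmark repeats
#' (e.g. long terminal repeats) as positives and exon transcribed regions as
#' negatives. Candidate thresholds are every distinct observed count plus
#' max + 1; ties are broken toward the smallest t.
#'
#' @param pos_counts duplicate counts of benchmark repeats.
#' @param neg_counts duplicate counts of exon transcribed regions.
#' @return The selected integer threshold, with the achieved F1 as attribute
#'   `"f1"`.
#' @export
duplicate_count_threshold <- function(pos_counts, neg_counts) {
  if (length(pos_counts) == 0 || length(neg_counts) == 0)
    stop("both count lists must be non-empty")
  cand <- sort(unique(c(pos_counts, neg_counts,
                        max(pos_counts, neg_counts) + 1L)))
  f1 <- vapply(cand, function(t) {
    tp <- sum(pos_counts >= t)
    fp <- sum(neg_counts >= t)
    fn <- sum(pos_counts < t)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  best <- cand[which.max(f1)]   # which.max takes the first (smallest) tie
  structure(as.integer(best), f1 = max(f1))
}

#' Flag likely repetitive regions
#'
#' A region is repetitive when it contains a repeat-associated protein domain
#' or has at least `threshold` within-species duplicate sequences.
#'
#' @param domains list of character vectors: protein domains per region.
#' @param duplicate_count integer vector of within-species duplicate counts.
#' @param enriched_domains repeat-associated domains from
#'   [repeat_domain_enrichment()].
#' @param threshold duplicate-count threshold from
#'   [duplicate_count_threshold()].
#' @return Logical vector.
#' @export
call_repetitive <- function(domains, duplicate_count, enriched_domains,
                            threshold) {
  stopifnot(threshold >= 0, length(domains) == length(duplicate_count))
  dom_hit <- vapply(domains, function(d) any(d %in% enriched_domains),
                    logical(1))
  dom_hit | duplicate_count >= threshold
}
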