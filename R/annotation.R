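#' Build an annotation set
#'
#' Container for the genome annotation consumed by region classification:
#' chromosome lengths, exons grouped by gene, pseudogene intervals and
#' likely-unmappable intervals. Introns are derived as the gaps between
#' consecutive exons of the same gene; they are never stored.
#'
#' All coordinates are 1-based closed ([GenomicRanges::GRanges]); BED input
#' and output is converted at the boundary by [read_bed()] / [write_bed()].
#'
#' @param seqlengths named integer vector of chromosome lengths (bp).
#' @param exons `GRanges` of exons with a `gene_id` metadata column. Exons of
#'   one gene must be pairwise disjoint.
#' @param pseudogenes `GRanges` of pseudogene intervals (may be empty).
#' @param unmappable `GRanges` of likely-unmappable intervals (may be empty).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(seqlengths, exons,
                           pseudogenes = GRanges(),
                           unmappable = GRanges()) {
  stopifnot(is.numeric(seqlengths), length(seqlengths) > 0,
            !is.null(names(seqlengths)), all(nzchar(names(seqlengths))))
  if (is.null(mcols(exons)$gene_id))
    stop("'exons' must carry a 'gene_id' metadata column")
  check_within <- function(gr, what) {
    if (length(gr) == 0) return(invisible())
    chr <- as.character(seqnames(gr))
    bad <- !(chr %in% names(seqlengths))
    if (any(bad)) stop(sprintf("%s on unknown chromosome: %s", what,
                               paste(unique(chr[bad]), collapse = ", ")))
    if (any(start(gr) < 1) || any(end(gr) > seqlengths[chr]))
      stop(sprintf("%s outside chromosome bounds", what))
  }
  check_within(exons, "exons")
  check_within(pseudogenes, "pseudogenes")
  check_within(unmappable, "unmappable regions")
  # exons of one gene must be pairwise disjoint
  by_gene <- split(ranges(exons), mcols(exons)$gene_id)
  if (any(vapply(by_gene, function(r) !isDisjoint(r), logical(1))))
    stop("exons of a single gene must be pairwise disjoint")
  obj <- list(seqlengths = stats::setNames(as.integer(seqlengths),
                                           names(seqlengths)),
              exons = sort(exons), pseudogenes = sort(pseudogenes),
              unmappable = sort(unmappable))
  class(obj) <- "annotation_set"
  obj
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set: %d chromosome(s), %.0f bp; %d exons / %d genes; %d pseudogenes; %d unmappable intervals\n",
    length(x$seqlengths), sum(as.numeric(x$seqlengths)), length(x$exons),
    length(unique(mcols(x$exons)$gene_id)), length(x$pseudogenes),
    length(x$unmappable)))
  invisible(x)
}

#' Gene bodies and derived introns
#'
#' `gene_bodies()` returns one range per gene spanning its first to last
#' exon. `intron_ranges()` returns the inter-exon gaps, each tagged with the
#' `gene_id` it derives from.
#'
#' @param annotation an [annotation_set()].
#' @return `GRanges`.
#' @export
gene_bodies <- function(annotation) {
  ex <- annotation$exons
  if (length(ex) == 0) return(GRanges())
  rng <- unlist(range(split(ranges(ex), mcols(ex)$gene_id)))
  chr <- vapply(split(as.character(seqnames(ex)), mcols(ex)$gene_id),
                function(v) v[1], character(1))
  gr <- GRanges(chr[names(rng)], rng)
  mcols(gr)$gene_id <- names(rng)
  sort(gr)
}

#' @rdname gene_bodies
#' @export
intron_ranges <- function(annotation) {
  ex <- annotation$exons
  if (length(ex) == 0) return(GRanges())
  gid <- mcols(ex)$gene_id
  ord <- order(gid, start(ex))
  chr <- as.character(seqnames(ex))[ord]
  gid <- gid[ord]
  s <- start(ex)[ord]
  e <- end(ex)[ord]
  n <- length(s)
  # gaps between consecutive exons of the same gene
  same <- gid[-n] == gid[-1]
  istart <- e[-n] + 1L
  iend <- s[-1] - 1L
  keep <- same & istart <= iend
  if (!any(keep)) return(GRanges())
  gr <- GRanges(chr[-n][keep], IRanges(istart[keep], iend[keep]))
  mcols(gr)$gene_id <- gid[-n][keep]
  sort(gr)
}

# Priority partition of the genome into annotation spaces.
# unmappable is removed first; remaining bases are assigned
# exon > intron > pseudogene > intergenic, so the five categories
# (four spaces + unmappable) tile the genome exactly.
annotation_spaces <- function(annotation) {
  sl <- annotation$seqlengths
  genome <- GRanges(names(sl), IRanges(1L, sl))
  unmap <- reduce(annotation$unmappable, ignore.strand = TRUE)
  mappable <- setdiff(genome, unmap, ignore.strand = TRUE)
  exon <- intersect(mappable, reduce(annotation$exons, ignore.strand = TRUE),
                    ignore.strand = TRUE)
  left <- setdiff(mappable, exon, ignore.strand = TRUE)
  intron <- intersect(left, reduce(intron_ranges(annotation),
                                   ignore.strand = TRUE), ignore.strand = TRUE)
  left <- setdiff(left, intron, ignore.strand = TRUE)
  pseudo <- intersect(left, reduce(annotation$pseudogenes,
                                   ignore.strand = TRUE), ignore.strand = TRUE)
  intergenic <- setdiff(left, pseudo, ignore.strand = TRUE)
  list(exon = exon, intron = intron, pseudogene = pseudo,
       intergenic = intergenic, unmappable = unmap)
}

#' Read and write BED intervals
#'
#' Minimal BED6 reader/writer. BED uses 0-based half-open coordinates; these
#' functions convert to and from the 1-based closed `GRanges` convention used
#' throughout the package. Column 4 is kept as `name`, column 5 as `score`.
#'
#' @param path file path.
#' @param gr a `GRanges` to write.
#' @return `read_bed()` returns a `GRanges`; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]),
                strand = if (ncol(df) >= 6) sub("^\\.$", "*", df[[6]])
                         else "*")
  if (ncol(df) >= 4) mcols(gr)$name <- as.character(df[[4]])
  if (ncol(df) >= 5) mcols(gr)$score <- df[[5]]
  gr
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = mcols(gr)$name %||% ".",
                   score = mcols(gr)$score %||% 0,
                   strand = sub("\\*", ".", as.character(strand(gr))))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GFF3 annotation into an annotation set
#'
#' Parses `exon` features grouped by their `Parent` (or `ID`) attribute into
#' genes, and features of `pseudogene_type` into pseudogene intervals.
#' Chromosome lengths are taken from `##sequence-region` pragmas when present,
#' otherwise from the maximum coordinate seen per chromosome.
#'
#' @param path GFF3 file path.
#' @param pseudogene_type feature type treated as pseudogene
#'   (default `"pseudogene"`).
#' @param unmappable optional `GRanges` of likely-unmappable regions, e.g.
#'   from [find_unmappable()].
#' @return An [annotation_set()].
#' @export
read_gff3_annotation <- function(path, pseudogene_type = "pseudogene",
                                 unmappable = GRanges()) {
  lines <- readLines(path)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  sl <- NULL
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    sl <- stats::setNames(as.integer(vapply(parts, `[`, "", 4)),
                          vapply(parts, `[`, "", 2))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(body, "\t", fixed = TRUE)
  f <- f[vapply(f, length, integer(1)) >= 9]
  df <- data.frame(chrom = vapply(f, `[`, "", 1),
                   type = vapply(f, `[`, "", 3),
                   start = as.integer(vapply(f, `[`, "", 4)),
                   end = as.integer(vapply(f, `[`, "", 5)),
                   strand = vapply(f, `[`, "", 7),
                   attr = vapply(f, `[`, "", 9),
                   stringsAsFactors = FALSE)
  attr_val <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0(key, "=[^;]+"), a))) > 0,
           sub(paste0(key, "="), "", m[match(a, a)]), NA_character_)
  }
  if (is.null(sl))
    sl <- vapply(split(df$end, df$chrom), max, integer(1))
  ex <- df[df$type == "exon", , drop = FALSE]
  gene_id <- sub("Parent=", "",
                 regmatches(ex$attr, regexpr("Parent=[^;]+", ex$attr)))
  if (length(gene_id) != nrow(ex))
    stop("every exon feature needs a Parent attribute")
  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end),
                   strand = sub("\\.", "*", ex$strand))
  mcols(exons)$gene_id <- gene_id
  ps <- df[df$type == pseudogene_type, , drop = FALSE]
  pseudo <- GRanges(ps$chrom, IRanges(ps$start, ps$end),
                    strand = sub("\\.", "*", ps$strand))
  annotation_set(sl, exons, pseudo, unmappable)
}

#' Write an annotation set to GFF3
#'
#' @param annotation an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chr in names(annotation$seqlengths))
    writeLines(sprintf("##sequence-region %s 1 %d", chr,
                       annotation$seqlengths[[chr]]), con)
  gb <- gene_bodies(annotation)
  rows <- character(0)
  if (length(gb))
    rows <- c(rows, sprintf("%s\titrfun\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            as.character(seqnames(gb)), start(gb), end(gb),
                            sub("\\*", ".", as.character(strand(gb))),
                            mcols(gb)$gene_id))
  ex <- annotation$exons
  if (length(ex))
    rows <- c(rows, sprintf("%s\titrfun\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                            as.character(seqnames(ex)), start(ex), end(ex),
                            sub("\\*", ".", as.character(strand(ex))),
                            mcols(ex)$gene_id))
  ps <- annotation$pseudogenes
  if (length(ps))
    rows <- c(rows, sprintf(
      "%s\titrfun\tpseudogene\t%d\t%d\t.\t%s\t.\tID=pseudo%05d",
      as.character(seqnames(ps)), start(ps), end(ps),
      sub("\\*", ".", as.character(strand(ps))), seq_along(ps)))
  writeLines(rows, con)
  invisible(path)
}
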