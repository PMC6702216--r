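test_that("fragments merge only when they share at least one base", {
  # overlapping fragments fuse into their union
  fr <- GRanges("chr1", IRanges(c(100, 150), c(199, 249)))
  m <- merge_fragments(fr)
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(100, 249))

  # bookended fragments (no shared base) stay separate
  fr <- GRanges("chr1", IRanges(c(100, 200), c(199, 299)))
  expect_equal(length(merge_fragments(fr)), 2L)

  # disjoint fragments pass through unchanged
  fr <- GRanges("chr1", IRanges(c(100, 500), c(150, 600)))
  m <- merge_fragments(fr)
  expect_equal(start(m), c(100, 500))

  expect_equal(length(merge_fragments(GRanges())), 0L)
})

test_that("merging keeps dataset provenance and fragment counts", {
  frags <- list(ds1 = GRanges("chr1", IRanges(100, 200)),
                ds2 = GRanges("chr1", IRanges(c(150, 900), c(250, 950))))
  m <- merge_fragments(frags)
  expect_equal(length(m), 2L)
  expect_equal(as.list(mcols(m)$datasets)[[1]], c("ds1", "ds2"))
  expect_equal(mcols(m)$n_fragments, c(2L, 1L))
})

test_that("merged output equals connected components of the overlap graph", {
  set.seed(401)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    s <- sample.int(2000, n, replace = TRUE)
    gr <- GRanges(sample(c("chr1", "chr2"), n, replace = TRUE),
                  IRanges(s, s + sample.int(150, n, replace = TRUE)))
    m <- merge_fragments(gr)
    o <- oracle_merge(gr)
    expect_equal(as.character(seqnames(m)), as.character(seqnames(o)))
    expect_equal(start(m), start(o))
    expect_equal(end(m), end(o))
  }
})

test_that("classification follows the exon > intron > pseudogene priority", {
  ann <- toy_annotation()
  # spans the g1 exon/intron boundary -> exon wins
  expect_equal(classify_regions(GRanges("chr1", IRanges(1150, 1350)), ann),
               "exon")
  # intron only
  expect_equal(classify_regions(GRanges("chr1", IRanges(1250, 1400)), ann),
               "intron")
  # pseudogene only
  expect_equal(classify_regions(GRanges("chr1", IRanges(5100, 5200)), ann),
               "pseudogene")
  # nothing annotated
  expect_equal(classify_regions(GRanges("chr1", IRanges(7000, 7100)), ann),
               "intergenic")
  expect_error(classify_regions(GRanges("chrX", IRanges(1, 10)), ann),
               "unknown chromosome")
})

test_that("classification agrees with a base-level oracle on random cases", {
  ann <- toy_annotation()
  set.seed(402)
  s <- sample.int(9900, 1000, replace = TRUE)
  regions <- GRanges("chr1", IRanges(s, s + sample.int(100, 1000,
                                                       replace = TRUE)))
  got <- classify_regions(regions, ann)
  want <- vapply(seq_along(regions), function(i)
    oracle_classify(regions[i], ann), character(1))
  expect_equal(got, want)
})

test_that("unmappable detection applies the 40-nt minimum run length", {
  seq39 <- paste0(strrep("A", 10), strrep("N", 39), strrep("C", 10))
  expect_equal(length(find_unmappable(c(chr1 = seq39))), 0L)

  seq40 <- paste0(strrep("A", 10), strrep("N", 40), strrep("C", 10))
  um <- find_unmappable(c(chr1 = seq40))
  expect_equal(c(start(um), end(um)), c(11, 50))

  expect_equal(length(find_unmappable(c(chr1 = "ACGTACGT"))), 0L)
  expect_error(find_unmappable(c(chr1 = "ACGTXN")), "non-nucleotide")
})

test_that("random intergenic sampling avoids all forbidden space", {
  ann <- toy_annotation()
  tr <- GRanges("chr1", IRanges(6001, 6500))
  got <- sample_random_intergenic(ann, rep(100, 20), transcribed = tr,
                                  seed = 7)
  expect_equal(length(got), 20L)
  expect_true(all(width(got) == 100))
  forbidden <- c(gene_bodies(ann), ann$pseudogenes, ann$unmappable, tr)
  expect_false(any(overlapsAny(got, forbidden, ignore.strand = TRUE)))
  expect_true(isDisjoint(got))
  # reproducible under the seed
  again <- sample_random_intergenic(ann, rep(100, 20), transcribed = tr,
                                    seed = 7)
  expect_identical(start(got), start(again))
  expect_equal(length(sample_random_intergenic(ann, integer(0))), 0L)
})

test_that("intervals containing ambiguous bases are dropped post hoc", {
  ann <- annotation_set(c(chr1 = 1000L),
                        GRanges("chr1", IRanges(1, 10),
                                gene_id = "g1"))
  genome <- c(chr1 = paste0(strrep("A", 500), strrep("N", 45),
                            strrep("C", 455)))
  ann$unmappable <- find_unmappable(genome)
  got <- sample_random_intergenic(ann, rep(50, 10), genome = genome,
                                  seed = 3)
  seqs <- vapply(seq_along(got), function(i)
    substr(genome[["chr1"]], start(got)[i], end(got)[i]), character(1))
  expect_false(any(grepl("N", seqs)))
})

test_that("sampling fails cleanly when no intergenic space fits", {
  exons <- GRanges("chr1", IRanges(1, 1000), gene_id = "g1")
  ann <- annotation_set(c(chr1 = 1000L), exons)
  expect_error(sample_random_intergenic(ann, 50), "no intergenic")
})

test_that("nearest-gene distance counts bases strictly between ends", {
  genes <- GRanges("chr1", IRanges(c(801, 2001), c(900, 2100)))
  expect_equal(nearest_gene_distance(GRanges("chr1", IRanges(850, 950)),
                                     genes), 0L)
  expect_equal(nearest_gene_distance(GRanges("chr1", IRanges(1001, 1100)),
                                     genes), 100L)
  # adjacent -> 0 bases between
  expect_equal(nearest_gene_distance(GRanges("chr1", IRanges(901, 950)),
                                     genes), 0L)
  expect_error(nearest_gene_distance(GRanges("chr2", IRanges(1, 10)),
                                     genes), "no gene")
})

test_that("space coverage excludes unmappable bases and partitions the genome", {
  ann <- toy_annotation()
  none <- GRanges()
  mcols(none)$region_class <- character(0)
  cov0 <- space_coverage(none, ann)
  expect_true(all(cov0$percent == 0))

  # the four spaces plus unmappable tile the chromosome
  expect_equal(sum(cov0$mappable_bp) + sum(width(ann$unmappable)), 10000)

  # a transcribed ITR covering a fifth of intergenic space
  spaces <- itrfun:::annotation_spaces(ann)
  inter_bp <- sum(width(spaces$intergenic))
  tr <- GRanges("chr1", IRanges(6001, 6000 + round(inter_bp / 5)))
  mcols(tr)$region_class <- "intergenic"
  cov <- space_coverage(tr, ann)
  got <- cov$percent[cov$space == "intergenic"]
  expect_equal(got, 100 * round(inter_bp / 5) / inter_bp, tolerance = 1e-6)

  # zero-size space reports undefined, not 0
  ann2 <- annotation_set(c(chr1 = 1000L),
                         GRanges("chr1", IRanges(1, 1000), gene_id = "g1"))
  tr2 <- GRanges("chr1", IRanges(1, 10))
  mcols(tr2)$region_class <- "exon"
  cov2 <- space_coverage(tr2, ann2)
  expect_true(is.nan(cov2$percent[cov2$space == "intergenic"]))
})

test_that("gene bridging fraction counts chains spanning ITR and neighbor gene", {
  genes <- GRanges("chr1", IRanges(1001, 2000))
  itrs <- GRanges("chr1", IRanges(c(2101, 2301, 2501, 9000),
                                  c(2200, 2400, 2600, 9100)))
  # chain touching the gene and the first two ITRs
  chain <- GRanges("chr1", IRanges(c(1900, 2150, 2350),
                                   c(1950, 2180, 2380)))
  # 3 ITRs are within 500 bp of the gene; 2 of them are bridged
  expect_equal(gene_bridging_fraction(list(chain), itrs, genes), 2 / 3)
  expect_equal(gene_bridging_fraction(list(), itrs, genes), 0)
  one <- GRanges("chr1", IRanges(2101, 2200))
  expect_equal(gene_bridging_fraction(
    list(GRanges("chr1", IRanges(c(1500, 2120), c(1600, 2150)))),
    one, genes), 1.0)
})
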