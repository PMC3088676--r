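# A single + strand gene spanning 1-based 1001..3000 with exons
# 1001..1500 and 2501..3000 (so one intron 1501..2500), mirrored from the
# worked classification examples.
single_gene <- function() {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000), strand = "+")
  g$gene_id <- "g1"
  ex <- methods::as(list(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 2501), c(1500, 3000)), strand = "+")),
    "GRangesList")
  gene_models(g, ex)
}

test_that("regions classify into strand-aware feature categories", {
  gm <- single_gene()
  region <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  expect_equal(classify_region(region(401, 600), gm), "five_prime")
  expect_equal(classify_region(region(1601, 1700), gm), "intron")
  expect_equal(classify_region(region(5001, 5100), gm), "intergenic")
  expect_equal(classify_region(region(3100, 3200), gm), "three_prime")
  # straddling the exon/intron boundary increments both
  expect_setequal(classify_region(region(1450, 1550), gm), c("exon", "intron"))
  # intergenic is exclusive of everything else
  m <- classify_regions(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(401, 1601, 5001, 900), c(600, 1700, 5100, 1100))), gm)
  expect_true(all(rowSums(m[, 1:4]) == 0 | !m[, "intergenic"]))
  expect_true(all(rowSums(m) >= 1))
})

test_that("minus-strand genes flip the 5'/3' categories", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 7000), strand = "-")
  g$gene_id <- "gm"
  ex <- methods::as(list(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(5001, 7000), strand = "-")), "GRangesList")
  gm <- gene_models(g, ex)
  region <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  # upstream of a minus gene lies to the right of its span
  expect_equal(classify_region(region(7100, 7200), gm), "five_prime")
  expect_equal(classify_region(region(4800, 4900), gm), "three_prime")
})

test_that("methylated-percent arithmetic reproduces the published table rows", {
  # (methylated, total) pairs from the four tissue libraries
  expect_identical(methylated_percent(1850, 20224), 9.1)
  expect_identical(methylated_percent(1472, 20224), 7.3)
  expect_identical(methylated_percent(1156, 20224), 5.7)
  expect_identical(methylated_percent(2657, 20224), 13.1)
  expect_error(methylated_percent(1, 0), "positive")
})

test_that("CGI methylation summaries count non-exclusively", {
  gm <- single_gene()
  islands <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(401, 1401, 5001), c(700, 1600, 5300)))
  peaks <- make_peaks(c(401, 1401), c(700, 1600))
  s <- summarize_cgi_methylation(islands, peaks, gm)
  expect_equal(s$total_cgis, 3L)
  expect_equal(s$total_methylated, 2L)
  # island 2 spans the exon/intron boundary: counted in both categories,
  # so the category sum exceeds the methylated total
  expect_equal(s$five_prime, 1L)
  expect_equal(s$exon, 1L)
  expect_equal(s$intron, 1L)
  cat_sum <- s$five_prime + s$three_prime + s$exon + s$intron + s$intergenic
  expect_gte(cat_sum, s$total_methylated)
  expect_identical(s$methylated_percent, methylated_percent(2, 3))

  none <- summarize_cgi_methylation(islands, GenomicRanges::GRanges(), gm)
  expect_identical(none$methylated_percent, 0)
  expect_error(summarize_cgi_methylation(GenomicRanges::GRanges(),
                                         peaks, gm), "no CpG islands")
})

test_that("HMR distribution summary counts peaks per category", {
  gm <- single_gene()
  peaks <- make_peaks(c(5001, 6001, 7001), c(5300, 6300, 7300))
  s <- summarize_hmr_distribution(peaks, gm)
  expect_equal(s$total_regions, 3L)
  expect_equal(s$intergenic, 3L)
  expect_equal(s$exon + s$intron + s$five_prime + s$three_prime, 0L)

  straddle <- make_peaks(1450, 1550)
  s2 <- summarize_hmr_distribution(straddle, gm)
  expect_equal(s2$exon, 1L)
  expect_equal(s2$intron, 1L)
})

test_that("repeat tag fractions assign ties by longest overlap", {
  repeats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1001, 3001, 5001), c(2000, 4000, 6000)))
  repeats$family <- c("CR1", "CR1", "LINE-L2")
  no_rep <- repeat_tag_fraction(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1, 35), strand = "+"), GenomicRanges::GRanges())
  expect_equal(no_rep$overall, 0)

  tag_at <- function(pos) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos, width = 35L), strand = "+")
  # 10 tags, 3 land in repeats (2 in CR1 elements, 1 in the LINE)
  tags <- do.call(c, lapply(c(1200, 3200, 5200, rep(50000, 7)), tag_at))
  rf <- repeat_tag_fraction(tags, repeats)
  expect_equal(rf$overall, 0.3)
  expect_equal(rf$per_family[["CR1"]], 2 / 3)
  expect_equal(rf$per_family[["LINE-L2"]], 1 / 3)

  # all tags inside one element
  rf1 <- repeat_tag_fraction(do.call(c, lapply(rep(1200, 5), tag_at)), repeats)
  expect_equal(rf1$overall, 1.0)
  expect_equal(rf1$per_family[["CR1"]], 1.0)

  # a tag overlapping two repeats goes to the longer overlap
  touching <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1001, 2101), c(2100, 3000)))
  touching$family <- c("A", "B")
  tie_tag <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2035),
                                    strand = "+")
  rf2 <- repeat_tag_fraction(tie_tag, touching, extension_length = 275L)
  # extended fragment 2001..2275: 100 bp in A, 175 bp in B
  expect_equal(names(rf2$per_family)[rf2$per_family == 1], "B")
})
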