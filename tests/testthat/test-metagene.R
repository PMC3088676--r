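track_from_ranges <- function(ranges, depth, lens = c(chr1 = 10000L),
                              library_size = 1000L) {
  cov <- GenomicRanges::coverage(
    GenomicRanges::GRanges("chr1", ranges), weight = depth, width = lens)
  structure(list(depth = cov, library_size = library_size,
                 extension_length = 275L), class = "coverage_track")
}

test_that("flat coverage gives a flat profile", {
  tr <- track_from_ranges(IRanges::IRanges(1, 10000), 1)
  prof <- compute_metagene(tr, toy_gene_models(), normalize = FALSE)
  expect_length(prof$values, 60L)
  expect_true(all(abs(prof$values - 1) < 1e-12))
  expect_equal(prof$n_genes_used, 2L)
})

test_that("body windows pick up gene-body depth, flanks stay at zero", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 5000), strand = "+")
  g$gene_id <- "g1"
  gm <- gene_models(g, methods::as(list(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(3001, 5000), strand = "+")), "GRangesList"))
  tr <- track_from_ranges(IRanges::IRanges(3001, 5000), 2)
  prof <- compute_metagene(tr, gm, normalize = FALSE)
  expect_equal(unname(prof$values[21:40]), rep(2, 20))
  expect_equal(unname(prof$values[c(1:20, 41:60)]), rep(0, 40))
  # normalization is tags per ten million
  profn <- compute_metagene(tr, gm, normalize = TRUE)
  expect_equal(unname(profn$values[21]), 2 * 1e7 / tr$library_size)
})

test_that("body windows tile the gene exactly", {
  for (L in c(2000L, 2017L, 9999L)) {
    bounds <- 1L + floor((0:20) * L / 20)
    widths <- diff(bounds)
    expect_equal(sum(widths), L)
    expect_true(all(widths >= 1L))
  }
})

test_that("the profile is strand-equivariant", {
  # depth pattern asymmetric around the gene; a minus-strand gene with the
  # mirrored pattern must give the identical profile
  lens <- c(chr1 = 10000L)
  gp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 6000), strand = "+")
  gp$gene_id <- "g"
  gmp <- gene_models(gp, methods::as(list(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(4001, 6000), strand = "+")), "GRangesList"))
  gneg <- gp
  BiocGenerics::strand(gneg) <- "-"
  gmm <- gene_models(gneg, methods::as(
    list(GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 6000),
                                strand = "-")), "GRangesList"))
  # plus-oriented pattern: high over [4001,4500], low elsewhere
  trp <- track_from_ranges(IRanges::IRanges(4001, 4500), 3)
  # mirrored pattern around the gene midpoint 5000.5: high over [5501,6000]
  trm <- track_from_ranges(IRanges::IRanges(5501, 6000), 3)
  pp <- compute_metagene(trp, gmp, normalize = FALSE)
  pm <- compute_metagene(trm, gmm, normalize = FALSE)
  expect_equal(pp$values, pm$values)
})

test_that("profile scales linearly with coverage", {
  tr1 <- track_from_ranges(IRanges::IRanges(c(2001, 5001), c(4000, 9000)),
                           c(1, 2))
  tr2 <- track_from_ranges(IRanges::IRanges(c(2001, 5001), c(4000, 9000)),
                           c(2, 4))
  p1 <- compute_metagene(tr1, toy_gene_models(), normalize = FALSE)
  p2 <- compute_metagene(tr2, toy_gene_models(), normalize = FALSE)
  expect_equal(p2$values, 2 * p1$values)
})

test_that("short genes are excluded and empty gene sets error", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 3100), strand = "+")
  g$gene_id <- "tiny"
  gm <- gene_models(g, methods::as(list(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(3001, 3100), strand = "+")), "GRangesList"))
  tr <- track_from_ranges(IRanges::IRanges(1, 10000), 1)
  expect_error(compute_metagene(tr, gm), "zero usable genes")
})
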