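test_that("genome generation is deterministic and respects packing rules", {
  params <- sim_params(chrom_len = 2e5, n_genes = 8L, n_repeats = 6L, seed = 7L)
  a <- generate_genome(params)
  b <- generate_genome(params)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(as.data.frame(a$landscape), as.data.frame(b$landscape))
  expect_identical(as.data.frame(a$truth$genes$genes),
                   as.data.frame(b$truth$genes$genes))

  g <- GenomicRanges::sort(a$truth$genes$genes, ignore.strand = TRUE)
  gaps <- BiocGenerics::start(g)[-1] - BiocGenerics::end(g)[-length(g)] - 1L
  expect_true(all(gaps >= params$gene_gap_min))

  # landscape positions are CpG cytosines of the final sequence
  chars <- strsplit(as.character(a$sequences[["chr1"]]), "")[[1]]
  pos <- BiocGenerics::start(a$landscape)
  expect_true(all(chars[pos] == "C"))
  expect_true(all(chars[pos + 1L] == "G"))
  expect_true(all(a$landscape$m >= 0 & a$landscape$m <= 1))

  # methylated domains are exactly the regions at or above m_high
  dom <- a$truth$methylated_domains
  inside <- IRanges::overlapsAny(a$landscape, dom)
  expect_true(all(a$landscape$m[inside] >= params$m_high))
  expect_true(all(a$landscape$m[!inside] < params$m_high))

  expect_error(generate_genome(sim_params(chrom_len = 1e4, n_genes = 10L)),
               "chrom_len")
})

test_that("a gene-free genome carries the intergenic level everywhere", {
  params <- sim_params(chrom_len = 5e4, n_genes = 0L, n_repeats = 0L, seed = 3L)
  gen <- generate_genome(params)
  expect_true(all(gen$landscape$m == params$m_intergenic))
  expect_length(gen$truth$methylated_domains, 0L)
})

test_that("planted CpG islands are recovered by the scanner", {
  gen <- fixture_1mb()$gen
  islands <- scan_cpg_islands(gen$sequences)
  expect_true(all(IRanges::overlapsAny(gen$truth$planted_cgis, islands)))
})

test_that("MeDIP sampling weights follow methylated-CpG content", {
  # two 10 kb domains with identical CpG layout, m = 1 vs 0
  chars <- rep(c("A", "T"), 1e4)
  pos <- seq(51, 19951, by = 100)
  chars[pos] <- "C"; chars[pos + 1L] <- "G"
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste0(chars, collapse = "")))
  GenomeInfoDb::seqlengths(seqs) <- c(chr1 = 2e4)
  m10 <- ifelse(pos <= 1e4, 1, 0)
  land <- make_landscape(pos, m10, len = 2e4)
  params <- sim_params(seed = 5L)
  tags <- simulate_medip(seqs, land, params, n_reads = 2000L)
  frac_first <- mean(BiocGenerics::start(tags) <= 1e4)
  expect_gt(frac_first, 0.97)  # only boundary-straddling fragments can leak

  # m = 0.8 vs 0.2 at equal density: read share 0.8 within 3 binomial SE
  land2 <- make_landscape(pos, ifelse(pos <= 1e4, 0.8, 0.2), len = 2e4)
  tags2 <- simulate_medip(seqs, land2, sim_params(epsilon = 0, seed = 11L),
                          n_reads = 4000L)
  mid <- BiocGenerics::start(tags2) + 17L
  share <- mean(mid <= 1e4)
  se <- sqrt(0.8 * 0.2 / 4000)
  expect_lt(abs(share - 0.8), 3 * se + 0.02)  # small slack for edge fragments

  # all-zero landscape with epsilon = 0 has nothing to sample
  land0 <- make_landscape(pos, rep(0, length(pos)), len = 2e4)
  expect_error(simulate_medip(seqs, land0, sim_params(epsilon = 0)),
               "no sampleable fragments")

  # determinism under a fixed seed
  t1 <- simulate_medip(seqs, land, params, n_reads = 500L)
  t2 <- simulate_medip(seqs, land, params, n_reads = 500L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("MeDIP coverage calibrates to the planted level ratio", {
  fx <- fixture_1mb()
  params <- fx$params
  track <- build_coverage(fx$tags, fx$gen$truth$chrom_lengths)
  reg <- fx$gen$truth$regions
  mean_depth <- function(r) {
    v <- IRanges::Views(track$depth$chr1,
                        IRanges::ranges(r[BiocGenerics::width(r) >= 500]))
    sum(IRanges::viewSums(v)) / sum(IRanges::width(v))
  }
  body <- mean_depth(reg[reg$m == params$m_body])
  flank <- mean_depth(reg[reg$m == params$m_flank])
  expected <- (params$m_body + params$epsilon) / (params$m_flank + params$epsilon)
  # fragment-edge smearing dilutes the contrast; require the right order of
  # magnitude and the right direction
  expect_gt(body / flank, 0.5 * expected)
  expect_gt(body / flank, 2)
})

test_that("RNA tag simulation couples expression to promoter methylation", {
  fx <- fixture_1mb()
  params <- fx$params
  counts <- simulate_rnaseq(fx$gen$truth$genes, fx$gen$landscape, params)
  expect_identical(sum(counts), as.integer(params$n_rna_tags))
  expect_named(counts, fx$gen$truth$genes$genes$gene_id)

  # beta = 0: symmetric two-gene case splits tags evenly
  gm <- toy_gene_models()
  land <- make_landscape(c(3100L, 6500L), c(1, 0), len = 1e4)
  p0 <- sim_params(beta = 0, n_rna_tags = 1e5, expr_sdlog = 0, seed = 2L)
  c0 <- simulate_rnaseq(gm, land, p0)
  se <- sqrt(0.25 * 1e5)
  expect_lt(abs(c0[["gA"]] - 5e4), 3 * se)

  # large beta: a fully methylated promoter is silenced relative to a
  # naked one (rate ratio exp(-5) ~ 0.0067)
  p5 <- sim_params(beta = 5, n_rna_tags = 1e5, expr_sdlog = 0, seed = 2L)
  c5 <- simulate_rnaseq(gm, land, p5)
  expect_lt(c5[["gA"]] / sum(c5), 0.015)

  empty_genes <- GenomicRanges::GRanges()
  empty_genes$gene_id <- character(0)
  empty <- gene_models(empty_genes, methods::as(list(), "GRangesList"))
  expect_error(simulate_rnaseq(empty, land, p0), "no genes")
})

test_that("bisulfite clone simulation follows the per-C conversion model", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "AACGTCCACGTT"))
  GenomeInfoDb::seqlengths(seqs) <- c(chr1 = 12L)
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 12))
  # CpGs at positions 3 and 9; non-CpG Cs at 6 and 7
  land1 <- make_landscape(c(3L, 9L), c(1, 1), len = 12L)
  p <- sim_params(n_clones = 20L, conversion_rate = 1, seed = 4L)
  clones <- simulate_bisulfite(seqs, land1, region, p)
  expect_length(clones, 20L)
  mat <- do.call(rbind, strsplit(as.character(clones), ""))
  expect_true(all(mat[, 3] == "C") && all(mat[, 9] == "C"))
  expect_true(all(mat[, 6] == "T") && all(mat[, 7] == "T"))

  land0 <- make_landscape(c(3L, 9L), c(0, 0), len = 12L)
  clones0 <- simulate_bisulfite(seqs, land0, region, p)
  mat0 <- do.call(rbind, strsplit(as.character(clones0), ""))
  expect_true(all(mat0[, c(3, 6, 7, 9)] == "T"))

  # Bernoulli mean: a 0.7 site is retained in ~70% of many clones
  land7 <- make_landscape(c(3L, 9L), c(0.7, 0.7), len = 12L)
  many <- simulate_bisulfite(seqs, land7, region,
                             sim_params(n_clones = 400L, seed = 9L))
  matm <- do.call(rbind, strsplit(as.character(many), ""))
  frac <- mean(matm[, c(3, 9)] == "C")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 800))

  expect_identical(as.character(simulate_bisulfite(seqs, land7, region, p)),
                   as.character(simulate_bisulfite(seqs, land7, region, p)))
})

test_that("independent MeDIP samplings of one landscape are highly correlated", {
  fx <- fixture_1mb()
  tags_b <- simulate_medip(fx$gen$sequences, fx$gen$landscape, fx$params,
                           seed = 20260926L)
  track_a <- build_coverage(fx$tags, fx$gen$truth$chrom_lengths)
  track_b <- build_coverage(tags_b, fx$gen$truth$chrom_lengths)
  bins <- IRanges::IRanges(seq(1L, 1e6, by = 1000L), width = 1000L)
  a <- IRanges::viewSums(IRanges::Views(track_a$depth$chr1, bins))
  b <- IRanges::viewSums(IRanges::Views(track_b$depth$chr1, bins))
  expect_gt(stats::cor(a, b), 0.95)
})
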