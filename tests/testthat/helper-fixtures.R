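# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Benchmark fixture: 1 Mb, 40 genes, 200k MeDIP reads, master seed 1.
fixture_1mb <- function() memo("f1mb", function() {
  params <- sim_params(seed = 1L)
  gen <- generate_genome(params)
  tags <- simulate_medip(gen$sequences, gen$landscape, params)
  peaks <- call_peaks(tags, gen$truth$chrom_lengths)
  list(params = params, gen = gen, tags = tags, peaks = peaks)
})

# Expression-integration fixture: 2 Mb, 120 genes (12 genes per expression
# decile), same generator, master seed 1.
fixture_2mb <- function() memo("f2mb", function() {
  params <- sim_params(chrom_len = 2e6, n_genes = 120L, seed = 1L)
  gen <- generate_genome(params)
  tags <- simulate_medip(gen$sequences, gen$landscape, params)
  peaks <- call_peaks(tags, gen$truth$chrom_lengths)
  list(params = params, gen = gen, tags = tags, peaks = peaks)
})

# A hand-built two-gene model on one 10 kb chromosome, for annotation and
# metagene unit tests (1-based closed coordinates).
toy_gene_models <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(3001, 6001), c(5000, 8000)),
    strand = c("+", "-"), seqlengths = c(chr1 = 10000L))
  genes$gene_id <- c("gA", "gB")
  exons <- methods::as(list(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3001, 4501), c(3500, 5000)),
                           strand = "+", seqlengths = c(chr1 = 10000L)),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(6001, 7501), c(7000, 8000)),
                           strand = "-", seqlengths = c(chr1 = 10000L))),
    "GRangesList")
  gene_models(genes, exons)
}

# Peaks GRanges from plain vectors (1-based closed).
make_peaks <- function(starts, ends, p = 1e-6) {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
  gr$tag_count <- rep(100L, length(gr))
  gr$p_value <- rep_len(p, length(gr))
  gr
}

# Landscape GRanges from position/level vectors.
make_landscape <- function(pos, m, chrom = "chr1", len = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  if (!is.null(len)) {
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(len, chrom)
  }
  gr$m <- m
  gr
}

# Independent brute-force CpG-island oracle: test every window of
# `window_len` by direct substring counting, union the qualifiers, apply
# the final length criterion. Deliberately naive.
brute_force_cgi <- function(seq_chars, window_len = 200L,
                            gc_min = 0.5, oe_min = 0.6) {
  L <- length(seq_chars)
  hits <- logical(max(L - window_len + 1L, 0L))
  for (s in seq_len(max(L - window_len + 1L, 0L))) {
    w <- seq_chars[s:(s + window_len - 1L)]
    if (any(!w %in% c("A", "C", "G", "T"))) next
    n_c <- sum(w == "C"); n_g <- sum(w == "G")
    gc <- (n_c + n_g) / window_len
    if (gc <= gc_min) next
    if (n_c == 0 || n_g == 0) next
    n_cpg <- sum(w[-window_len] == "C" & w[-1L] == "G")
    if ((n_cpg * window_len) / (n_c * n_g) > oe_min) hits[s] <- TRUE
  }
  ir <- IRanges::reduce(IRanges::IRanges(which(hits), width = window_len))
  ir[IRanges::width(ir) > window_len]
}

# Direct-summation oracle for the upper Poisson tail: sum the pmf from k
# upward until terms vanish.
poisson_tail_oracle <- function(k, lambda) {
  total <- 0
  term <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  i <- k
  while (term > total * 1e-17 || i < k + 10) {
    total <- total + term
    i <- i + 1
    term <- term * lambda / i
  }
  total
}

# Exhaustive hypergeometric upper-tail oracle via binomial coefficients.
fisher_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
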