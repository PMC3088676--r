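test_that("per-CpG calls count retained versus converted cytosines", {
  ref <- "AACGTACGTT"      # CpGs at positions 3 and 7
  clones <- c(rep("AATGTATGTT", 3), rep("AACGTACGTT", 7))
  calls <- call_methylation(ref, clones)
  expect_equal(calls$position, c(3L, 7L))
  expect_equal(calls$fraction, c(0.7, 0.7))
  expect_equal(calls$n_c, c(7L, 7L))
  expect_equal(calls$n_t, c(3L, 3L))

  all_c <- call_methylation(ref, rep("AACGTACGTT", 5))
  expect_equal(all_c$fraction, c(1.0, 1.0))

  # a non-C/T base at a CpG position is ignored but logged
  odd <- call_methylation(ref, c("AAGGTACGTT", "AACGTACGTT"))
  expect_equal(odd$n_other[1], 1L)
  expect_equal(odd$fraction[1], 1.0)

  expect_equal(nrow(call_methylation("ATTA", c("ATTA", "ATTA"))), 0L)
  expect_error(call_methylation(ref, "AAC"), "length")
})

test_that("conversion efficiency is estimated from non-CpG cytosines", {
  ref <- "ACCGAC"          # CpG at 3; non-CpG Cs at 2 and 6
  clones <- c("ATCGAT", "ACCGAT", "ATTGAT")
  calls <- call_methylation(ref, clones)
  # 6 non-CpG C slots, 5 converted to T
  expect_equal(attr(calls, "conversion_efficiency"), 5 / 6)
})

test_that("lollipop matrix marks methylated and converted CpGs", {
  ref <- "AACGTACGTT"
  lol <- methylation_lollipop(ref, c(a = "AACGTATGTT", b = "AATGTACGTT"))
  expect_equal(dim(lol), c(2L, 2L))
  expect_equal(unname(lol["a", ]), c("*", "o"))
  expect_equal(unname(lol["b", ]), c("o", "*"))
})

test_that("clone estimates converge to the planted level", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = strrep("AACGTTTAAT", 20)))
  GenomeInfoDb::seqlengths(seqs) <- c(chr1 = 200L)
  pos <- seq(3L, 193L, by = 10L)
  land <- make_landscape(pos, rep(0.7, length(pos)), len = 200L)
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
  clones <- simulate_bisulfite(seqs, land, region,
                               sim_params(n_clones = 200L, seed = 8L))
  calls <- call_methylation(Biostrings::subseq(seqs[[1]], 1, 200), clones)
  expect_equal(mean(calls$fraction), 0.7, tolerance = 0.05)
  se <- sqrt(0.7 * 0.3 / 200)
  expect_true(mean(abs(calls$fraction - 0.7) <= 3 * se) >= 0.95)
})

test_that("concordance separates peak from non-peak regions", {
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1001, 5001), c(1400, 5400)))
  regions$region_id <- c("r1", "r2")
  peaks <- make_peaks(900, 1500)
  calls_hi <- data.frame(position = 1:3, n_c = c(9, 8, 10), n_t = c(1, 2, 0),
                         n_other = 0, fraction = c(0.9, 0.8, 1.0))
  calls_lo <- data.frame(position = 1:3, n_c = c(1, 0, 1), n_t = c(9, 10, 9),
                         n_other = 0, fraction = c(0.1, 0.0, 0.1))
  rep <- concordance(peaks, list(r1 = calls_hi, r2 = calls_lo), regions,
                     n_clones = 10L)
  expect_equal(rep$region_kind, c("peak", "non_peak"))
  expect_equal(rep$mean_fraction, c(0.9, 2 / 30))
  expect_gt(attr(rep, "separation"), 0)

  # identical calls in both kinds: the separation check fails loudly
  expect_warning(concordance(peaks, list(r1 = calls_lo, r2 = calls_lo),
                             regions, n_clones = 10L),
                 "concordance check failed")
  # a kind with zero regions is an error
  both_peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1001, 1101), c(1400, 1500)))
  both_peak$region_id <- c("r1", "r2")
  expect_error(concordance(peaks, list(r1 = calls_hi, r2 = calls_hi),
                           both_peak), "each kind")
})
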