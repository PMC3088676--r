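#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, the window null used by the peak
#' caller. Vectorized over `k` and `lambda`.
#'
#' @param k Non-negative integer count(s).
#' @param lambda Positive Poisson mean(s).
#' @return Tail probability in (0, 1].
#' @export
poisson_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(k < 0) || any(k != round(k))) stop("k must be a non-negative integer")
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Peak-caller parameters
#'
#' @param window_len Scanning window length in bp.
#' @param step Window step in bp (must be <= `window_len`).
#' @param merge_gap Significant windows closer than this many bp are merged
#'   into one peak.
#' @param extension_length Fragment extension applied to each tag before
#'   counting (bp).
#' @param effective_genome_len Genome length used for the background rate;
#'   `NULL` means the sum of the supplied chromosome lengths.
#' @param min_tags Strict lower tag-count threshold: a window is eligible
#'   only with more than this many tags.
#' @param p_cutoff Strict Poisson-tail p-value threshold.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(window_len = 300L, step = 100L, merge_gap = 100L,
                          extension_length = 275L, effective_genome_len = NULL,
                          min_tags = 10L, p_cutoff = 1e-5) {
  if (step > window_len) stop("step must be <= window_len")
  if (any(c(window_len, step, merge_gap, extension_length) <= 0))
    stop("caller parameters must be positive")
  structure(as.list(environment()), class = "caller_params")
}

#' Call highly methylated regions (HMRs) from MeDIP tags
#'
#' Simplified Poisson window model. Each chromosome is tiled with windows
#' (`window_len`, `step`); a window's tag count is the number of tags whose
#' extended fragment overlaps it. The background rate is the expected
#' overlap count of a uniform library,
#' `lambda = library_size * (window_len + extension_length) /
#' effective_genome_len` (a tag overlaps a window whenever its 5' end falls
#' within `window_len + extension_length` bases of it, so the rate must
#' count that whole catchment). A window is significant iff its count
#' strictly exceeds `min_tags` (10) and its Poisson tail probability is
#' strictly below `p_cutoff` (1e-5). Significant windows within
#' `merge_gap` bp are merged; each peak reports the tag count over its full
#' span and the minimum constituent-window p-value, uncorrected (the
#' thresholds are fixed raw cut-offs, not an FDR).
#'
#' Windows truncated at chromosome ends keep the nominal lambda, which is
#' slightly conservative there.
#'
#' @param tags `GRanges` of aligned tags (non-empty).
#' @param chrom_lengths Named chromosome lengths.
#' @param params A [caller_params] object.
#' @return Sorted, disjoint `GRanges` of peaks with metadata columns
#'   `tag_count` and `p_value`.
#' @export
call_peaks <- function(tags, chrom_lengths, params = caller_params()) {
  stopifnot(inherits(params, "caller_params"))
  if (length(tags) == 0L) stop("no tags supplied")
  egl <- if (is.null(params$effective_genome_len))
    sum(as.numeric(chrom_lengths)) else params$effective_genome_len
  if (egl < max(chrom_lengths))
    stop("effective_genome_len is smaller than the largest chromosome")
  ext <- extend_tags(tags, params$extension_length, chrom_lengths)
  lambda <- length(tags) * (params$window_len + params$extension_length) / egl

  windows <- do.call(c, lapply(names(chrom_lengths), function(chrom) {
    starts <- seq.int(1L, chrom_lengths[[chrom]], by = params$step)
    ends <- pmin(starts + params$window_len - 1L, chrom_lengths[[chrom]])
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                           seqlengths = chrom_lengths)
  }))
  counts <- GenomicRanges::countOverlaps(windows, ext, ignore.strand = TRUE)
  eligible <- counts > params$min_tags
  pvals <- rep(1, length(windows))
  # floor at the smallest normal double: extreme windows underflow the
  # Poisson tail to 0, and downstream -log10(p) scores must stay finite
  pvals[eligible] <- pmax(poisson_tail(counts[eligible], lambda),
                          .Machine$double.xmin)
  sig <- eligible & pvals < params$p_cutoff
  if (!any(sig)) {
    out <- GenomicRanges::GRanges(seqlengths = chrom_lengths)
    out$tag_count <- integer(0); out$p_value <- numeric(0)
    return(out)
  }
  peaks <- GenomicRanges::reduce(windows[sig], min.gapwidth = params$merge_gap + 1L)
  peaks$tag_count <- GenomicRanges::countOverlaps(peaks, ext, ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(windows[sig], peaks)
  peaks$p_value <- as.numeric(tapply(pvals[sig][S4Vectors::queryHits(hit)],
                                     S4Vectors::subjectHits(hit), min))
  GenomicRanges::sort(peaks)
}

#' Write / read peaks as TSV
#'
#' Columns `chrom`, `start`, `end` (1-based closed), `tag_count`,
#' `p_value`.
#'
#' @param peaks Peak `GRanges` from [call_peaks()].
#' @param path File path.
#' @return `read_peaks_tsv()` returns the peak `GRanges`.
#' @export
write_peaks_tsv <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                   start = BiocGenerics::start(peaks),
                   end = BiocGenerics::end(peaks),
                   tag_count = peaks$tag_count,
                   p_value = peaks$p_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_tsv
#' @export
read_peaks_tsv <- function(path) {
  df <- utils::read.delim(path)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$tag_count <- df$tag_count
  gr$p_value <- df$p_value
  gr
}
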