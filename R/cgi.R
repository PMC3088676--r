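#' CpG observed/expected ratio of a window
#'
#' The Gardiner-Garden statistic: `(N_CpG * L) / (N_C * N_G)` over a
#' window of length L, where `N_CpG` counts CG dinucleotides. When the
#' window has no C or no G the ratio is undefined; the function returns
#' `Inf` as a sentinel, which the island scanner treats as failing the
#' criterion (such a window has no CpG either).
#'
#' @param window_sequence Character scalar (or `DNAString`) of A/C/G/T;
#'   windows containing `N` are rejected.
#' @return The observed/expected ratio.
#' @export
obs_exp_ratio <- function(window_sequence) {
  s <- toupper(as.character(window_sequence))
  if (nchar(s) < 2L) stop("window must be at least 2 bp")
  if (grepl("N", s, fixed = TRUE)) stop("window contains N")
  chars <- strsplit(s, "")[[1]]
  n_c <- sum(chars == "C")
  n_g <- sum(chars == "G")
  n_cpg <- sum(chars[-length(chars)] == "C" & chars[-1L] == "G")
  if (n_c * n_g == 0L) return(Inf)
  (n_cpg * length(chars)) / (n_c * n_g)
}

#' Scan a genome for CpG islands
#'
#' Slides a `window_len` bp window at 1 bp steps; a window qualifies iff it
#' contains no `N`, its G+C fraction exceeds `gc_min` and its CpG
#' observed/expected ratio exceeds `oe_min` (strict inequalities, with the
#' length criterion "length > `window_len`" applied to the merged island).
#' Overlapping and adjacent qualifying windows are merged into maximal
#' islands; the reported GC fraction, observed/expected ratio and CpG count
#' are recomputed over the merged span (reported for information — the
#' merged span is not re-filtered, since each constituent window already
#' qualifies).
#'
#' @param sequences A `DNAStringSet` (or single sequence / character).
#' @param window_len Window length in bp (default 200, the minimum island
#'   length of the criteria).
#' @param gc_min,oe_min Strict lower thresholds for G+C fraction and CpG
#'   observed/expected ratio.
#' @return A sorted, disjoint `GRanges` with metadata columns
#'   `gc_fraction`, `obs_exp` and `n_cpg`.
#' @export
scan_cpg_islands <- function(sequences, window_len = 200L,
                             gc_min = 0.5, oe_min = 0.6) {
  if (is.character(sequences) || methods::is(sequences, "DNAString"))
    sequences <- Biostrings::DNAStringSet(stats::setNames(as.character(sequences), "seq"))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  per_chrom <- lapply(names(sequences), function(chrom) {
    chars <- strsplit(toupper(as.character(sequences[[chrom]])), "")[[1]]
    L <- length(chars)
    if (L < window_len) return(NULL)
    is_c <- chars == "C"; is_g <- chars == "G"; is_n <- !(chars %in% c("A", "C", "G", "T"))
    is_cpg <- c(is_c[-L] & is_g[-1L], FALSE)
    cum <- function(x) c(0L, cumsum(x))
    cc <- cum(is_c); cg <- cum(is_g); cn <- cum(is_n); ccpg <- cum(is_cpg)
    starts <- seq_len(L - window_len + 1L)
    ends <- starts + window_len - 1L
    n_c <- cc[ends + 1L] - cc[starts]
    n_g <- cg[ends + 1L] - cg[starts]
    n_n <- cn[ends + 1L] - cn[starts]
    # CpG fully inside the window: its C at positions start..end-1
    n_cpg <- ccpg[ends] - ccpg[starts]
    gc_ok <- (n_c + n_g) / window_len > gc_min
    oe_ok <- n_c * n_g > 0L & n_cpg * window_len > oe_min * n_c * n_g
    ok <- n_n == 0L & gc_ok & oe_ok
    if (!any(ok)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(starts[ok], width = window_len))
    ir <- ir[IRanges::width(ir) > window_len]
    if (length(ir) == 0L) return(NULL)
    s <- BiocGenerics::start(ir); e <- BiocGenerics::end(ir)
    gr <- GenomicRanges::GRanges(chrom, ir)
    gr$gc_fraction <- (cc[e + 1L] - cc[s] + cg[e + 1L] - cg[s]) / IRanges::width(ir)
    m_nc <- cc[e + 1L] - cc[s]; m_ng <- cg[e + 1L] - cg[s]
    m_ncpg <- ccpg[e] - ccpg[s]
    gr$obs_exp <- ifelse(m_nc * m_ng == 0L, Inf,
                         m_ncpg * IRanges::width(ir) / (m_nc * m_ng))
    gr$n_cpg <- m_ncpg
    gr
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, TRUE)]
  if (length(per_chrom) == 0L) {
    out <- GenomicRanges::GRanges()
    out$gc_fraction <- numeric(0); out$obs_exp <- numeric(0); out$n_cpg <- integer(0)
    return(out)
  }
  GenomicRanges::sort(do.call(c, per_chrom))
}

#' Split CpG islands into methylated and unmethylated sets
#'
#' An island is methylated iff it overlaps at least `min_overlap` bp with
#' at least one methylation peak; the partition is exhaustive and disjoint.
#'
#' @param islands `GRanges` of CpG islands.
#' @param peaks `GRanges` of methylation peaks (HMRs).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List with elements `methylated` and `unmethylated`.
#' @export
classify_methylated_cgis <- function(islands, peaks, min_overlap = 1L) {
  hit <- IRanges::overlapsAny(islands, peaks, minoverlap = min_overlap,
                              ignore.strand = TRUE)
  list(methylated = islands[hit], unmethylated = islands[!hit])
}
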