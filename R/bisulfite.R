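#' Call per-CpG methylation fractions from bisulfite clones
#'
#' Clones must be aligned to the reference region (equal length, no
#' indels, + strand). At each reference CpG cytosine the function counts
#' retained `C` (methylated) versus converted `T` (unmethylated) across
#' clones; any other base at that position is ignored but counted in
#' `n_other`. Non-CpG cytosines are used to estimate the bisulfite
#' conversion efficiency, reported as an attribute but never used to
#' adjust the calls.
#'
#' @param reference_region_seq Reference sequence of the region (character
#'   or `DNAString`).
#' @param clone_seqs `DNAStringSet` (or character vector) of clone
#'   sequences, each the same length as the reference.
#' @return `data.frame` with `position` (1-based within the region),
#'   `n_c`, `n_t`, `n_other`, `fraction`; attribute
#'   `conversion_efficiency` holds the observed non-CpG C -> T rate (NA
#'   when the region has no non-CpG cytosine).
#' @export
call_methylation <- function(reference_region_seq, clone_seqs) {
  ref <- strsplit(toupper(as.character(reference_region_seq)), "")[[1]]
  clones <- toupper(as.character(clone_seqs))
  if (any(nchar(clones) != length(ref)))
    stop("clone length differs from reference length")
  mat <- do.call(rbind, strsplit(clones, ""))
  cpg <- which(ref[-length(ref)] == "C" & ref[-1L] == "G")
  noncpg_c <- setdiff(which(ref == "C"), cpg)
  conv <- if (length(noncpg_c)) {
    sub <- mat[, noncpg_c, drop = FALSE]
    sum(sub == "T") / sum(sub %in% c("C", "T"))
  } else NA_real_
  if (length(cpg) == 0L) {
    out <- data.frame(position = integer(0), n_c = integer(0), n_t = integer(0),
                      n_other = integer(0), fraction = numeric(0))
    attr(out, "conversion_efficiency") <- conv
    return(out)
  }
  n_c <- colSums(mat[, cpg, drop = FALSE] == "C")
  n_t <- colSums(mat[, cpg, drop = FALSE] == "T")
  n_other <- nrow(mat) - n_c - n_t
  out <- data.frame(position = cpg, n_c = n_c, n_t = n_t, n_other = n_other,
                    fraction = n_c / (n_c + n_t), row.names = NULL)
  attr(out, "conversion_efficiency") <- conv
  out
}

#' Lollipop-style text matrix of clone methylation
#'
#' One row per clone, one column per CpG: `*` for retained C (methylated),
#' `o` for converted T, `?` otherwise.
#'
#' @param reference_region_seq Reference sequence of the region.
#' @param clone_seqs Clone sequences.
#' @return Character matrix (clones x CpGs).
#' @export
methylation_lollipop <- function(reference_region_seq, clone_seqs) {
  ref <- strsplit(toupper(as.character(reference_region_seq)), "")[[1]]
  clones <- toupper(as.character(clone_seqs))
  mat <- do.call(rbind, strsplit(clones, ""))
  cpg <- which(ref[-length(ref)] == "C" & ref[-1L] == "G")
  sub <- mat[, cpg, drop = FALSE]
  out <- ifelse(sub == "C", "*", ifelse(sub == "T", "o", "?"))
  dimnames(out) <- list(if (!is.null(names(clone_seqs))) names(clone_seqs),
                        paste0("CpG", cpg))
  out
}

#' Peak versus non-peak bisulfite concordance
#'
#' Labels each validation region `peak` or `non_peak` by overlap with the
#' called peak set, summarizes its per-CpG methylation fractions, and
#' checks the expected separation: mean fraction over peak regions above
#' mean fraction over non-peak regions. Failure of that separation raises
#' a warning (loudly, but without aborting a pipeline run).
#'
#' @param peaks Peak `GRanges`.
#' @param calls_by_region Named list of per-region call `data.frame`s from
#'   [call_methylation()]; names are region ids.
#' @param regions `GRanges` of the validation regions, in the same order
#'   as `calls_by_region`, with a `region_id` metadata column (or names).
#' @param n_clones Number of clones per region (recorded in the report).
#' @return `data.frame` of class `concordance_report`: `region_id`,
#'   `region_kind`, `mean_fraction`, `n_cpgs`, `n_clones`; attribute
#'   `separation` holds mean(peak) - mean(non_peak).
#' @export
concordance <- function(peaks, calls_by_region, regions, n_clones = NA_integer_) {
  ids <- if (!is.null(regions$region_id)) regions$region_id else names(regions)
  if (is.null(ids)) ids <- paste0("region_", seq_along(regions))
  stopifnot(length(calls_by_region) == length(regions))
  kind <- ifelse(IRanges::overlapsAny(regions, peaks, ignore.strand = TRUE),
                 "peak", "non_peak")
  if (!all(c("peak", "non_peak") %in% kind))
    stop("need at least one region of each kind (peak and non_peak)")
  mean_fraction <- vapply(calls_by_region, function(df) {
    if (nrow(df) == 0L) NA_real_ else mean(df$fraction)
  }, 0)
  out <- data.frame(region_id = ids, region_kind = kind,
                    mean_fraction = mean_fraction,
                    n_cpgs = vapply(calls_by_region, nrow, 0L),
                    n_clones = n_clones, row.names = NULL)
  sep <- mean(out$mean_fraction[kind == "peak"], na.rm = TRUE) -
    mean(out$mean_fraction[kind == "non_peak"], na.rm = TRUE)
  if (!is.na(sep) && sep <= 0)
    warning("concordance check failed: peak regions are not more methylated ",
            "than non-peak regions (separation = ", signif(sep, 3), ")")
  attr(out, "separation") <- sep
  class(out) <- c("concordance_report", "data.frame")
  out
}
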