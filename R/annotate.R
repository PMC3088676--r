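#' Classify regions into genomic feature categories
#'
#' Categories follow the HMR/CGI summary convention: `five_prime` is the
#' 2 kb strand-aware region upstream of a TSS, `three_prime` the 2 kb
#' downstream of a TTS, `exon` / `intron` overlap with any exon or exon
#' gap of any gene, and `intergenic` means none of the above. Counting is
#' non-exclusive — a region straddling an exon/intron boundary increments
#' both — except `intergenic`, which excludes all other labels.
#'
#' `classify_regions()` returns the full logical incidence matrix;
#' `classify_region()` is the single-region convenience wrapper returning
#' the category names.
#'
#' @param regions `GRanges` of regions to classify.
#' @param gm A [gene_models] object.
#' @param flank_len Flank length defining the 5'/3' end categories (bp).
#' @return `classify_regions()`: logical matrix (regions x 5 categories);
#'   `classify_region()`: character vector of categories for one region.
#' @export
classify_regions <- function(regions, gm, flank_len = 2000L) {
  ov <- function(subject) {
    if (length(subject) == 0L) return(rep(FALSE, length(regions)))
    IRanges::overlapsAny(regions, subject, ignore.strand = TRUE)
  }
  five <- ov(gene_flank5(gm, flank_len))
  three <- ov(gene_flank3(gm, flank_len))
  exon <- ov(unlist(gm$exons))
  intron <- ov(unlist(gene_introns(gm)))
  inter <- !(five | three | exon | intron)
  cbind(five_prime = five, three_prime = three, exon = exon,
        intron = intron, intergenic = inter)
}

#' @rdname classify_regions
#' @param region A single-range `GRanges`.
#' @export
classify_region <- function(region, gm, flank_len = 2000L) {
  stopifnot(length(region) == 1L)
  m <- classify_regions(region, gm, flank_len)
  colnames(m)[m[1L, ]]
}

feature_category_counts <- function(regions, gm, flank_len = 2000L) {
  if (length(regions) == 0L)
    return(c(five_prime = 0L, three_prime = 0L, exon = 0L,
             intron = 0L, intergenic = 0L))
  colSums(classify_regions(regions, gm, flank_len))
}

#' Percentage of methylated CpG islands
#'
#' `100 * n_methylated / n_total`, rounded to one decimal — the arithmetic
#' of the methylated-CGI summary tables.
#'
#' @param n_methylated,n_total Island counts.
#' @return Percentage rounded to one decimal.
#' @export
methylated_percent <- function(n_methylated, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  round(100 * n_methylated / n_total, 1)
}

#' Summarize methylated CpG islands by genomic feature
#'
#' Islands overlapping a peak are methylated; each methylated island is
#' counted once per overlapping feature category (non-exclusive, so the
#' category counts may sum to more than the methylated total), and the
#' methylated percentage is computed over all islands.
#'
#' @param islands CpG island `GRanges`.
#' @param peaks Peak `GRanges`.
#' @param genes A [gene_models] object.
#' @param flank_len Flank length for the 5'/3' categories (bp).
#' @return A list of class `annotation_summary` with the per-category
#'   counts, `total_methylated`, `total_cgis` and `methylated_percent`.
#' @export
summarize_cgi_methylation <- function(islands, peaks, genes, flank_len = 2000L) {
  if (length(islands) == 0L) stop("no CpG islands supplied")
  split <- classify_methylated_cgis(islands, peaks)
  counts <- feature_category_counts(split$methylated, genes, flank_len)
  structure(c(as.list(counts),
              list(total_methylated = length(split$methylated),
                   total_cgis = length(islands),
                   methylated_percent = methylated_percent(length(split$methylated),
                                                           length(islands)))),
            class = "annotation_summary")
}

#' Summarize the feature distribution of HMRs
#'
#' Non-exclusive per-category counts of called peaks, as in the
#' HMR-distribution summary; `total_regions` is the number of peaks.
#'
#' @inheritParams summarize_cgi_methylation
#' @return A list of class `annotation_summary`.
#' @export
summarize_hmr_distribution <- function(peaks, genes, flank_len = 2000L) {
  counts <- feature_category_counts(peaks, genes, flank_len)
  structure(c(as.list(counts), list(total_regions = length(peaks))),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  df <- as.data.frame(x[!vapply(x, is.null, TRUE)])
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.annotation_summary <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Fraction of tags falling in repeat elements
#'
#' A tag belongs to a repeat iff its extended fragment overlaps it by at
#' least 1 bp. Per-family fractions are computed over repeat-assigned tags
#' only (they sum to 1); a tag overlapping several repeats is assigned to
#' the longest overlap, ties broken by repeat coordinate.
#'
#' @param tags Tag `GRanges`.
#' @param repeats Repeat `GRanges` with a `family` metadata column.
#' @param extension_length Fragment extension in bp.
#' @return List with `overall` (fraction of all tags in repeats) and
#'   `per_family` (named numeric).
#' @export
repeat_tag_fraction <- function(tags, repeats, extension_length = 275L) {
  if (length(repeats) == 0L || length(tags) == 0L)
    return(list(overall = 0, per_family = stats::setNames(numeric(0), character(0))))
  ext <- extend_tags(tags, extension_length)
  hits <- GenomicRanges::findOverlaps(ext, repeats, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(list(overall = 0, per_family = stats::setNames(numeric(0), character(0))))
  ovw <- BiocGenerics::width(IRanges::pintersect(ext[S4Vectors::queryHits(hits)],
                                                 repeats[S4Vectors::subjectHits(hits)],
                                                 ignore.strand = TRUE))
  ord <- order(S4Vectors::queryHits(hits), -ovw,
               BiocGenerics::start(repeats)[S4Vectors::subjectHits(hits)])
  first <- !duplicated(S4Vectors::queryHits(hits)[ord])
  assigned <- S4Vectors::subjectHits(hits)[ord][first]
  fam <- table(repeats$family[assigned])
  list(overall = length(assigned) / length(tags),
       per_family = stats::setNames(as.numeric(fam) / length(assigned), names(fam)))
}
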