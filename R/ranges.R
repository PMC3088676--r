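#' Gene model container
#'
#' Bundles gene spans and their exon structure into a light container used
#' throughout the package. Gene spans are a \code{GRanges} with strand
#' \code{+} or \code{-} and a \code{gene_id} metadata column; exons are a
#' \code{GRangesList} parallel to the genes. The transcription start site
#' (TSS) is the strand-aware 5' end of the span and the transcription
#' termination site (TTS) the strand-aware 3' end.
#'
#' @param genes `GRanges` of gene spans; strand must be `+` or `-`; must
#'   carry a `gene_id` metadata column with unique values.
#' @param exons `GRangesList` parallel to `genes`: per gene, sorted,
#'   pairwise-disjoint exons contained in the gene span.
#' @return An object of class `gene_models` with elements `genes` and
#'   `exons`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(exons, "GRangesList"))
  exons <- methods::as(exons, "CompressedGRangesList")
  if (is.null(genes$gene_id)) stop("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id values")
  if (length(exons) != length(genes)) stop("exons must be parallel to genes")
  if (any(!as.character(BiocGenerics::strand(genes)) %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  for (i in seq_along(genes)) {
    ex <- exons[[i]]
    if (length(ex) == 0L) stop("gene ", genes$gene_id[i], " has no exons")
    if (is.unsorted(BiocGenerics::start(ex)))
      stop("exons of gene ", genes$gene_id[i], " are not sorted")
    if (length(ex) > 1L &&
        any(BiocGenerics::start(ex)[-1L] <= BiocGenerics::end(ex)[-length(ex)]))
      stop("exons of gene ", genes$gene_id[i], " overlap")
    contained <- BiocGenerics::start(ex) >= BiocGenerics::start(genes)[i] &
      BiocGenerics::end(ex) <= BiocGenerics::end(genes)[i]
    if (!all(contained))
      stop("exon outside the span of gene ", genes$gene_id[i])
  }
  names(exons) <- genes$gene_id
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$genes), "genes,",
      sum(lengths(x$exons)), "exons on",
      length(unique(as.character(GenomeInfoDb::seqnames(x$genes)))),
      "chromosome(s)\n")
  invisible(x)
}

#' @export
length.gene_models <- function(x) length(x$genes)

#' Strand-aware gene anchors and promoter windows
#'
#' `gene_tss()` / `gene_tts()` return width-1 ranges at the 5' and 3' ends
#' of each gene. `gene_promoters()` returns the proximal promoter, the
#' region from `upstream` bp before to `downstream` bp after the TSS
#' (default 2 kb each side). `gene_flank5()` / `gene_flank3()` return the
#' 2 kb flank entirely upstream of the TSS / downstream of the TTS, the
#' regions used for the "5' end of a gene" / "3' end of a gene" feature
#' categories.
#'
#' @param gm A `gene_models` object.
#' @param upstream,downstream,width Flank sizes in bp.
#' @return A `GRanges` parallel to the genes.
#' @export
gene_tss <- function(gm) GenomicRanges::resize(gm$genes, width = 1L, fix = "start")

#' @rdname gene_tss
#' @export
gene_tts <- function(gm) GenomicRanges::resize(gm$genes, width = 1L, fix = "end")

#' @rdname gene_tss
#' @export
gene_promoters <- function(gm, upstream = 2000L, downstream = 2000L) {
  GenomicRanges::promoters(gm$genes, upstream = upstream, downstream = downstream)
}

#' @rdname gene_tss
#' @export
gene_flank5 <- function(gm, width = 2000L) {
  GenomicRanges::flank(gm$genes, width = width, start = TRUE)
}

#' @rdname gene_tss
#' @export
gene_flank3 <- function(gm, width = 2000L) {
  GenomicRanges::flank(gm$genes, width = width, start = FALSE)
}

#' Intronic ranges of each gene
#'
#' @param gm A `gene_models` object.
#' @return A `GRangesList` parallel to the genes holding the gaps between
#'   consecutive exons (empty for single-exon genes).
#' @export
gene_introns <- function(gm) {
  GenomicRanges::psetdiff(gm$genes, gm$exons)
}
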