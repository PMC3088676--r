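#' Library-size normalization of RNA tag counts
#'
#' Scales raw per-gene tag counts to tags per million:
#' `raw_tags * 1e6 / library_size`, with the library size the sum of all
#' raw counts.
#'
#' @param raw_counts Named numeric vector of raw tag counts.
#' @return `data.frame` with `gene_id`, `raw_tags`, `tags_per_million`
#'   (input order preserved).
#' @export
normalize_expression <- function(raw_counts) {
  if (is.null(names(raw_counts))) stop("raw_counts must be named by gene_id")
  lib <- sum(raw_counts)
  if (lib <= 0) stop("all-zero library: cannot normalize")
  data.frame(gene_id = names(raw_counts),
             raw_tags = as.numeric(raw_counts),
             tags_per_million = as.numeric(raw_counts) * 1e6 / lib,
             row.names = NULL)
}

#' Promoter methylation score of genes
#'
#' The proximal promoter is TSS +/- `flank_len` (strand-aware). The score
#' is `-log10` of the smallest p-value among peaks overlapping the
#' promoter, and 0 when no peak overlaps — absence of a peak is evidence
#' of low methylation (p = 1), not missing data.
#'
#' @param genes A [gene_models] object.
#' @param peaks Peak `GRanges` with a `p_value` column.
#' @param flank_len Promoter half-width in bp.
#' @return Named numeric vector of scores (one per gene).
#' @export
promoter_methylation_score <- function(genes, peaks, flank_len = 2000L) {
  prom <- gene_promoters(genes, flank_len, flank_len)
  score <- rep(0, length(prom))
  if (length(peaks)) {
    hits <- GenomicRanges::findOverlaps(prom, peaks, ignore.strand = TRUE)
    if (length(hits)) {
      minp <- tapply(peaks$p_value[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits), min)
      idx <- as.integer(names(minp))
      score[idx] <- -log10(as.numeric(minp))
    }
  }
  stats::setNames(score, genes$genes$gene_id)
}

#' Expression-decile versus promoter-methylation correlation
#'
#' Genes are sorted by normalized expression (ascending, ties broken by
#' gene id) and split into 10 near-equal deciles (sizes differ by at most
#' one; the lowest deciles absorb the remainder). For each decile the mean
#' expression and mean methylation score are computed; `r` is the Pearson
#' correlation over the 10 (mean expression, mean score) pairs, with the
#' two-sided p-value for n = 10 reported alongside.
#'
#' @param expression `data.frame` from [normalize_expression()].
#' @param scores Named numeric vector from [promoter_methylation_score()];
#'   must cover the same gene ids.
#' @param n_groups Number of expression groups (default 10).
#' @return A list of class `decile_correlation` with `r`, `p_value` and
#'   `table` (`decile`, `mean_tags_per_million`, `mean_score`, `n_genes`).
#' @export
decile_correlation <- function(expression, scores, n_groups = 10L) {
  if (nrow(expression) < n_groups)
    stop("need at least ", n_groups, " genes")
  missing <- setdiff(expression$gene_id, names(scores))
  if (length(missing))
    stop("no methylation score for gene(s): ", paste(missing, collapse = ", "))
  ord <- order(expression$tags_per_million, expression$gene_id)
  tpm <- expression$tags_per_million[ord]
  sc <- as.numeric(scores[expression$gene_id[ord]])
  n <- length(tpm)
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  decile <- rep(seq_len(n_groups), sizes)
  mean_tpm <- tapply(tpm, decile, mean)
  mean_score <- tapply(sc, decile, mean)
  if (stats::sd(mean_tpm) == 0 || stats::sd(mean_score) == 0)
    stop("undefined correlation: zero variance in decile means")
  ct <- stats::cor.test(mean_tpm, mean_score)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 table = data.frame(decile = seq_len(n_groups),
                                    mean_tags_per_million = as.numeric(mean_tpm),
                                    mean_score = as.numeric(mean_score),
                                    n_genes = sizes)),
            class = "decile_correlation")
}

#' @export
print.decile_correlation <- function(x, ...) {
  cat(sprintf("decile_correlation: Pearson r = %.3f (p = %.3g) over %d deciles\n",
              x$r, x$p_value, nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
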