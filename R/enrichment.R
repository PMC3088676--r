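#' One-sided Fisher over-representation p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of drawing at least
#' `k` term genes in a sample of `n` genes from a universe of `N` genes of
#' which `K` carry the term.
#'
#' @param k Observed overlap (selected genes carrying the term).
#' @param K Term size.
#' @param n Selected-set size.
#' @param N Universe size.
#' @return Tail probability in (0, 1].
#' @export
fisher_over_representation <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k > pmin(K, n))) stop("k must not exceed min(K, n)")
  if (any(k < pmax(0, K + n - N))) stop("k below the feasible minimum overlap")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Select methylated genes
#'
#' A gene is methylated iff any peak overlaps its proximal promoter
#' (TSS +/- `flank_len`) or its gene body (the full span).
#'
#' @param genes A [gene_models] object.
#' @param peaks Peak `GRanges`.
#' @param flank_len Promoter half-width in bp.
#' @return Character vector of methylated gene ids.
#' @export
select_methylated_genes <- function(genes, peaks, flank_len = 2000L) {
  if (length(peaks) == 0L) return(character(0))
  prom <- gene_promoters(genes, flank_len, flank_len)
  hit <- IRanges::overlapsAny(prom, peaks, ignore.strand = TRUE) |
    IRanges::overlapsAny(genes$genes, peaks, ignore.strand = TRUE)
  genes$genes$gene_id[hit]
}

#' GO over-representation with a resampled null
#'
#' For each term the Fisher (hypergeometric upper-tail) p-value of the
#' observed selected set is computed, then calibrated against `iters`
#' random same-size gene samples from the universe: the empirical p-value
#' is `(1 + #{samples with fisher_p <= observed}) / (iters + 1)` (the +1
#' correction keeps it off zero). Both p-values are reported; no
#' multiple-testing correction is applied.
#'
#' @param selected Character vector of selected (methylated) gene ids;
#'   must be a subset of the annotation universe.
#' @param annotation List with `terms` (named list term -> gene ids) and
#'   `universe`, as from [read_go_annotation()].
#' @param iters Number of resampling iterations (>= 1).
#' @param seed RNG seed for the resampling.
#' @return `data.frame` with columns `term`, `k`, `K`, `n`, `N`,
#'   `fisher_p`, `empirical_p`, sorted by `fisher_p` (ties by term id).
#' @export
resampled_enrichment <- function(selected, annotation, iters = 999L, seed = 1L) {
  stopifnot(iters >= 1L)
  universe <- annotation$universe
  selected <- unique(selected)
  outside <- setdiff(selected, universe)
  if (length(outside))
    stop("selected genes outside the annotation universe: ",
         paste(outside, collapse = ", "))
  terms <- annotation$terms
  N <- length(universe)
  n <- length(selected)
  K <- vapply(terms, length, 0L)
  k_obs <- vapply(terms, function(g) length(intersect(g, selected)), 0L)
  fisher_p <- fisher_over_representation(k_obs, K, n, N)

  set.seed(seed)
  memb <- vapply(terms, function(g) universe %in% g, logical(N))  # N x T
  exceed <- numeric(length(terms))
  for (it in seq_len(iters)) {
    samp <- sample.int(N, n)
    k_s <- colSums(memb[samp, , drop = FALSE])
    p_s <- fisher_over_representation(k_s, K, n, N)
    exceed <- exceed + (p_s <= fisher_p)
  }
  empirical_p <- (1 + exceed) / (iters + 1)
  out <- data.frame(term = names(terms), k = k_obs, K = K, n = n, N = N,
                    fisher_p = as.numeric(fisher_p),
                    empirical_p = as.numeric(empirical_p),
                    row.names = NULL)
  out[order(out$fisher_p, out$term), , drop = FALSE]
}
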