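#' Metagene methylation profile around genes
#'
#' Computes the classic 60-window average profile of normalized depth:
#' per gene, 20 fixed-width windows tiling the 2 kb upstream flank
#' (ending at the TSS), 20 equal-fraction windows tiling the gene body
#' (window i spans `[floor(i*L/20), floor((i+1)*L/20))` of the gene, an
#' exact tiling), and 20 fixed-width windows tiling the 2 kb downstream
#' flank. Windows are strand-aware: index 1 is always the 5'-most
#' upstream window. Each window's value is its mean depth times the
#' tags-per-ten-million scale factor; the profile is the mean over genes.
#'
#' Genes shorter than `min_gene_len` are excluded (and not counted in
#' `n_genes_used`); window parts outside chromosome bounds are trimmed.
#'
#' @param track A `coverage_track` from [build_coverage()].
#' @param genes A [gene_models] object.
#' @param flank_len Flank length in bp (default 2000; 100 bp per window).
#' @param n_windows Windows per segment (default 20).
#' @param min_gene_len Minimum gene length in bp (default 200).
#' @param normalize Scale window means by `1e7 / library_size`?
#' @return A list of class `metagene_profile`: `values` (length
#'   `3 * n_windows`), `segment` (labels `upstream` / `body` /
#'   `downstream`), `n_genes_used`, `normalization`.
#' @export
compute_metagene <- function(track, genes, flank_len = 2000L, n_windows = 20L,
                             min_gene_len = 200L, normalize = TRUE) {
  stopifnot(inherits(track, "coverage_track"))
  g <- genes$genes
  g <- g[BiocGenerics::width(g) >= min_gene_len]
  if (length(g) == 0L) stop("zero usable genes (all shorter than ", min_gene_len, " bp)")
  nseg <- 3L * n_windows
  fw <- flank_len / n_windows
  chrom_lens <- vapply(track$depth, length, 0L)

  prof <- matrix(NA_real_, nrow = length(g), ncol = nseg)
  for (i in seq_along(g)) {
    chrom <- as.character(GenomeInfoDb::seqnames(g))[i]
    L <- BiocGenerics::width(g)[i]
    gs <- BiocGenerics::start(g)[i]; ge <- BiocGenerics::end(g)[i]
    body_bounds <- gs + floor((0:n_windows) * L / n_windows)   # half-open tiling
    up_bounds <- gs - flank_len + round((0:n_windows) * fw)
    down_bounds <- ge + 1L + round((0:n_windows) * fw)
    bounds <- c(up_bounds, body_bounds[-1L], down_bounds[-1L])
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    cl <- chrom_lens[[chrom]]
    ok <- ends >= 1L & starts <= cl
    vals <- rep(NA_real_, nseg)
    if (any(ok)) {
      v <- IRanges::Views(track$depth[[chrom]],
                          IRanges::IRanges(pmax(starts[ok], 1L), pmin(ends[ok], cl)))
      vals[ok] <- IRanges::viewMeans(v)
    }
    if (as.character(BiocGenerics::strand(g))[i] == "-") vals <- rev(vals)
    prof[i, ] <- vals
  }
  scale <- if (normalize) 1e7 / track$library_size else 1
  values <- colMeans(prof, na.rm = TRUE) * scale
  structure(list(values = values,
                 segment = rep(c("upstream", "body", "downstream"), each = n_windows),
                 n_genes_used = length(g),
                 normalization = scale),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  n <- length(x$values) / 3
  cat("metagene_profile over", x$n_genes_used, "genes\n")
  cat(sprintf("  upstream mean %.3f | body mean %.3f | downstream mean %.3f\n",
              mean(x$values[x$segment == "upstream"]),
              mean(x$values[x$segment == "body"]),
              mean(x$values[x$segment == "downstream"])))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  n <- length(x$values) / 3
  graphics::plot(seq_along(x$values), x$values, type = "l",
                 xlab = "window (upstream | body | downstream)",
                 ylab = "mean normalized depth", ...)
  graphics::abline(v = c(n, 2 * n) + 0.5, lty = 2, col = "grey40")
}

#' Write a metagene profile to TSV
#'
#' Columns `window`, `segment`, `mean_depth`.
#'
#' @param profile A `metagene_profile`.
#' @param path File path.
#' @export
write_metagene_tsv <- function(profile, path) {
  utils::write.table(data.frame(window = seq_along(profile$values),
                                segment = profile$segment,
                                mean_depth = profile$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
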