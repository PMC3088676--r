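#' Simulation parameters for the synthetic methylome
#'
#' Collects every knob of the synthetic genome / methylation-landscape /
#' sequencing generator. Defaults describe the benchmark conditions used
#' throughout the package: a 1 Mb chromosome carrying 40 genes of 2-10 kb
#' spaced at least 5 kb apart, with half of the promoters carrying a planted
#' CpG island, single-copy repeat elements in the intergenic space, and a
#' methylation landscape that is high over gene bodies and repeats, low over
#' promoter flanks and CpG islands, and intermediate elsewhere.
#'
#' Methylation levels are per-CpG probabilities in \[0,1\] assigned by
#' region with precedence CGI > repeat > flank > body > intergenic.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_genes Genes per genome.
#' @param gene_len_min,gene_len_max Gene length bounds in bp.
#' @param flank_len Promoter/terminator flank length in bp (2 kb).
#' @param gene_gap_min Minimum gap between consecutive gene spans in bp.
#' @param cgi_prob Probability a promoter carries a planted CpG island.
#' @param cgi_meth_prob Probability a planted island is hypermethylated at
#'   `m_cgi_meth` instead of `m_cgi`. The default landscape keeps every
#'   island unmethylated; raise this to exercise the methylated-island
#'   classification on synthetic data. Methylated islands are extreme
#'   MeDIP attractors (high CpG density times high level), so non-zero
#'   values make promoter peak scores heavy-tailed.
#' @param m_cgi_meth Methylation level of methylated islands.
#' @param cgi_shore_len Length in bp of the island shores: the island's
#'   methylation level extends this far beyond the island sequence on both
#'   sides, so the transition to the surrounding level happens outside the
#'   detectable island.
#' @param cpg_spacing Background CpG spacing in bp: outside planted CpG
#'   islands, one CpG is placed per `cpg_spacing`-bp bin at a uniform
#'   within-bin position, giving a CpG-depleted background whose density
#'   is locally near-constant (so MeDIP coverage reflects methylation
#'   level, the quantity the benchmark probes, rather than CpG-density
#'   fluctuation).
#' @param n_repeats Number of single-copy repeat elements.
#' @param repeat_len_min,repeat_len_max Repeat length bounds in bp.
#' @param cr1_fraction Probability a repeat belongs to the CR1 family.
#' @param m_body,m_flank,m_cgi,m_repeat,m_intergenic Methylation levels.
#' @param m_high Level at or above which a region counts as a methylated
#'   domain of the ground truth.
#' @param epsilon Unmethylated pulldown baseline: a fragment's sampling
#'   weight is the summed methylation of its CpGs plus
#'   `epsilon * fragment_len / 100`.
#' @param frag_len_min,frag_len_max Sonicated fragment length bounds in bp.
#' @param read_len Sequencing read (tag) length in bp.
#' @param n_medip_reads MeDIP tags to simulate.
#' @param n_rna_tags RNA tags to distribute over genes.
#' @param beta Expression-promoter-methylation coupling (>= 0): the
#'   expression rate of gene g is proportional to
#'   `e_g * exp(-beta * P_g)` with `P_g` the mean landscape level over the
#'   CpGs in TSS +/- `flank_len`.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of the base
#'   expression level `e_g`.
#' @param conversion_rate Bisulfite conversion probability for unmethylated
#'   (non-CpG) cytosines.
#' @param n_clones Bisulfite clones sequenced per region.
#' @param seed Master seed; every generator substream (genome, medip, rna,
#'   bis, go) is derived from it deterministically.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_chrom = 1L, chrom_len = 1e6, n_genes = 40L,
                       gene_len_min = 2000L, gene_len_max = 10000L,
                       flank_len = 2000L, gene_gap_min = 5000L,
                       cgi_prob = 0.5, cgi_meth_prob = 0,
                       m_cgi_meth = 0.8, cgi_shore_len = 300L,
                       cpg_spacing = 100L,
                       n_repeats = 30L, repeat_len_min = 500L,
                       repeat_len_max = 1500L, cr1_fraction = 0.6,
                       m_body = 0.7, m_flank = 0.1, m_cgi = 0.05,
                       m_repeat = 0.8, m_intergenic = 0.35, m_high = 0.6,
                       epsilon = 0.01,
                       frag_len_min = 200L, frag_len_max = 350L,
                       read_len = 35L, n_medip_reads = 200000L,
                       n_rna_tags = 1e6, beta = 2,
                       expr_meanlog = 0, expr_sdlog = 0.6,
                       conversion_rate = 0.99, n_clones = 10L,
                       seed = 1L) {
  p <- as.list(environment())
  levels <- c(p$m_body, p$m_flank, p$m_cgi, p$m_repeat, p$m_intergenic)
  if (any(levels < 0 | levels > 1)) stop("methylation levels must lie in [0,1]")
  if (p$epsilon < 0) stop("epsilon must be >= 0")
  if (p$beta < 0) stop("beta must be >= 0")
  if (p$gene_len_min > p$gene_len_max) stop("invalid gene length bounds")
  if (p$frag_len_min > p$frag_len_max || p$frag_len_min < p$read_len)
    stop("invalid fragment length bounds")
  structure(p, class = "sim_params")
}

# Deterministic substream seeds (< 2^31) derived from the master seed, so
# that each generator component is reproducible on its own.
derive_seed <- function(seed, stream) {
  offset <- c(genome = 101L, medip = 211L, rna = 307L, bis = 401L,
              go = 503L, regions = 601L)[[stream]]
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

random_dna <- function(n, p_gc = 0.42) {
  probs <- c(A = (1 - p_gc) / 2, C = p_gc / 2, G = p_gc / 2, T = (1 - p_gc) / 2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# CpG-depleted background with locally near-constant CpG density: all
# spontaneous CG dinucleotides are broken, then one CG is planted at a
# uniform position inside each `cpg_spacing`-bp bin (stratified placement).
# Holding density locally constant makes MeDIP coverage track methylation
# level rather than CpG-density fluctuation, which is what the benchmark
# probes; the overall density (1 CpG per `cpg_spacing` bp) matches a
# CpG-depleted vertebrate background.
random_background <- function(n, p_gc = 0.42, cpg_spacing = 100L) {
  chars <- random_dna(n, p_gc)
  cg <- which(chars[-length(chars)] == "C" & chars[-1L] == "G")
  if (length(cg))
    chars[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
  bin_starts <- seq.int(1L, n - cpg_spacing + 1L, by = cpg_spacing)
  pos <- bin_starts + sample.int(cpg_spacing - 1L, length(bin_starts),
                                 replace = TRUE) - 1L
  chars[pos] <- "C"
  chars[pos + 1L] <- "G"
  chars
}

# Planted island sequence: GC 0.6 with one CpG per 16 bp (observed/expected
# ~0.69), comfortably but not extravagantly above the island criteria
# (GC > 0.5, obs/exp > 0.6) — like real islands, detectable without being
# caricatures, and with a methylated-CpG mass at m_cgi that stays below the
# pulldown background (most islands are unmethylated and must not peak).
cgi_like_dna <- function(n) {
  random_background(n, p_gc = 0.6, cpg_spacing = 16L)
}

cpg_positions <- function(chars) {
  which(chars[-length(chars)] == "C" & chars[-1L] == "G")
}

#' Generate a synthetic genome with a planted methylation landscape
#'
#' Builds a CpG-depleted background sequence, packs non-overlapping genes
#' (with exon/intron structure) separated by at least `gene_gap_min`,
#' plants a CG-rich island over roughly `cgi_prob` of the promoters
#' (spanning from 500 bp upstream of the TSS to the end of the proximal
#' promoter, so island-promoter genes are hypomethylated across the whole
#' TSS +/- 2 kb window, as CpG-island promoters are in vivo; a fraction
#' `cgi_meth_prob` of islands is instead hypermethylated, and every
#' island's level extends over `cgi_shore_len` bp shores), drops
#' single-copy repeat elements into the intergenic space, and assigns every
#' + strand CpG a methylation level by region with precedence
#' CGI > repeat > flank > body > intergenic.
#'
#' @param params A [sim_params] object.
#' @return A list with `sequences` (`DNAStringSet` with seqlengths),
#'   `truth` (class `synthetic_truth`: `genes`, `repeats`, `planted_cgis`,
#'   `methylated_domains`, `regions` — the precedence-resolved region map —
#'   and `params`) and `landscape` (width-1 `GRanges` with `m`).
#' @export
generate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, "genome"))
  n_per_chrom <- diff(floor(seq(0, params$n_genes, length.out = params$n_chrom + 1)))
  chrom_names <- paste0("chr", seq_len(params$n_chrom))
  chrom_lengths <- stats::setNames(rep(as.integer(params$chrom_len), params$n_chrom),
                                   chrom_names)

  seq_chars <- list()
  gene_rows <- list(); exon_rows <- list(); cgi_rows <- list(); rep_rows <- list()
  gid <- 0L
  for (ci in seq_len(params$n_chrom)) {
    chrom <- chrom_names[ci]
    L <- chrom_lengths[[chrom]]
    chars <- random_background(L, cpg_spacing = params$cpg_spacing)
    ng <- n_per_chrom[ci]

    # --- gene packing: margins cover flanks and keep >= gene_gap_min gaps
    lens <- sample(seq(params$gene_len_min, params$gene_len_max), ng, replace = TRUE)
    edge <- params$gene_gap_min
    slack <- L - sum(lens) - (ng + 1L) * edge
    if (slack < 0)
      stop("chrom_len too small to pack ", ng, " genes with ", edge,
           " bp gaps; increase chrom_len")
    cuts <- sort(sample.int(slack + 1L, ng + 1L, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    starts <- integer(ng)
    pos <- 0L
    for (i in seq_len(ng)) {
      pos <- pos + edge + extra[i]
      starts[i] <- pos + 1L
      pos <- pos + lens[i]
    }
    strands <- sample(c("+", "-"), ng, replace = TRUE)

    for (i in seq_len(ng)) {
      gid <- gid + 1L
      g_start <- starts[i]; g_end <- starts[i] + lens[i] - 1L
      id <- sprintf("gene_%03d", gid)
      gene_rows[[gid]] <- data.frame(chrom = chrom, start = g_start, end = g_end,
                                     strand = strands[i], gene_id = id)
      # exon/intron structure: odd segments are exons
      k <- sample(2:6, 1L)
      nseg <- 2L * k - 1L
      w <- as.vector(stats::rmultinom(1L, lens[i] - nseg * 50L, rep(1, nseg))) + 50L
      bounds <- g_start + cumsum(c(0L, w))
      ex_i <- seq(1L, nseg, by = 2L)
      exon_rows[[gid]] <- data.frame(chrom = chrom,
                                     start = bounds[ex_i],
                                     end = bounds[ex_i + 1L] - 1L,
                                     strand = strands[i], gene_id = id)
      # CpG-island planting across the proximal promoter
      if (stats::runif(1) < params$cgi_prob) {
        if (strands[i] == "+") {
          c_start <- g_start - 500L
          c_end <- g_start + params$flank_len - 1L
        } else {
          c_start <- g_end - params$flank_len + 1L
          c_end <- g_end + 500L
        }
        cgi_m <- if (stats::runif(1) < params$cgi_meth_prob)
          params$m_cgi_meth else params$m_cgi
        cgi_rows[[length(cgi_rows) + 1L]] <-
          data.frame(chrom = chrom, start = c_start, end = c_end, m = cgi_m)
        chars[c_start:c_end] <- cgi_like_dna(c_end - c_start + 1L)
      }
    }

    # --- repeats in intergenic space, >= flank_len + 500 away from genes
    if (params$n_repeats > 0L && ng > 0L) {
      nr <- diff(floor(seq(0, params$n_repeats, length.out = params$n_chrom + 1)))[ci]
      gaps_lo <- c(1L, starts + lens)               # first base after each gene
      gaps_hi <- c(starts - 1L, L)                  # last base before next gene
      margin <- params$flank_len + 500L
      placed <- 0L; guard <- 0L
      occupied <- GenomicRanges::GRanges()
      while (placed < nr && guard < 1000L) {
        guard <- guard + 1L
        rl <- sample(seq(params$repeat_len_min, params$repeat_len_max), 1L)
        gi <- sample(length(gaps_lo), 1L)
        lo <- gaps_lo[gi] + margin
        hi <- gaps_hi[gi] - margin - rl
        if (hi <= lo) next
        r_start <- sample(lo:hi, 1L)
        cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(r_start, r_start + rl - 1L))
        if (length(occupied) &&
            any(IRanges::overlapsAny(cand + 500L, occupied))) next
        occupied <- c(occupied, cand)
        placed <- placed + 1L
        fam <- if (stats::runif(1) < params$cr1_fraction) "CR1" else
          sample(c("LINE-L2", "LTR-ERV", "SINE-MIR"), 1L)
        rep_rows[[length(rep_rows) + 1L]] <-
          data.frame(chrom = chrom, start = r_start, end = r_start + rl - 1L,
                     family = fam)
      }
      if (placed < nr)
        warning("placed only ", placed, " of ", nr, " repeats on ", chrom)
    }
    seq_chars[[chrom]] <- chars
  }

  df2gr <- function(rows, mcol = NULL) {
    if (length(rows) == 0L) {
      gr <- GenomicRanges::GRanges(seqlengths = chrom_lengths)
      for (m in mcol) S4Vectors::mcols(gr)[[m]] <- character(0)
      return(gr)
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                                 strand = if (!is.null(df$strand)) df$strand else "*",
                                 seqlengths = chrom_lengths)
    for (m in mcol) S4Vectors::mcols(gr)[[m]] <- df[[m]]
    gr
  }
  genes_gr <- df2gr(gene_rows, "gene_id")
  exons_gr <- df2gr(exon_rows, "gene_id")
  exl <- GenomicRanges::split(exons_gr, exons_gr$gene_id)[genes_gr$gene_id]
  exl <- methods::as(lapply(exl, function(g) { S4Vectors::mcols(g) <- NULL; g }),
                     "GRangesList")
  gm <- gene_models(genes_gr, exl)
  cgis_gr <- df2gr(cgi_rows, "m")
  reps_gr <- df2gr(rep_rows, "family")

  sequences <- Biostrings::DNAStringSet(vapply(seq_chars, paste0, "", collapse = ""))
  GenomeInfoDb::seqlengths(sequences) <- chrom_lengths

  regions <- landscape_regions(gm, reps_gr, cgis_gr, params, chrom_lengths)
  landscape <- landscape_from_regions(seq_chars, regions, params, chrom_lengths)
  domains <- GenomicRanges::reduce(regions[regions$m >= params$m_high])

  truth <- structure(list(genes = gm, repeats = reps_gr, planted_cgis = cgis_gr,
                          methylated_domains = domains, regions = regions,
                          chrom_lengths = chrom_lengths, params = params),
                     class = "synthetic_truth")
  list(sequences = sequences, truth = truth, landscape = landscape)
}

# Precedence-resolved disjoint region map with a methylation level per piece:
# CGI > repeat > flank > body > intergenic.
landscape_regions <- function(gm, repeats, cgis, params, chrom_lengths) {
  genome <- GenomicRanges::GRanges(names(chrom_lengths),
                                   IRanges::IRanges(1L, chrom_lengths),
                                   seqlengths = chrom_lengths)
  layer <- function(gr, m, above) {
    gr <- GenomicRanges::reduce(granges(gr), ignore.strand = TRUE)
    BiocGenerics::strand(gr) <- "*"
    if (length(above)) gr <- GenomicRanges::setdiff(gr, above, ignore.strand = TRUE)
    if (length(gr)) gr$m <- m
    gr
  }
  taken <- GenomicRanges::GRanges()
  out <- GenomicRanges::GRanges()
  add <- function(gr, m) {
    piece <- layer(gr, m, taken)
    taken <<- GenomicRanges::reduce(c(taken, granges(piece)), ignore.strand = TRUE)
    out <<- c(out, piece)
  }
  if (length(cgis)) {
    # each island (plus its shores) carries its own level: most are
    # unmethylated (m_cgi), a fraction hypermethylated (m_cgi_meth)
    shored <- GenomicRanges::trim(suppressWarnings(cgis + params$cgi_shore_len))
    for (v in sort(unique(cgis$m)))
      add(shored[cgis$m == v], v)
  }
  if (length(repeats)) add(repeats, params$m_repeat)
  if (length(gm$genes)) {
    flanks <- c(gene_flank5(gm, params$flank_len), gene_flank3(gm, params$flank_len))
    add(flanks, params$m_flank)
    add(gm$genes, params$m_body)
  }
  add(genome, params$m_intergenic)
  GenomeInfoDb::seqlevels(out) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(out) <- chrom_lengths
  GenomicRanges::sort(out)
}

landscape_from_regions <- function(seq_chars, regions, params, chrom_lengths) {
  parts <- lapply(names(seq_chars), function(chrom) {
    pos <- cpg_positions(seq_chars[[chrom]])
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                                 seqlengths = chrom_lengths)
    hit <- GenomicRanges::findOverlaps(gr, regions, select = "first")
    gr$m <- regions$m[hit]
    gr
  })
  do.call(c, parts)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$genes$genes), "genes,",
      length(x$planted_cgis), "planted CGIs,", length(x$repeats), "repeats,",
      length(x$methylated_domains), "methylated domains over",
      sum(as.numeric(x$chrom_lengths)), "bp\n")
  invisible(x)
}

#' Simulate MeDIP-seq tags from a methylation landscape
#'
#' Models the anti-5-methylcytosine pulldown as weighted fragment sampling:
#' a candidate fragment has uniform start, length uniform on
#' \[`frag_len_min`, `frag_len_max`\], and sampling weight equal to the
#' summed methylation of the CpGs it covers plus
#' `epsilon * fragment_len / 100` (the unmethylated carry-over baseline).
#' Fragments are drawn by exact rejection sampling against the maximum
#' fragment weight; the sequenced tag is the 5'-most `read_len` bases of a
#' uniformly chosen fragment end (strand).
#'
#' @param sequences `DNAStringSet` genome (used for chromosome lengths).
#' @param landscape Width-1 `GRanges` of CpG methylation levels (`m`).
#' @param params A [sim_params] object.
#' @param n_reads,seed Optional overrides of `params$n_medip_reads` and the
#'   medip substream seed (pass a different `seed` for an independent
#'   technical replicate of the same landscape).
#' @return `GRanges` of tag spans (width `read_len`, stranded), sorted by
#'   position.
#' @export
simulate_medip <- function(sequences, landscape, params = sim_params(),
                           n_reads = params$n_medip_reads,
                           seed = derive_seed(params$seed, "medip")) {
  stopifnot(n_reads > 0)
  set.seed(seed)
  chrom_lengths <- GenomeInfoDb::seqlengths(sequences)
  chroms <- names(chrom_lengths)
  # per-chromosome base-level cumulative methylation mass
  cums <- lapply(chroms, function(chrom) {
    m <- numeric(chrom_lengths[[chrom]])
    on_c <- landscape[GenomeInfoDb::seqnames(landscape) == chrom]
    m[BiocGenerics::start(on_c)] <- on_c$m
    c(0, cumsum(m))
  })
  names(cums) <- chroms
  frag_weight <- function(chrom, start, len) {
    cu <- cums[[chrom]]
    (cu[pmin(start + len, length(cu))] - cu[start]) + params$epsilon * len / 100
  }
  # upper bound on any fragment weight, per chromosome
  wmax <- max(vapply(chroms, function(chrom) {
    cu <- cums[[chrom]]
    L <- length(cu) - 1L
    w <- params$frag_len_max
    if (L <= w) return(cu[L + 1L])
    max(cu[(w + 1L):(L + 1L)] - cu[1L:(L + 1L - w)])
  }, 0)) + params$epsilon * params$frag_len_max / 100
  if (wmax <= 0) stop("no sampleable fragments: landscape is all zero and epsilon = 0")

  total_len <- sum(as.numeric(chrom_lengths))
  out_chrom <- character(0); out_start <- integer(0)
  out_len <- integer(0); out_strand <- character(0)
  while (length(out_start) < n_reads) {
    batch <- max(10000L, as.integer(2.5 * (n_reads - length(out_start))))
    ci <- sample(seq_along(chroms), batch, replace = TRUE,
                 prob = as.numeric(chrom_lengths))
    len <- sample(seq(params$frag_len_min, params$frag_len_max), batch, replace = TRUE)
    start <- integer(batch)
    for (j in seq_along(chroms)) {
      idx <- which(ci == j)
      if (length(idx))
        start[idx] <- sample.int(chrom_lengths[[j]] - params$frag_len_max, length(idx),
                                 replace = TRUE)
    }
    w <- numeric(batch)
    for (j in seq_along(chroms)) {
      idx <- which(ci == j)
      if (length(idx)) w[idx] <- frag_weight(chroms[j], start[idx], len[idx])
    }
    keep <- stats::runif(batch) < w / wmax
    out_chrom <- c(out_chrom, chroms[ci[keep]])
    out_start <- c(out_start, start[keep])
    out_len <- c(out_len, len[keep])
    out_strand <- c(out_strand, sample(c("+", "-"), sum(keep), replace = TRUE))
  }
  keep <- seq_len(n_reads)
  chrom <- out_chrom[keep]; fs <- out_start[keep]
  fl <- out_len[keep]; st <- out_strand[keep]
  read_start <- ifelse(st == "+", fs, fs + fl - params$read_len)
  tags <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(read_start, width = params$read_len),
                                 strand = st, seqlengths = chrom_lengths)
  GenomicRanges::sort(tags, ignore.strand = TRUE)
}

#' Simulate 3'-tag RNA-seq counts coupled to promoter methylation
#'
#' Base expression `e_g` is log-normal; the sampling rate of gene g is
#' proportional to `e_g * exp(-beta * P_g)` where `P_g` is the mean
#' landscape methylation over CpGs in the proximal promoter (TSS +/- 2 kb;
#' 0 when the promoter has no CpG). Tag counts are one multinomial draw of
#' `n_rna_tags` tags over genes.
#'
#' @param genes A [gene_models] object.
#' @param landscape Width-1 `GRanges` of CpG methylation levels.
#' @param params A [sim_params] object.
#' @param seed Substream seed override.
#' @return Named integer vector of raw tag counts (sums to `n_rna_tags`).
#' @export
simulate_rnaseq <- function(genes, landscape, params = sim_params(),
                            seed = derive_seed(params$seed, "rna")) {
  if (length(genes$genes) == 0L) stop("no genes to simulate expression for")
  set.seed(seed)
  prom <- GenomicRanges::promoters(genes$genes, params$flank_len, params$flank_len)
  P <- promoter_mean_methylation(prom, landscape)
  e <- stats::rlnorm(length(prom), params$expr_meanlog, params$expr_sdlog)
  rate <- e * exp(-params$beta * P)
  counts <- as.vector(stats::rmultinom(1L, params$n_rna_tags, rate / sum(rate)))
  stats::setNames(counts, genes$genes$gene_id)
}

# Mean landscape level over the CpGs falling in each query range (0 if none).
promoter_mean_methylation <- function(ranges, landscape) {
  hits <- GenomicRanges::findOverlaps(ranges, landscape, ignore.strand = TRUE)
  s <- tapply(landscape$m[S4Vectors::subjectHits(hits)],
              factor(S4Vectors::queryHits(hits), levels = seq_along(ranges)),
              mean, default = 0)
  as.numeric(ifelse(is.na(s), 0, s))
}

#' Simulate bisulfite clone sequences over a region
#'
#' Per clone, each CpG cytosine is retained as C with probability equal to
#' its landscape level (else read as T); each non-CpG cytosine is converted
#' to T with probability `conversion_rate`. Clones are emitted on the +
#' strand with no indels, so they align to the reference by position.
#'
#' @param sequences `DNAStringSet` genome.
#' @param landscape Width-1 `GRanges` of CpG methylation levels.
#' @param region Single-range `GRanges` to clone.
#' @param params A [sim_params] object.
#' @param seed Substream seed override.
#' @return `DNAStringSet` of `n_clones` clone sequences named
#'   `clone_1..clone_n`.
#' @export
simulate_bisulfite <- function(sequences, landscape, region,
                               params = sim_params(),
                               seed = derive_seed(params$seed, "bis")) {
  stopifnot(length(region) == 1L, params$n_clones >= 1L)
  chrom <- as.character(GenomeInfoDb::seqnames(region))
  L <- GenomeInfoDb::seqlengths(sequences)[[chrom]]
  if (BiocGenerics::start(region) < 1L || BiocGenerics::end(region) > L)
    stop("region outside the sequence")
  set.seed(seed)
  ref <- strsplit(as.character(sequences[[chrom]]), "")[[1]][
    BiocGenerics::start(region):BiocGenerics::end(region)]
  in_region <- landscape[GenomeInfoDb::seqnames(landscape) == chrom &
                           BiocGenerics::start(landscape) >= BiocGenerics::start(region) &
                           BiocGenerics::start(landscape) <= BiocGenerics::end(region)]
  cpg_rel <- BiocGenerics::start(in_region) - BiocGenerics::start(region) + 1L
  m <- in_region$m
  c_pos <- which(ref == "C")
  if (length(c_pos) == 0L)
    warning("region contains no cytosine; downstream calls will be empty")
  noncpg_c <- setdiff(c_pos, cpg_rel)
  clones <- vapply(seq_len(params$n_clones), function(i) {
    cl <- ref
    if (length(cpg_rel)) {
      toT <- stats::runif(length(cpg_rel)) >= m
      cl[cpg_rel[toT]] <- "T"
    }
    if (length(noncpg_c)) {
      conv <- stats::runif(length(noncpg_c)) < params$conversion_rate
      cl[noncpg_c[conv]] <- "T"
    }
    paste0(cl, collapse = "")
  }, "")
  names(clones) <- paste0("clone_", seq_len(params$n_clones))
  Biostrings::DNAStringSet(clones)
}

#' Synthetic flat GO annotation for the toy genome
#'
#' Assigns each gene to a random subset of invented GO-like terms so that
#' enrichment machinery can be exercised end-to-end on synthetic data. The
#' annotation is random and carries no biology.
#'
#' @param gene_ids Character vector of gene ids (the universe).
#' @param n_terms Number of terms.
#' @param mean_terms_per_gene Average number of terms per gene.
#' @param seed Substream seed.
#' @return Annotation list as from [read_go_annotation()].
#' @export
simulate_go_annotation <- function(gene_ids, n_terms = 10L,
                                   mean_terms_per_gene = 2,
                                   seed = 1L) {
  set.seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  memb <- lapply(gene_ids, function(g) {
    k <- min(n_terms, stats::rpois(1, mean_terms_per_gene))
    sample(terms, k)
  })
  df <- data.frame(term = unlist(memb),
                   gene_id = rep(gene_ids, lengths(memb)))
  term_list <- lapply(split(df$gene_id, df$term), unique)
  list(terms = term_list, universe = sort(gene_ids))
}
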