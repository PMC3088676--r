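#' Pipeline configuration
#'
#' Bundles every stage's parameters behind one object. The master seed
#' lives in `sim$seed`; each stage derives its own substream from it.
#'
#' @param sim A [sim_params] object (the synthetic study conditions).
#' @param caller A [caller_params] object.
#' @param cgi_window_len,cgi_gc_min,cgi_oe_min CpG-island scanner options.
#' @param flank_len Flank length (bp) shared by the annotation categories,
#'   promoter definitions and metagene flanks.
#' @param go_iters,go_alpha,go_n_terms Resampled-enrichment options.
#' @param n_validation_regions Bisulfite validation regions (half peak,
#'   half non-peak).
#' @param validation_region_len Length of each validation region (bp).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(), caller = caller_params(),
                            cgi_window_len = 200L, cgi_gc_min = 0.5,
                            cgi_oe_min = 0.6, flank_len = 2000L,
                            go_iters = 199L, go_alpha = 0.05, go_n_terms = 10L,
                            n_validation_regions = 8L,
                            validation_region_len = 400L) {
  stopifnot(inherits(sim, "sim_params"), inherits(caller, "caller_params"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic methylome analysis
#'
#' Executes the stages in dependency order — `simulate`, `scan-cgi`,
#' `call-peaks`, `annotate`, `metagene`, `expression-corr`, `go-enrich`,
#' `bis-validate` — writing every intermediate in its standard text format
#' under `outdir`. A subset of stages can be run; later stages reload the
#' intermediates they need from `outdir`, so a subset run is valid
#' whenever its inputs were produced by an earlier run. Re-running with
#' the same configuration reproduces identical non-log outputs.
#'
#' @param config A [pipeline_config] object.
#' @param outdir Output directory (created if missing).
#' @param stages Character vector of stage names (default: all).
#' @param verbose Print per-stage progress to stderr?
#' @return Invisibly, the run manifest: a list with the seed, stage
#'   records (name, outputs, elapsed seconds) and headline results; also
#'   written to `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "medipr_run",
                         stages = pipeline_stages(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[medipr] ", ...)
  path <- function(f) file.path(outdir, f)
  state <- new.env(parent = emptyenv())
  results <- list()
  manifest <- list(seed = config$sim$seed, stages = list())

  # lazy accessors: in-memory object if the producing stage ran, else disk
  need <- function(key) {
    if (!is.null(state[[key]])) return(state[[key]])
    state[[key]] <- switch(key,
      sequences = read_fasta(path("genome.fa")),
      genes = read_gtf_genes(path("genes.gtf")),
      repeats = read_bed_intervals(path("repeats.bed")),
      landscape = read_landscape_tsv(path("landscape.tsv")),
      tags = read_bed_tags(path("medip_tags.bed"), config$sim$read_len),
      raw_counts = read_expression_tsv(path("expression.tsv")),
      go_annotation = read_go_annotation(path("go_annotation.tsv")),
      islands = read_bed_intervals(path("cgis.bed")),
      peaks = read_peaks_tsv(path("peaks.tsv")),
      chrom_lengths = {
        seqs <- need("sequences")
        stats::setNames(BiocGenerics::width(seqs), names(seqs))
      },
      stop("no provider for '", key, "'"))
    state[[key]]
  }
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    say("stage ", name)
    t0 <- proc.time()[["elapsed"]]
    outs <- tryCatch(fun(),
                     error = function(e) stop("stage '", name, "' failed: ",
                                              conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(name = name, outputs = outs,
                                     elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    invisible(NULL)
  }

  run_stage("simulate", function() {
    gen <- generate_genome(config$sim)
    state$sequences <- gen$sequences
    state$truth <- gen$truth
    state$landscape <- gen$landscape
    state$genes <- gen$truth$genes
    state$repeats <- gen$truth$repeats
    state$chrom_lengths <- gen$truth$chrom_lengths
    state$tags <- simulate_medip(gen$sequences, gen$landscape, config$sim)
    # gene-free genomes still simulate MeDIP; the gene-based stages fail
    # later with their own messages
    state$raw_counts <- if (length(gen$truth$genes$genes))
      simulate_rnaseq(gen$truth$genes, gen$landscape, config$sim)
    else stats::setNames(integer(0), character(0))
    state$go_annotation <- simulate_go_annotation(
      gen$truth$genes$genes$gene_id, n_terms = config$go_n_terms,
      seed = derive_seed(config$sim$seed, "go"))
    write_fasta(gen$sequences, path("genome.fa"))
    if (length(gen$truth$genes$genes)) write_gtf_genes(gen$truth$genes, path("genes.gtf"))
    write_bed_intervals(gen$truth$repeats, path("repeats.bed"))
    write_landscape_tsv(gen$landscape, path("landscape.tsv"))
    tg <- state$tags
    tg$name <- paste0("tag_", seq_along(tg))
    tg$score <- 0L
    rtracklayer::export(tg, path("medip_tags.bed"), format = "bed")
    write_expression_tsv(state$raw_counts, path("expression.tsv"))
    write_go_annotation(state$go_annotation, path("go_annotation.tsv"))
    c("genome.fa", "genes.gtf", "repeats.bed", "landscape.tsv",
      "medip_tags.bed", "expression.tsv", "go_annotation.tsv")
  })

  run_stage("scan-cgi", function() {
    islands <- scan_cpg_islands(need("sequences"), config$cgi_window_len,
                                config$cgi_gc_min, config$cgi_oe_min)
    state$islands <- islands
    write_bed_intervals(islands, path("cgis.bed"))
    utils::write.table(
      data.frame(chrom = as.character(GenomeInfoDb::seqnames(islands)),
                 start = BiocGenerics::start(islands),
                 end = BiocGenerics::end(islands),
                 gc_fraction = islands$gc_fraction,
                 obs_exp = islands$obs_exp, n_cpg = islands$n_cpg),
      path("cgis.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    results$n_cgis <<- length(islands)
    c("cgis.bed", "cgis.tsv")
  })

  run_stage("call-peaks", function() {
    peaks <- call_peaks(need("tags"), need("chrom_lengths"), config$caller)
    state$peaks <- peaks
    write_peaks_tsv(peaks, path("peaks.tsv"))
    write_bed_intervals(peaks, path("peaks.bed"))
    results$n_peaks <<- length(peaks)
    c("peaks.tsv", "peaks.bed")
  })

  run_stage("annotate", function() {
    genes <- need("genes"); peaks <- need("peaks")
    cgi_sum <- summarize_cgi_methylation(need("islands"), peaks, genes,
                                         config$flank_len)
    hmr_sum <- summarize_hmr_distribution(peaks, genes, config$flank_len)
    rep_frac <- repeat_tag_fraction(need("tags"), need("repeats"),
                                    config$caller$extension_length)
    split <- classify_methylated_cgis(need("islands"), peaks)
    write_bed_intervals(split$methylated, path("cgis_methylated.bed"))
    write_bed_intervals(split$unmethylated, path("cgis_unmethylated.bed"))
    utils::write.table(as.data.frame(cgi_sum), path("cgi_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(hmr_sum), path("hmr_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(family = c("all", names(rep_frac$per_family)),
                 fraction = c(rep_frac$overall, as.numeric(rep_frac$per_family))),
      path("repeat_fractions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    results$cgi_methylated_percent <<- cgi_sum$methylated_percent
    results$repeat_tag_fraction <<- rep_frac$overall
    c("cgis_methylated.bed", "cgis_unmethylated.bed", "cgi_summary.tsv",
      "hmr_summary.tsv", "repeat_fractions.tsv")
  })

  run_stage("metagene", function() {
    track <- build_coverage(need("tags"), need("chrom_lengths"),
                            config$caller$extension_length)
    write_bedgraph(track, path("coverage.bedgraph"))
    prof <- compute_metagene(track, need("genes"), config$flank_len)
    state$metagene <- prof
    write_metagene_tsv(prof, path("metagene.tsv"))
    results$metagene_body_flank_ratio <<-
      mean(prof$values[prof$segment == "body"]) /
      mean(prof$values[c(1:10, 51:60)])
    c("coverage.bedgraph", "metagene.tsv")
  })

  run_stage("expression-corr", function() {
    expr <- normalize_expression(need("raw_counts"))
    scores <- promoter_methylation_score(need("genes"), need("peaks"),
                                         config$flank_len)
    dc <- decile_correlation(expr, scores)
    state$decile <- dc
    utils::write.table(dc$table, path("decile_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sprintf("pearson_r\t%.6f\np_value\t%.6g", dc$r, dc$p_value),
               path("decile_correlation.tsv"))
    results$decile_r <<- dc$r
    c("decile_table.tsv", "decile_correlation.tsv")
  })

  run_stage("go-enrich", function() {
    selected <- select_methylated_genes(need("genes"), need("peaks"),
                                        config$flank_len)
    enr <- resampled_enrichment(selected, need("go_annotation"),
                                iters = config$go_iters,
                                seed = derive_seed(config$sim$seed, "go") + 1L)
    enr$significant <- enr$fisher_p < config$go_alpha
    utils::write.table(enr, path("go_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$n_methylated_genes <<- length(selected)
    "go_enrichment.tsv"
  })

  run_stage("bis-validate", function() {
    peaks <- need("peaks"); landscape <- need("landscape")
    regions <- pick_validation_regions(peaks, need("genes"),
                                       need("chrom_lengths"),
                                       n = config$n_validation_regions,
                                       len = config$validation_region_len)
    calls <- list()
    for (i in seq_along(regions)) {
      clones <- simulate_bisulfite(need("sequences"), landscape, regions[i],
                                   config$sim,
                                   seed = derive_seed(config$sim$seed, "bis") + i)
      write_fasta(clones, path(sprintf("clones_%s.fa", regions$region_id[i])))
      ref <- Biostrings::subseq(need("sequences")[[
        as.character(GenomeInfoDb::seqnames(regions))[i]]],
        BiocGenerics::start(regions)[i], BiocGenerics::end(regions)[i])
      calls[[regions$region_id[i]]] <- call_methylation(ref, clones)
    }
    rep <- concordance(peaks, calls, regions, n_clones = config$sim$n_clones)
    utils::write.table(as.data.frame(rep), path("bis_concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$bis_peak_mean <<-
      mean(rep$mean_fraction[rep$region_kind == "peak"], na.rm = TRUE)
    results$bis_nonpeak_mean <<-
      mean(rep$mean_fraction[rep$region_kind == "non_peak"], na.rm = TRUE)
    c("bis_concordance.tsv",
      sprintf("clones_%s.fa", regions$region_id))
  })

  manifest$results <- results
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname run_pipeline
#' @export
pipeline_stages <- function() {
  c("simulate", "scan-cgi", "call-peaks", "annotate", "metagene",
    "expression-corr", "go-enrich", "bis-validate")
}

# Validation regions for bisulfite concordance: half centred on the
# strongest peaks, half in peak-free promoter flanks (hypomethylated by
# construction in the synthetic landscape).
pick_validation_regions <- function(peaks, genes, chrom_lengths,
                                    n = 8L, len = 400L) {
  n_peak <- n %/% 2L
  n_non <- n - n_peak
  if (length(peaks) < n_peak) stop("not enough peaks for validation regions")
  best <- peaks[order(peaks$p_value, -peaks$tag_count)][seq_len(n_peak)]
  peak_regions <- GenomicRanges::resize(granges(best), width = len, fix = "center")
  flanks <- granges(gene_flank5(genes))
  BiocGenerics::strand(flanks) <- "*"
  cand <- GenomicRanges::resize(flanks, width = len, fix = "center")
  cand <- cand[!IRanges::overlapsAny(cand + len, peaks, ignore.strand = TRUE)]
  if (length(cand) < n_non) stop("not enough peak-free regions for validation")
  non_regions <- cand[seq_len(n_non)]
  regions <- c(peak_regions, non_regions)
  GenomeInfoDb::seqlevels(regions) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(regions) <- chrom_lengths
  regions <- GenomicRanges::trim(regions)
  regions$region_id <- c(sprintf("peak_%d", seq_len(n_peak)),
                         sprintf("nonpeak_%d", seq_len(n_non)))
  regions
}
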