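#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases the
#' sequences (the DNA encoding folds case) and keeps `N` characters.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A `DNAStringSet` named by the FASTA headers (first word).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read aligned MeDIP tags from a BED6 file
#'
#' Each record is one uniquely aligned sequencing tag; the strand column
#' orients the tag so that its 5' end is the BED start for `+` records and
#' the last covered base for `-` records (standard tag-directionality
#' convention). Fragment extension for coverage and peak calling proceeds
#' downstream of that 5' end.
#'
#' @param path Path to a BED6 file.
#' @param read_len Expected tag length in bp (default 35); records of a
#'   different width are accepted but trigger a warning.
#' @return A `GRanges` of tag spans with strand set.
#' @export
read_bed_tags <- function(path, read_len = 35L) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L)
    return(GenomicRanges::GRanges())
  tags <- rtracklayer::import(path, format = "bed")
  st <- as.character(BiocGenerics::strand(tags))
  if (any(!st %in% c("+", "-")))
    stop("tag BED records must have strand '+' or '-'")
  if (any(BiocGenerics::width(tags) != read_len))
    warning("some tags are not ", read_len, " bp wide")
  tags
}

#' Extend tags to fragment length
#'
#' Resizes each tag to `extension_length` bases downstream of its
#' strand-aware 5' end (the sonicated fragment the tag represents), clipped
#' at chromosome bounds when lengths are known.
#'
#' @param tags `GRanges` of tags.
#' @param extension_length Fragment length in bp; must be at least the tag
#'   width.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clip extended fragments.
#' @return A `GRanges` of extended fragments.
#' @export
extend_tags <- function(tags, extension_length = 275L, chrom_lengths = NULL) {
  if (length(tags) && extension_length < max(BiocGenerics::width(tags)))
    stop("extension_length must be >= the tag length")
  if (!is.null(chrom_lengths)) {
    missing <- setdiff(GenomeInfoDb::seqlevels(tags),
                       names(chrom_lengths))
    if (length(missing))
      stop("tags on unknown chromosome(s): ", paste(missing, collapse = ", "))
    GenomeInfoDb::seqlevels(tags) <- names(chrom_lengths)
    GenomeInfoDb::seqlengths(tags) <- chrom_lengths
  }
  ext <- suppressWarnings(
    GenomicRanges::resize(tags, width = extension_length, fix = "start"))
  GenomicRanges::trim(ext)
}

#' Build a genome-wide coverage track from tags
#'
#' Each tag contributes +1 depth over `extension_length` bases downstream
#' of its 5' end (strand-aware), clipped at chromosome ends. Tags on
#' chromosomes absent from `chrom_lengths` are a hard error: silently
#' dropping them would corrupt the library size.
#'
#' @param tags `GRanges` of tags.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param extension_length Fragment extension in bp (default 275, the
#'   midpoint of a 200-350 bp sonication range).
#' @return A `coverage_track`: list with `depth` (an `RleList`, one run-
#'   length-encoded depth vector per chromosome), `library_size` (number of
#'   tags) and `extension_length`.
#' @export
build_coverage <- function(tags, chrom_lengths, extension_length = 275L) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  ext <- extend_tags(tags, extension_length, chrom_lengths)
  depth <- GenomicRanges::coverage(ext, width = chrom_lengths)
  structure(list(depth = depth, library_size = length(tags),
                 extension_length = extension_length),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$library_size, "tags extended to",
      x$extension_length, "bp over",
      length(x$depth), "chromosome(s)\n")
  invisible(x)
}

#' Write / read a coverage track as bedGraph
#'
#' Zero-depth runs are omitted from the file, per bedGraph convention.
#' `read_bedgraph()` reconstructs the depth `RleList` (library size and
#' extension length are not stored in the format and must be re-supplied
#' if needed downstream).
#'
#' @param track A `coverage_track` (or bare `RleList`).
#' @param path File path.
#' @param chrom_lengths Named lengths used to rebuild the `RleList` on read.
#' @return `read_bedgraph()` returns an `RleList`.
#' @export
write_bedgraph <- function(track, path) {
  depth <- if (inherits(track, "coverage_track")) track$depth else track
  gr <- GenomicRanges::GRanges(depth)
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = gr$score, width = chrom_lengths)
}

#' Write genomic intervals to BED
#'
#' Intervals with a `p_value` column (peaks) get a BED score of
#' `-10 * log10(p)` capped at 1000; intervals with a numeric `score`
#' column keep it; otherwise the score is 0. A `name`/`gene_id`/`family`
#' column, when present, fills the BED name field.
#'
#' @param items `GRanges` to write.
#' @param path Output path.
#' @export
write_bed_intervals <- function(items, path) {
  gr <- granges(items)
  nm <- if (!is.null(items$name)) items$name
    else if (!is.null(items$gene_id)) items$gene_id
    else if (!is.null(items$family)) items$family
    else paste0("region_", seq_along(items))
  if (length(items)) gr$name <- nm
  gr$score <- if (!is.null(items$p_value)) {
    pmin(round(-10 * log10(pmax(items$p_value, 1e-100))), 1000)
  } else if (!is.null(items$score)) items$score else rep(0, length(items))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

granges <- function(x) GenomicRanges::granges(x)

#' @rdname write_bed_intervals
#' @export
read_bed_intervals <- function(path) {
  if (file.size(path) == 0L) return(GenomicRanges::GRanges())
  rtracklayer::import(path, format = "bed")
}

#' Read gene models from a GTF file
#'
#' Accepts GTF with `exon` features carrying `gene_id` attributes (and
#' optionally explicit `gene` features for the spans). GTF's 1-based closed
#' coordinates map directly onto `GRanges`. Exons are grouped per gene and
#' validated against the gene span.
#'
#' @param path Path to a GTF file.
#' @return A [gene_models] object.
#' @export
read_gtf_genes <- function(path) {
  gff <- rtracklayer::import(path, format = "gtf")
  if (is.null(gff$gene_id)) stop("GTF lacks gene_id attributes: ", path)
  ex <- gff[gff$type == "exon"]
  if (length(ex) == 0L) stop("GTF has no exon features: ", path)
  ex <- GenomicRanges::sort(ex, ignore.strand = TRUE)
  exl <- GenomicRanges::split(granges(ex), ex$gene_id)
  gene_feats <- gff[gff$type == "gene"]
  if (length(gene_feats)) {
    gene_feats <- gene_feats[match(names(exl), gene_feats$gene_id)]
    genes <- granges(gene_feats)
    genes$gene_id <- gene_feats$gene_id
  } else {
    genes <- unlist(range(exl))
    genes$gene_id <- names(genes)
    names(genes) <- NULL
  }
  gene_models(genes, exl)
}

#' Write gene models to GTF
#'
#' Emits one `gene` and per-exon `exon` features with `gene_id` attributes.
#'
#' @param gm A [gene_models] object.
#' @param path Output path.
#' @export
write_gtf_genes <- function(gm, path) {
  genes <- granges(gm$genes)
  genes$source <- "medipr"
  genes$type <- "gene"
  genes$gene_id <- gm$genes$gene_id
  ex <- unlist(gm$exons)
  exg <- granges(ex)
  exg$source <- "medipr"
  exg$type <- "exon"
  exg$gene_id <- names(ex)
  names(exg) <- NULL
  all <- c(genes, exg)
  all <- all[order(as.character(GenomeInfoDb::seqnames(all)),
                   BiocGenerics::start(all), all$type != "gene")]
  rtracklayer::export(all, path, format = "gtf")
  invisible(path)
}

#' Read / write a per-CpG methylation landscape as TSV
#'
#' Plain-text ground-truth format: columns `chrom`, `pos` (1-based position
#' of the CpG cytosine on the + strand) and `m` (methylation level in
#' \[0,1\]).
#'
#' @param landscape Width-1 `GRanges` with an `m` metadata column.
#' @param path File path.
#' @return `read_landscape_tsv()` returns the landscape `GRanges`.
#' @export
write_landscape_tsv <- function(landscape, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(landscape)),
                   pos = BiocGenerics::start(landscape),
                   m = landscape$m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_tsv
#' @export
read_landscape_tsv <- function(path) {
  df <- utils::read.delim(path)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L))
  gr$m <- df$m
  gr
}

#' Read / write per-gene expression tag counts as TSV
#'
#' Columns `gene_id` and `raw_tags`.
#'
#' @param counts Named numeric vector of raw tag counts.
#' @param path File path.
#' @return `read_expression_tsv()` returns a named numeric vector.
#' @export
write_expression_tsv <- function(counts, path) {
  utils::write.table(data.frame(gene_id = names(counts), raw_tags = as.integer(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(df$raw_tags, df$gene_id)
}

#' Read a flattened GO annotation table
#'
#' Two tab-separated columns, `term` and `gene_id`, one row per
#' (term, gene) pair. The universe is the set of all annotated genes.
#'
#' @param path File path.
#' @return A list with `terms` (named list term -> character vector of
#'   gene ids) and `universe` (character vector).
#' @export
read_go_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("term", "gene_id") %in% names(df)))
    stop("GO annotation TSV needs columns 'term' and 'gene_id'")
  terms <- lapply(split(df$gene_id, df$term), unique)
  list(terms = terms, universe = sort(unique(df$gene_id)))
}

#' @rdname read_go_annotation
#' @param annotation List as returned by `read_go_annotation()`.
#' @export
write_go_annotation <- function(annotation, path) {
  df <- data.frame(term = rep(names(annotation$terms), lengths(annotation$terms)),
                   gene_id = unlist(annotation$terms, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
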