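#' Read and write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' which is what the simulator and callers work with.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED files are 0-based half-open on disk; in memory the package uses
#' 1-based closed coordinates, so `start` gains 1 on reading and loses 1 on
#' writing.  Name and score columns are carried when present.
#'
#' @param path File path.
#' @return `read_bed`: data frame `chrom`, `start`, `end` (1-based closed)
#'   and, when present, `name` and `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = IRanges::start(gr), end = IRanges::end(gr),
                    stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) out$name <- md$name
  if (!is.null(md$score)) out$score <- md$score
  out
}

#' @rdname read_bed
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based
#'   closed) and optional `name`, `score`.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  if (!is.null(intervals$name)) S4Vectors::mcols(gr)$name <- intervals$name
  if (!is.null(intervals$score)) S4Vectors::mcols(gr)$score <- intervals$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read and write GFF3 annotation
#'
#' @param path File path.
#' @return `read_gff3`: data frame `chrom`, `source`, `type`, `start`,
#'   `end` (1-based closed), `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             source = as.character(S4Vectors::mcols(gr)$source),
             type = as.character(S4Vectors::mcols(gr)$type),
             start = IRanges::start(gr), end = IRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_gff3
#' @param features Data frame with `chrom`, `type`, `start`, `end` and
#'   optional `source`, `strand`.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start, features$end),
    strand = if (is.null(features$strand)) "*" else features$strand)
  S4Vectors::mcols(gr)$source <- if (is.null(features$source)) "phsdup" else
    features$source
  S4Vectors::mcols(gr)$type <- features$type
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write and read PHS records as minimal single-sample VCF
#'
#' One record per PHS with `allele1` as REF and `allele2` as ALT, genotype
#' 0/1 (the pseudoheterozygous signal), allele support in `AD` and total
#' depth in `DP`.  The subset of VCF written here is deliberately tiny and
#' fixed; files produced by `write_phs_vcf()` are standard VCF 4.2 readable
#' by any compliant parser.
#'
#' @param phs Data frame of PHS records from [filter_phs()].
#' @param path Output path.
#' @param sample_name Sample column name; defaults to the genome id.
#' @export
write_phs_vcf <- function(phs, path, sample_name = NULL) {
  if (is.null(sample_name))
    sample_name <- if (nrow(phs)) phs$genome_id[1] else "sample"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=phsdup",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  if (nrow(phs)) {
    writeLines(paste(phs$chrom, phs$pos, ".", phs$allele1, phs$allele2,
                     ".", "PASS", paste0("DP=", phs$total_depth), "GT:AD",
                     paste0("0/1:", phs$support1, ",", phs$support2),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_phs_vcf
#' @return `read_phs_vcf`: data frame with the [filter_phs()] columns.
#' @export
read_phs_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (length(body) == 0L || !startsWith(body[1], "#CHROM"))
    stop("missing #CHROM header line in ", path, call. = FALSE)
  header <- strsplit(sub("^#", "", body[1]), "\t", fixed = TRUE)[[1]]
  sample_name <- header[10]
  body <- body[-1]
  proto <- data.frame(genome_id = character(), chrom = character(),
                      pos = integer(), allele1 = character(),
                      allele2 = character(), support1 = integer(),
                      support2 = integer(), total_depth = integer(),
                      stringsAsFactors = FALSE)
  if (length(body) == 0L) return(proto)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 10L)
  if (length(bad))
    stop(sprintf("malformed VCF record at line %d",
                 which(!startsWith(lines, "##"))[1] + bad[1]), call. = FALSE)
  m <- do.call(rbind, parts)
  ad <- strsplit(sub("^[^:]*:", "", m[, 10]), ",", fixed = TRUE)
  data.frame(
    genome_id = sample_name,
    chrom = m[, 1], pos = as.integer(m[, 2]),
    allele1 = m[, 4], allele2 = m[, 5],
    support1 = as.integer(vapply(ad, `[`, "", 1L)),
    support2 = as.integer(vapply(ad, `[`, "", 2L)),
    total_depth = as.integer(sub("^DP=", "", m[, 8])),
    stringsAsFactors = FALSE
  )
}

#' Read and write tab-separated track tables
#'
#' Plain TSV with a header line; a `.gz` suffix writes/reads through a gzip
#' connection.  Used for the pileup, split-read, depth, truth and catalog
#' tables, whose columns are documented at their producing functions.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @return `read_tsv_track`: data frame.
#' @export
read_tsv_track <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_track
#' @param x Data frame to write.
#' @export
write_tsv_track <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth set to BED and TSV
#'
#' The event table becomes a BED file (name = event id, score = copy
#' number, i.e. 2 for these single-copy-gain events) and the divergent
#' sites a TSV table.
#'
#' @param sim A `"phs_sim"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed <- file.path(dir, "truth_events.bed")
  tsv <- file.path(dir, "truth_divergent_sites.tsv")
  ev <- sim$events
  write_bed(data.frame(chrom = "ref", start = ev$start, end = ev$end,
                       name = paste0("dup", ev$event_id),
                       score = 2L, stringsAsFactors = FALSE), bed)
  write_tsv_track(sim$div_sites, tsv)
  invisible(c(bed, tsv))
}
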