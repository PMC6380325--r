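#' Build site masks for PHS filtering
#'
#' Three classes of positions are masked before PHS are accepted:
#' homopolymer runs of at least `homopolymer_min` identical bases; repeat
#' positions, defined as every start position of a `k`-mer that occurs more
#' than once in the reference (an exact-match stand-in for multi-mapping
#' under remapping); and qualifying indels (genotype quality > 30 supported
#' by > 5 reads) extended by `indel_flank` bp on both sides.
#'
#' @param reference Reference sequence (single character string).
#' @param indels Optional data frame of indel records with columns `pos`,
#'   `length`, `genotype_quality`, `supporting_reads`.
#' @param k Word size for exact repeat detection (bp).
#' @param homopolymer_min Minimum run length masked (bp).
#' @param indel_flank Flank added to each qualifying indel (bp).
#' @param min_gq,min_reads Thresholds a candidate indel must exceed
#'   (strictly) to be masked.
#' @return A list of class `"site_masks"` with `IRanges` elements
#'   `homopolymer`, `repeats`, `indel`, plus the reference length.
#' @examples
#' m <- build_masks(paste0(strrep("ACGT", 10), "AAAAAA", strrep("GT", 10)))
#' m$homopolymer
#' @export
build_masks <- function(reference, indels = NULL, k = 30L,
                        homopolymer_min = 6L, indel_flank = 5L,
                        min_gq = 30, min_reads = 5) {
  if (!is.character(reference) || length(reference) != 1L ||
      nchar(reference) == 0L)
    stop("`reference` must be a non-empty sequence string", call. = FALSE)
  L <- nchar(reference)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]

  r <- rle(chars)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  hp <- r$lengths >= homopolymer_min
  homopolymer <- IRanges::IRanges(run_start[hp], run_end[hp])

  repeats <- IRanges::IRanges()
  if (L >= k) {
    kmers <- substring(reference, seq_len(L - k + 1L), seq(k, L))
    multi <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
    if (any(multi)) {
      st <- which(multi)
      repeats <- IRanges::reduce(IRanges::IRanges(st, st))
    }
  }

  indel <- IRanges::IRanges()
  if (!is.null(indels) && nrow(indels)) {
    if (any(indels$length == 0))
      stop("indel records must have nonzero `length`", call. = FALSE)
    keep <- indels$genotype_quality > min_gq & indels$supporting_reads > min_reads
    if (any(keep)) {
      st <- pmax(1L, indels$pos[keep] - as.integer(indel_flank))
      en <- pmin(L, indels$pos[keep] + pmax(indels$length[keep], 0L) +
                   as.integer(indel_flank))
      indel <- IRanges::reduce(IRanges::IRanges(st, en))
    }
  }

  structure(list(homopolymer = homopolymer, repeats = repeats, indel = indel,
                 reference_length = L),
            class = "site_masks")
}

#' @export
print.site_masks <- function(x, ...) {
  cat(sprintf("Site masks over %d bp: %d homopolymer, %d repeat, %d indel intervals\n",
              x$reference_length, length(x$homopolymer), length(x$repeats),
              length(x$indel)))
  invisible(x)
}

# union of all mask intervals as one IRanges
.mask_union <- function(masks) {
  IRanges::reduce(c(masks$homopolymer, masks$repeats, masks$indel))
}

#' Call candidate biallelic sites from pileup observations
#'
#' A candidate is a pileup column with exactly two observed alleles, each
#' supported by at least one read.  Monomorphic columns are skipped; columns
#' with three or more alleles are discarded entirely (they signal error or
#' more than two collapsed copies).
#'
#' @param pileup Data frame of per-read observations with columns
#'   `genome_id`, `chrom`, `pos`, `base`, `qual`, `off5`, `off3` (offsets of
#'   the site from the read 5' and 3' ends in bp), sorted by position within
#'   each genome.
#' @return Data frame with one row per candidate: `genome_id`, `chrom`,
#'   `pos`, `allele1`, `allele2`, `n1`, `n2`, `total_depth`.  Alleles are
#'   ordered by read count (ties alphabetical).
#' @export
call_candidate_sites <- function(pileup) {
  proto <- data.frame(genome_id = character(), chrom = character(),
                      pos = integer(), allele1 = character(),
                      allele2 = character(), n1 = integer(), n2 = integer(),
                      total_depth = integer(), stringsAsFactors = FALSE)
  if (nrow(pileup) == 0L) return(proto)
  unsorted <- unlist(tapply(pileup$pos,
                            paste(pileup$genome_id, pileup$chrom),
                            is.unsorted), use.names = FALSE)
  if (any(unsorted))
    stop("pileup must be sorted by position within each genome", call. = FALSE)

  key <- paste(pileup$genome_id, pileup$chrom, pileup$pos, sep = "\r")
  fid <- factor(key, levels = unique(key))
  counts <- table(fid, factor(pileup$base, levels = DNA_BASES))
  counts <- matrix(as.integer(counts), nrow = nlevels(fid),
                   dimnames = dimnames(counts))
  n_alleles <- rowSums(counts > 0L)
  bi <- which(n_alleles == 2L)
  if (length(bi) == 0L) return(proto)

  cb <- counts[bi, , drop = FALSE]
  i1 <- max.col(cb, ties.method = "first")
  n1 <- cb[cbind(seq_along(bi), i1)]
  cb[cbind(seq_along(bi), i1)] <- -1L
  i2 <- max.col(cb, ties.method = "first")
  n2 <- counts[bi, , drop = FALSE][cbind(seq_along(bi), i2)]

  parts <- strsplit(levels(fid)[bi], "\r", fixed = TRUE)
  data.frame(
    genome_id = vapply(parts, `[`, "", 1L),
    chrom = vapply(parts, `[`, "", 2L),
    pos = as.integer(vapply(parts, `[`, "", 3L)),
    allele1 = DNA_BASES[i1], allele2 = DNA_BASES[i2],
    n1 = n1, n2 = n2,
    total_depth = as.integer(rowSums(counts[bi, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

#' Filter candidate sites into pseudoheterozygous site (PHS) records
#'
#' A candidate passes when (a) each allele has at least `min_support` reads
#' that both carry base quality >= `min_qual` and place the site at least
#' `min_end_dist` bp from both read ends, (b) the total read depth of the
#' column exceeds `min_depth`, and (c) the position falls in no mask
#' interval.  Only quality- and position-qualified observations count toward
#' allele support; the depth cutoff counts all reads.
#'
#' @param candidates Result of [call_candidate_sites()].
#' @param pileup The per-read observations the candidates were derived from.
#' @param masks A [build_masks()] result (or `NULL` to skip masking).
#' @param min_qual Minimum base quality of a supporting observation.
#' @param min_end_dist Minimum distance from both read ends (bp).
#' @param min_support Minimum qualified supporting reads per allele.
#' @param min_depth Total read depth must be strictly greater than this.
#' @param details Return every candidate annotated with the individual
#'   filter verdicts (`pass_support`, `pass_depth`, `masked`, `pass`)
#'   instead of the passing records only.
#' @return Data frame of PHS records: `genome_id`, `chrom`, `pos`, `allele1`,
#'   `allele2`, `support1`, `support2`, `total_depth`.
#' @export
filter_phs <- function(candidates, pileup, masks = NULL,
                       min_qual = 25L, min_end_dist = 15L,
                       min_support = 5L, min_depth = 8L, details = FALSE) {
  proto <- data.frame(genome_id = character(), chrom = character(),
                      pos = integer(), allele1 = character(),
                      allele2 = character(), support1 = integer(),
                      support2 = integer(), total_depth = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    if (details) {
      candidates$support1 <- integer(0); candidates$support2 <- integer(0)
      candidates$pass_support <- logical(0)
      candidates$pass_depth <- logical(0)
      candidates$masked <- logical(0); candidates$pass <- logical(0)
      return(candidates)
    }
    return(proto)
  }

  good <- pileup$qual >= min_qual & pileup$off5 >= min_end_dist &
    pileup$off3 >= min_end_dist
  gp <- pileup[good, , drop = FALSE]
  count_support <- function(allele) {
    if (nrow(gp) == 0L) return(integer(nrow(candidates)))
    key <- paste(gp$genome_id, gp$chrom, gp$pos, gp$base, sep = "\r")
    tab <- table(key)
    want <- paste(candidates$genome_id, candidates$chrom, candidates$pos,
                  allele, sep = "\r")
    out <- as.integer(tab[want])
    out[is.na(out)] <- 0L
    out
  }
  support1 <- count_support(candidates$allele1)
  support2 <- count_support(candidates$allele2)

  pass_support <- support1 >= min_support & support2 >= min_support
  pass_depth <- candidates$total_depth > min_depth
  masked <- if (!is.null(masks)) IRanges::overlapsAny(
    IRanges::IRanges(candidates$pos, candidates$pos), .mask_union(masks)) else
      rep(FALSE, nrow(candidates))
  keep <- pass_support & pass_depth & !masked
  if (details) {
    candidates$support1 <- support1
    candidates$support2 <- support2
    candidates$pass_support <- pass_support
    candidates$pass_depth <- pass_depth
    candidates$masked <- masked
    candidates$pass <- keep
    return(candidates)
  }
  out <- data.frame(
    genome_id = candidates$genome_id, chrom = candidates$chrom,
    pos = candidates$pos, allele1 = candidates$allele1,
    allele2 = candidates$allele2, support1 = support1, support2 = support2,
    total_depth = candidates$total_depth, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call PHS from pileup observations in one step
#'
#' Convenience wrapper running [call_candidate_sites()] then [filter_phs()].
#'
#' @inheritParams filter_phs
#' @inheritParams call_candidate_sites
#' @param ... Passed to [filter_phs()].
#' @return See [filter_phs()].
#' @export
call_phs <- function(pileup, masks = NULL, ...) {
  filter_phs(call_candidate_sites(pileup), pileup, masks, ...)
}
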