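#' Reconstruct the two copies of a PHS duplication
#'
#' The reference carries one collapsed copy of the duplicated segment; the
#' PHS inside a call are the positions where the two real copies differ.
#' Copy A takes `allele1` and copy B `allele2` at every PHS of the call;
#' everywhere else both copies equal the reference.  Allele phase is
#' arbitrary (and immaterial for substitution counting).
#'
#' @param call One call row (`chrom`, `start`, `end`) from [merge_phs()].
#' @param phs PHS records of the same genome (`pos`, `allele1`, `allele2`);
#'   every PHS inside the span is used, a PHS outside it is an error.
#' @param reference Reference sequence string.
#' @return A list of class `"paralog_pair"`: `start`, `end`, `copy_a`,
#'   `copy_b` (character strings of the span), `n_phs`.
#' @export
reconstruct_paralogs <- function(call, phs, reference) {
  st <- call$start; en <- call$end
  if (en > nchar(reference) || st < 1)
    stop("call span outside the reference", call. = FALSE)
  p <- phs[phs$pos >= st & phs$pos <= en, , drop = FALSE]
  if (nrow(p) != nrow(phs))
    stop("PHS outside the call span", call. = FALSE)
  base <- strsplit(substr(reference, st, en), "", fixed = TRUE)[[1]]
  a <- base; b <- base
  if (nrow(p)) {
    off <- p$pos - st + 1L
    a[off] <- p$allele1
    b[off] <- p$allele2
  }
  structure(list(start = st, end = en,
                 copy_a = paste(a, collapse = ""),
                 copy_b = paste(b, collapse = ""),
                 n_phs = nrow(p)),
            class = "paralog_pair")
}

#' @export
print.paralog_pair <- function(x, ...) {
  cat(sprintf("Paralog pair over %d-%d (%d bp), %d divergent sites\n",
              x$start, x$end, x$end - x$start + 1L, x$n_phs))
  invisible(x)
}

# ---- Nei-Gojobori (1986) machinery ----------------------------------------

# fraction of the 3 possible substitutions at each codon position that are
# synonymous; stop codons return NA
.ng86_codon_sites <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.na(aa) || aa == "*") return(NA_real_)
  s <- 0
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, chars[p])) {
      mut <- chars
      mut[p] <- b
      maa <- Biostrings::GENETIC_CODE[[paste(mut, collapse = "")]]
      if (!is.na(maa) && maa == aa) s <- s + 1 / 3
    }
  }
  s
}

# synonymous/nonsynonymous fractional differences between two codons,
# averaged over all minimal mutational pathways; pathways passing through a
# stop codon are excluded (all pathways are used if every one hits a stop)
.ng86_codon_diff <- function(c1, c2) {
  x <- strsplit(c1, "", fixed = TRUE)[[1]]
  y <- strsplit(c2, "", fixed = TRUE)[[1]]
  pos <- which(x != y)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- if (k == 1L) list(pos) else
    lapply(seq_len(factorial(k)), function(i) .nth_perm(pos, i))
  score_path <- function(ord) {
    cur <- x
    sd <- 0; nd <- 0; valid <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- y[p]
      a1 <- Biostrings::GENETIC_CODE[[paste(cur, collapse = "")]]
      a2 <- Biostrings::GENETIC_CODE[[paste(nxt, collapse = "")]]
      if (a2 == "*" || a1 == "*") valid <- FALSE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, valid = as.numeric(valid))
  }
  sc <- vapply(paths, score_path, c(sd = 0, nd = 0, valid = 0))
  use <- sc["valid", ] == 1
  if (!any(use)) use <- rep(TRUE, ncol(sc))
  c(sd = mean(sc["sd", use]), nd = mean(sc["nd", use]))
}

# i-th permutation (1-based, lexicographic by index) of a vector
.nth_perm <- function(v, i) {
  out <- integer(0)
  i <- i - 1L
  pool <- v
  for (n in rev(seq_along(v))) {
    f <- factorial(n - 1)
    idx <- i %/% f + 1L
    out <- c(out, pool[idx])
    pool <- pool[-idx]
    i <- i %% f
  }
  out
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Synonymous and nonsynonymous site counts are the NG86 fractional counts
#' per codon, averaged over the two sequences (so N + S = 3 x codons
#' exactly); differences are classified per codon with equal-weight
#' averaging over all minimal mutational pathways for multi-hit codons.
#' Proportions are Jukes-Cantor corrected.  Pairs with dS = 0 and dN > 0 are
#' reported with an undefined-ratio flag rather than dropped.
#'
#' @param x A `"paralog_pair"` from [reconstruct_paralogs()], or a character
#'   vector of two equal-length in-frame coding sequences.
#' @param cds Optional data frame of CDS intervals (`start`, `end`, 1-based
#'   on the same coordinates as the pair); the analysed sequence is the
#'   concatenated overlap of the pair span with these intervals.
#' @param frame Offset (0-2) of the first complete codon within the
#'   extracted sequence.
#' @return A list of class `"dnds"`: `dn`, `ds`, `ratio`,
#'   `ratio_undefined`, `n_sites`, `s_sites`, `n_diff`, `s_diff`,
#'   `n_codons`.
#' @examples
#' dn_ds(c("TTTGGGAAA", "TTAGGGAAA"))
#' @export
dn_ds <- function(x, cds = NULL, frame = 0L) {
  if (inherits(x, "paralog_pair")) {
    seqs <- c(x$copy_a, x$copy_b)
    if (!is.null(cds)) {
      pick <- function(s) {
        keep <- character(0)
        for (r in seq_len(nrow(cds))) {
          st <- max(cds$start[r], x$start)
          en <- min(cds$end[r], x$end)
          if (st <= en)
            keep <- c(keep, substr(s, st - x$start + 1L, en - x$start + 1L))
        }
        paste(keep, collapse = "")
      }
      seqs <- c(pick(x$copy_a), pick(x$copy_b))
    }
  } else {
    seqs <- x
  }
  if (length(seqs) != 2L || nchar(seqs[1]) != nchar(seqs[2]))
    stop("need two aligned sequences of equal length", call. = FALSE)
  if (frame > 0L) seqs <- substring(seqs, frame + 1L)
  L <- nchar(seqs[1])
  if (L < 3L) stop("coding overlap shorter than one codon", call. = FALSE)
  if (L %% 3L != 0L) {
    warning("sequence length not a codon multiple; trailing bases trimmed",
            call. = FALSE)
    seqs <- substring(seqs, 1L, L - L %% 3L)
    L <- nchar(seqs[1])
  }
  starts <- seq(1L, L, by = 3L)
  cod1 <- substring(seqs[1], starts, starts + 2L)
  cod2 <- substring(seqs[2], starts, starts + 2L)

  s_sites <- 0; n_sites <- 0; s_diff <- 0; n_diff <- 0; used <- 0L
  for (i in seq_along(cod1)) {
    st1 <- .ng86_codon_sites(cod1[i])
    st2 <- .ng86_codon_sites(cod2[i])
    if (is.na(st1) || is.na(st2)) {
      warning(sprintf("internal stop codon at codon %d skipped", i),
              call. = FALSE)
      next
    }
    used <- used + 1L
    s_sites <- s_sites + (st1 + st2) / 2
    n_sites <- n_sites + 3 - (st1 + st2) / 2
    d <- .ng86_codon_diff(cod1[i], cod2[i])
    s_diff <- s_diff + d[["sd"]]
    n_diff <- n_diff + d[["nd"]]
  }
  if (used == 0L) stop("no analysable codons", call. = FALSE)
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ds <- jc(s_diff / s_sites)
  dn <- jc(n_diff / n_sites)
  undefined <- is.na(ds) || (ds == 0 && dn > 0)
  structure(list(
    dn = dn, ds = ds,
    ratio = if (!undefined && !is.na(dn)) dn / ds else NA_real_,
    ratio_undefined = undefined,
    n_sites = n_sites, s_sites = s_sites,
    n_diff = n_diff, s_diff = s_diff,
    n_codons = used
  ), class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("NG86 pairwise rates over %d codons: dN = %.5g, dS = %.5g",
              x$n_codons, x$dn, x$ds))
  if (x$ratio_undefined) cat("  (dN/dS undefined)")
  else cat(sprintf(", dN/dS = %.4g", x$ratio))
  cat("\n")
  invisible(x)
}

#' Sign test comparing paralog and ortholog dN/dS ratios
#'
#' Two-sided sign test on gene-paired ratios; ties are dropped, and pairs
#' with an undefined ratio must be excluded by the caller (they are a
#' separate reporting category).
#'
#' @param paralog,ortholog Numeric vectors of dN/dS ratios paired by gene.
#' @return A list of class `"phs_test"`: `n_pairs` (informative),
#'   `n_greater` (paralog > ortholog), `p_value` (two-sided).
#' @examples
#' compare_paralog_ortholog(rep(1, 12), rep(0.2, 12))  # p = 2 * 2^-12
#' @export
compare_paralog_ortholog <- function(paralog, ortholog) {
  if (length(paralog) != length(ortholog))
    stop("ratio vectors must be paired", call. = FALSE)
  ok <- is.finite(paralog) & is.finite(ortholog)
  d <- paralog[ok] - ortholog[ok]
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all pairs tied; sign test undefined", call. = FALSE)
  if (length(d) < 6L)
    warning("fewer than 6 informative pairs; the sign test has little power",
            call. = FALSE)
  bt <- stats::binom.test(sum(d > 0), length(d), 0.5,
                          alternative = "two.sided")
  structure(list(n_pairs = length(d), n_greater = sum(d > 0),
                 statistic = sum(d > 0), df = NA_integer_,
                 p_value = bt$p.value,
                 method = "sign test, paralog vs ortholog dN/dS"),
            class = "phs_test")
}

#' Classify cross-species homology hits per duplication
#'
#' A hit qualifies when its identity strictly exceeds 90% and its alignment
#' length strictly exceeds half of the query length.  Queries with no
#' qualifying hit have no homolog; one qualifying locus means a single copy
#' in the subject genome; two or more non-overlapping qualifying loci mean
#' the region is itself duplicated in the subject.
#'
#' @param hits Data frame with columns `query_id`, `query_length`,
#'   `subject_start`, `subject_end`, `identity` (percent), `align_length`.
#'   Queries absent from the table get status `no_homolog`.
#' @param query_ids Optional character vector of all query ids to report.
#' @param min_identity,min_coverage Strict thresholds (percent identity,
#'   fraction of query length aligned).
#' @return Data frame: `query_id`, `n_hits` (qualifying, non-overlapping),
#'   `status`.
#' @export
filter_homology_hits <- function(hits, query_ids = NULL, min_identity = 90,
                                 min_coverage = 0.5) {
  if (is.null(query_ids)) query_ids <- unique(hits$query_id)
  qual <- hits[hits$identity > min_identity &
                 hits$align_length > min_coverage * hits$query_length, ,
               drop = FALSE]
  n_loci <- vapply(query_ids, function(q) {
    h <- qual[qual$query_id == q, , drop = FALSE]
    if (nrow(h) == 0L) return(0L)
    length(IRanges::reduce(IRanges::IRanges(h$subject_start, h$subject_end)))
  }, integer(1))
  data.frame(
    query_id = query_ids,
    n_hits = unname(n_loci),
    status = ifelse(n_loci == 0L, "no_homolog",
                    ifelse(n_loci == 1L, "single_copy",
                           "duplicated_in_subject")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
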