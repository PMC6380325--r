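#' Build a genome annotation object
#'
#' Collects CDS, 5'UTR, 3'UTR and intron intervals (1-based closed, per
#' chromosome) plus chromosome lengths; everything not covered is
#' intergenic.
#'
#' @param cds,utr5,utr3,intron Data frames with columns `chrom`, `start`,
#'   `end` (1-based closed); `NULL` for an empty class.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @return A list of class `"genome_annotation"` holding the four interval
#'   sets as `GRanges` plus `chrom_lengths`.
#' @export
build_annotation <- function(cds = NULL, utr5 = NULL, utr3 = NULL,
                             intron = NULL, chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("`chrom_lengths` must be a named vector", call. = FALSE)
  as_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
      return(GenomicRanges::GRanges())
    if (any(df$start < 1) ||
        any(df$end > chrom_lengths[as.character(df$chrom)]))
      stop("annotation intervals outside chromosome bounds", call. = FALSE)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  }
  structure(list(cds = as_gr(cds), utr5 = as_gr(utr5), utr3 = as_gr(utr3),
                 intron = as_gr(intron), chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("Genome annotation: %d chromosome(s), %d CDS / %d 5'UTR / %d 3'UTR / %d intron intervals\n",
              length(x$chrom_lengths), length(x$cds), length(x$utr5),
              length(x$utr3), length(x$intron)))
  invisible(x)
}

#' Total bp per region class, intergenic as complement
#'
#' @param annotation A [build_annotation()] result.
#' @return Named numeric vector over CDS, utr5, utr3, intron, intergenic.
#' @export
region_lengths <- function(annotation) {
  red <- lapply(annotation[c("cds", "utr5", "utr3", "intron")],
                GenomicRanges::reduce)
  # priority share: a bp counts for the highest-priority class covering it
  taken <- GenomicRanges::GRanges()
  out <- numeric(4)
  names(out) <- c("cds", "utr5", "utr3", "intron")
  for (k in names(out)) {
    free <- GenomicRanges::setdiff(red[[k]], taken)
    out[k] <- sum(IRanges::width(free))
    taken <- GenomicRanges::reduce(c(taken, red[[k]]))
  }
  total <- sum(annotation$chrom_lengths)
  c(out, intergenic = total - sum(IRanges::width(taken)))
}

#' Assign sites or calls to genomic region classes
#'
#' Each item is labelled by the highest-priority region class it overlaps:
#' CDS > 5'UTR > 3'UTR > intron > intergenic (coding impact dominates when
#' transcripts overlap).
#'
#' @param items Data frame with `chrom` and either `pos` or `start`/`end`.
#' @param annotation A [build_annotation()] result.
#' @return `items` with a `region` column appended; use `table()` for
#'   region counts.
#' @export
assign_regions <- function(items, annotation) {
  if (nrow(items) == 0L) {
    items$region <- character(0)
    return(items)
  }
  st <- if (!is.null(items$pos)) items$pos else items$start
  en <- if (!is.null(items$pos)) items$pos else items$end
  if (any(st < 1) ||
      any(en > annotation$chrom_lengths[as.character(items$chrom)]))
    stop("items outside chromosome bounds", call. = FALSE)
  gr <- GenomicRanges::GRanges(items$chrom, IRanges::IRanges(st, en))
  region <- rep("intergenic", nrow(items))
  for (k in c("intron", "utr3", "utr5", "cds")) {   # ascending priority
    hit <- IRanges::overlapsAny(gr, annotation[[k]])
    region[hit] <- sub("^utr5$", "5'UTR",
                       sub("^utr3$", "3'UTR", sub("^cds$", "CDS", k)))
  }
  items$region <- region
  items
}

#' Per-region chi-square deviation from length-proportional expectation
#'
#' Expected counts are proportional to each region class's share of the
#' genome; each class is tested against its complement with a 1-df Pearson
#' chi-square (no continuity correction).
#'
#' @param counts Named vector of observed counts per region class.
#' @param lengths Named vector of region lengths in bp (same names), e.g.
#'   [region_lengths()].
#' @return Data frame: `region`, `observed`, `expected`, `statistic`, `p`,
#'   `direction` (+1 enriched / -1 depleted).
#' @export
region_chi_square <- function(counts, lengths) {
  zero <- lengths <= 0
  if (any(zero)) {
    warning("dropping zero-length region class(es): ",
            paste(names(lengths)[zero], collapse = ", "), call. = FALSE)
    lengths <- lengths[!zero]
    counts <- counts[names(lengths)]
  }
  counts <- counts[names(lengths)]
  counts[is.na(counts)] <- 0
  N <- sum(counts)
  share <- lengths / sum(lengths)
  expected <- N * share
  stat <- (counts - expected)^2 / expected +
    ((N - counts) - (N - expected))^2 / (N - expected)
  data.frame(
    region = names(lengths),
    observed = as.numeric(counts),
    expected = as.numeric(expected),
    statistic = as.numeric(stat),
    p = stats::pchisq(as.numeric(stat), df = 1, lower.tail = FALSE),
    direction = sign(as.numeric(counts) - as.numeric(expected)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# sample length-matched random fragments; one row per (draw, fragment)
.sample_fragments <- function(lengths, chrom_lengths, n_draws) {
  lens <- rep(lengths, times = n_draws)
  chroms <- names(chrom_lengths)
  if (length(chroms) == 1L) {
    ch <- rep(chroms, length(lens))
  } else {
    w <- pmax(chrom_lengths - mean(lengths), 1)
    ch <- sample(chroms, length(lens), replace = TRUE, prob = w)
  }
  maxstart <- pmax(chrom_lengths[ch] - lens + 1, 1)
  st <- floor(stats::runif(length(lens)) * maxstart) + 1
  data.frame(draw = rep(seq_len(n_draws), each = length(lengths)),
             chrom = ch, start = st, end = pmin(st + lens - 1,
                                                chrom_lengths[ch]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation test of call overlap with a functional-element track
#'
#' The observed statistic is the number of calls overlapping (by >= 1 bp)
#' any track interval.  The null distribution resamples, `n_perm` times, one
#' length-matched fragment per call uniformly from the genome and counts
#' overlaps the same way.  The empirical p-value uses the add-one
#' (pseudocount) formula, so it is never 0 and never exceeds 1; the
#' two-sided p doubles the smaller tail, capped at 1.
#'
#' @param calls Data frame with `chrom`, `start`, `end`.
#' @param track Data frame of track intervals (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_perm Number of permutations (values below 100 draw a warning).
#' @return A list of class `"perm_result"`: `observed`, `expected` (null
#'   mean), `ratio` (observed/expected), `p_lower`, `p_upper`, `p_two_sided`,
#'   `n_perm`, `null` (the null counts).
#' @export
permutation_enrichment <- function(calls, track, chrom_lengths,
                                   n_perm = 10000) {
  if (n_perm < 100)
    warning("fewer than 100 permutations; empirical p is coarse",
            call. = FALSE)
  if (nrow(calls) == 0L) stop("no calls supplied", call. = FALSE)
  track_gr <- if (nrow(track)) GenomicRanges::reduce(
    GenomicRanges::GRanges(track$chrom, .as_iranges(track))) else
      GenomicRanges::GRanges()
  call_gr <- GenomicRanges::GRanges(calls$chrom, .as_iranges(calls))
  observed <- sum(IRanges::overlapsAny(call_gr, track_gr))

  lens <- calls$end - calls$start + 1
  frags <- .sample_fragments(lens, chrom_lengths, n_perm)
  frag_gr <- GenomicRanges::GRanges(frags$chrom, .as_iranges(frags))
  hit <- IRanges::overlapsAny(frag_gr, track_gr)
  null <- as.integer(rowsum(as.integer(hit), frags$draw))

  p_upper <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_lower <- (1 + sum(null <= observed)) / (n_perm + 1)
  structure(list(
    observed = observed,
    expected = mean(null),
    ratio = if (mean(null) > 0) observed / mean(null) else
      if (observed == 0) 0 else Inf,
    p_lower = p_lower, p_upper = p_upper,
    p_two_sided = min(1, 2 * min(p_lower, p_upper)),
    n_perm = as.integer(n_perm), null = null
  ), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%d resamples): observed %s vs expected %.2f (ratio %.3f)\n",
              x$n_perm, format(x$observed), x$expected, x$ratio))
  cat(sprintf("  p(depletion) = %.4g, p(enrichment) = %.4g, two-sided = %.4g\n",
              x$p_lower, x$p_upper, x$p_two_sided))
  invisible(x)
}

#' Permutation test of the no-homolog fraction of duplication calls
#'
#' Compares the observed fraction of calls without a cross-species homolog
#' against the fraction obtained for equally many random fixed-length
#' genomic fragments, resampled `n_perm` times and scored by a user-supplied
#' status function (in practice a wrapper over precomputed homology search
#' results; synthetic in tests).
#'
#' @param call_status Character vector of homology status per call
#'   (`"no_homolog"`, `"single_copy"`, `"duplicated_in_subject"`).
#' @param status_fun Function taking a fragment data frame (`chrom`,
#'   `start`, `end`) and returning a status vector.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_perm Number of resamples.
#' @param fragment_length Length of the random fragments (bp).
#' @return A `"perm_result"` (see [permutation_enrichment()]) where
#'   `observed` and `null` are no-homolog fractions; the minimal achievable
#'   one-sided p is `1 / (n_perm + 1)`.
#' @export
homolog_fraction_permutation <- function(call_status, status_fun,
                                         chrom_lengths, n_perm = 1000,
                                         fragment_length = 400) {
  observed <- mean(call_status == "no_homolog")
  m <- length(call_status)
  frags <- .sample_fragments(rep(fragment_length, m), chrom_lengths, n_perm)
  status <- status_fun(frags)
  null <- as.numeric(rowsum((status == "no_homolog") + 0, frags$draw)) / m
  p_upper <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_lower <- (1 + sum(null <= observed)) / (n_perm + 1)
  structure(list(
    observed = observed, expected = mean(null),
    ratio = if (mean(null) > 0) observed / mean(null) else
      if (observed == 0) 0 else Inf,
    p_lower = p_lower, p_upper = p_upper,
    p_two_sided = min(1, 2 * min(p_lower, p_upper)),
    n_perm = as.integer(n_perm), null = null
  ), class = "perm_result")
}

#' Depletion trend of duplication age groups across functional elements
#'
#' For every duplication age group and every track, computes the
#' observed/expected overlap ratio by [permutation_enrichment()]; then, per
#' group, a sign test across tracks of H0 "median ratio = 1"; across
#' groups, a Friedman test on the track-by-group ratio matrix followed by
#' pairwise Wilcoxon signed-rank tests with Bonferroni correction.
#'
#' @param groups Named list of call data frames (`chrom`, `start`, `end`),
#'   in age order (e.g. young singleton, old singleton, nonsingleton).
#' @param tracks Named list of track data frames of one element class.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_perm Permutations per group x track cell.
#' @return A list of class `"age_trend"`: `ratios` (track x group matrix),
#'   `sign_tests` (per group: `n_below`, `n_ties`, `p_one_sided`,
#'   `p_two_sided`), `friedman_p`, `pairwise` (Bonferroni-adjusted Wilcoxon
#'   p matrix or NULL with < 3 groups).
#' @export
age_group_trend <- function(groups, tracks, chrom_lengths, n_perm = 1000) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (length(tracks) < 2L) stop("need at least two tracks", call. = FALSE)
  if (length(tracks) < 6L)
    warning("fewer than 6 tracks; sign tests have little power", call. = FALSE)
  ratios <- matrix(NA_real_, nrow = length(tracks), ncol = length(groups),
                   dimnames = list(names(tracks), names(groups)))
  for (g in seq_along(groups)) for (t in seq_along(tracks)) {
    ratios[t, g] <- permutation_enrichment(groups[[g]], tracks[[t]],
                                           chrom_lengths, n_perm)$ratio
  }
  sign_tests <- lapply(seq_along(groups), function(g) {
    r <- ratios[, g]
    below <- sum(r < 1); above <- sum(r > 1); m <- below + above
    if (m == 0L) return(list(n_below = 0L, n_ties = length(r),
                             p_one_sided = 1, p_two_sided = 1))
    bt <- stats::binom.test(below, m, 0.5, alternative = "greater")
    bt2 <- stats::binom.test(below, m, 0.5, alternative = "two.sided")
    list(n_below = below, n_ties = length(r) - m,
         p_one_sided = bt$p.value, p_two_sided = bt2$p.value)
  })
  names(sign_tests) <- names(groups)

  fr <- stats::friedman.test(ratios)
  pairwise <- NULL
  if (length(groups) >= 2L) {
    k <- length(groups)
    pairwise <- matrix(NA_real_, k, k,
                       dimnames = list(names(groups), names(groups)))
    n_pairs <- k * (k - 1) / 2
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (all(ratios[, i] == ratios[, j])) {
        p <- 1
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(ratios[, i], ratios[, j], paired = TRUE)$p.value)
      }
      pairwise[i, j] <- pairwise[j, i] <- min(1, p * n_pairs)
    }
  }
  structure(list(ratios = ratios, sign_tests = sign_tests,
                 friedman_p = fr$p.value, pairwise = pairwise),
            class = "age_trend")
}

#' @export
print.age_trend <- function(x, ...) {
  cat("Age-group depletion trend\n  median ratio per group:\n")
  med <- apply(x$ratios, 2, stats::median)
  for (g in names(med)) {
    cat(sprintf("    %s: %.3f (sign test p = %.3g)\n", g, med[g],
                x$sign_tests[[g]]$p_two_sided))
  }
  cat(sprintf("  Friedman test across groups: p = %.3g\n", x$friedman_p))
  invisible(x)
}
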