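#' Site frequency spectrum of duplication events
#'
#' Counts of events by number of carrier genomes (1..n-1), with the harmonic
#' normaliser `a = sum(1/i, i = 1..n-1)` that scales the total count into
#' the neutral singleton expectation.
#'
#' @param frequencies Integer vector of carrier counts, one per event.
#' @param n Number of genomes sampled.
#' @return A list of class `"sfs"`: `n`, `counts` (length n-1), `S` (total
#'   events) and `a` (harmonic normaliser).
#' @examples
#' sfs(c(1, 1, 2, 5), n = 29)
#' @export
sfs <- function(frequencies, n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (length(frequencies) && (any(frequencies < 1) || any(frequencies > n - 1)))
    stop("carrier counts must lie in 1..(n-1)", call. = FALSE)
  counts <- tabulate(frequencies, nbins = n - 1L)
  structure(list(n = as.integer(n), counts = counts,
                 S = length(frequencies), a = sum(1 / seq_len(n - 1L))),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("Site frequency spectrum: %d events over %d genomes (a = %.4f)\n",
              x$S, x$n, x$a))
  cat(sprintf("  singletons: %d observed vs %.1f expected under neutrality\n",
              x$counts[1], x$S / x$a))
  invisible(x)
}

#' Neutral-expectation counts per frequency class
#'
#' Under the standard neutral model the expected number of variants carried
#' by i of n genomes is proportional to 1/i, so with S variants in total the
#' expected count in class i is `S / (a * i)` with
#' `a = sum(1/i, i = 1..n-1)`.  The expected singleton count is `S / a` and
#' the classes sum to S exactly.
#'
#' @param S Total number of observed variants (events).
#' @param n Number of genomes sampled.
#' @return A list: `a`, `expected` (length n-1), `singleton`,
#'   `nonsingleton`, and their rounded integer versions
#'   `singleton_rounded` / `nonsingleton_rounded`.
#' @examples
#' neutral_expectation(2282, 29)$singleton_rounded   # 581
#' @export
neutral_expectation <- function(S, n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (S < 0) stop("`S` must be nonnegative", call. = FALSE)
  i <- seq_len(n - 1L)
  a <- sum(1 / i)
  expected <- S / (a * i)
  singleton <- S / a
  list(a = a, expected = expected, singleton = singleton,
       nonsingleton = S - singleton,
       singleton_rounded = round(singleton),
       nonsingleton_rounded = round(S - singleton))
}

#' Chi-square test for singleton excess against the neutral expectation
#'
#' One-degree-of-freedom Pearson chi-square (no continuity correction) of
#' the observed singleton/nonsingleton split against the neutral split
#' `(S/a, S - S/a)`.
#'
#' @param observed_singleton,observed_nonsingleton Observed counts; must sum
#'   to `S`.
#' @param S Total number of events.
#' @param n Number of genomes sampled.
#' @return A list of class `"phs_test"`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `excess` (sign of the singleton deviation).
#' @examples
#' singleton_excess_test(1656, 626, S = 2282, n = 29)
#' @export
singleton_excess_test <- function(observed_singleton, observed_nonsingleton,
                                  S = observed_singleton + observed_nonsingleton,
                                  n) {
  if (observed_singleton + observed_nonsingleton != S)
    stop("observed counts must sum to `S`", call. = FALSE)
  ex <- neutral_expectation(S, n)
  expected <- c(singleton = ex$singleton, nonsingleton = ex$nonsingleton)
  if (any(expected < 5))
    warning("expected class count below 5; chi-square approximation is poor",
            call. = FALSE)
  observed <- c(singleton = observed_singleton,
                nonsingleton = observed_nonsingleton)
  stat <- sum((observed - expected)^2 / expected)
  structure(list(
    statistic = stat, df = 1L,
    p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    observed = observed, expected = expected,
    excess = sign(observed_singleton - ex$singleton),
    method = "chi-square vs neutral singleton expectation"
  ), class = "phs_test")
}

#' @export
print.phs_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.3g\n",
              x$statistic, format(x$df), x$p_value))
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 proportion table
#'
#' Exact hypergeometric test, e.g. comparing singleton proportions between
#' undetermined and in-silico-validated PHS.
#'
#' @param table A 2x2 matrix (or object coercible to one) of nonnegative
#'   integer counts with positive margins.
#' @return A list of class `"phs_test"` with `p_value`, `odds_ratio` and the
#'   input table.
#' @examples
#' proportion_test(matrix(c(1208, 295, 3525, 1474), nrow = 2, byrow = TRUE))
#' @export
proportion_test <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tb < 0) || any(tb != round(tb)))
    stop("table must hold nonnegative integers", call. = FALSE)
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("table margins must be positive", call. = FALSE)
  ft <- stats::fisher.test(tb, alternative = "two.sided")
  structure(list(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 statistic = unname(ft$estimate), df = NA_integer_,
                 table = tb,
                 method = "Fisher exact test (two-sided)"),
            class = "phs_test")
}

#' Singleton-based false-positive estimate for an undetermined call set
#'
#' If validated calls are taken as true positives, the excess singleton
#' proportion of the undetermined set over the validated set, scaled by the
#' undetermined share, estimates the false-positive fraction of the whole
#' set: `N_und * (s_und/N_und - s_val/N_val) / N_total`.
#'
#' @param n_undetermined,singletons_undetermined Size and singleton count of
#'   the undetermined set.
#' @param n_validated,singletons_validated Size and singleton count of the
#'   validated set.
#' @param n_total Total calls; must equal the two set sizes summed.
#' @return A list: `fraction`, `percent` (rounded to one decimal), and the
#'   two singleton proportions.
#' @examples
#' false_positive_estimate(1503, 1208, 4999, 3525, 6502)$percent  # 2.3
#' @export
false_positive_estimate <- function(n_undetermined, singletons_undetermined,
                                    n_validated, singletons_validated,
                                    n_total) {
  if (n_undetermined + n_validated != n_total)
    stop("`n_undetermined` + `n_validated` must equal `n_total`", call. = FALSE)
  p_und <- singletons_undetermined / n_undetermined
  p_val <- singletons_validated / n_validated
  frac <- n_undetermined * (p_und - p_val) / n_total
  if (frac < 0) {
    warning("validated set has the higher singleton proportion; estimate set to 0",
            call. = FALSE)
    frac <- 0
  }
  list(fraction = frac, percent = round(100 * frac, 1),
       prop_undetermined = p_und, prop_validated = p_val)
}

#' Nucleotide diversity and Watterson's theta
#'
#' `pi` is the mean pairwise difference per site,
#' `sum(2 i (n - i)) / (n (n-1)) / L` over segregating sites carried by i of
#' n genomes; `theta_W = S / (a L)` with the harmonic normaliser
#' `a = sum(1/i, i = 1..n-1)`.
#'
#' @param x Either a character vector of n equal-length haploid sequences,
#'   or an integer vector of derived-allele carrier counts (one per
#'   segregating site).
#' @param n Number of genomes; inferred from `x` when sequences are given.
#' @param L Sites surveyed (bp); inferred from sequence length.
#' @return A list: `pi`, `theta_w`, `S`, `n`, `L`.
#' @examples
#' diversity(c("ACGT", "ACGA"))   # pi = theta = 0.25
#' @export
diversity <- function(x, n = NULL, L = NULL) {
  if (is.character(x)) {
    if (length(x) < 2L) stop("need at least two sequences", call. = FALSE)
    if (length(unique(nchar(x))) != 1L)
      stop("sequences must have equal length", call. = FALSE)
    n <- length(x)
    L <- nchar(x[1])
    if (L == 0L) stop("`L` must be positive", call. = FALSE)
    mat <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    counts <- integer(0)
    for (j in seq_len(L)) {
      tab <- table(mat[, j])
      if (length(tab) > 1L) {
        # per-site carrier counts of all non-major alleles
        counts <- c(counts, as.integer(tab[-which.max(tab)]))
      }
    }
  } else {
    counts <- as.integer(x)
    if (is.null(n) || is.null(L))
      stop("`n` and `L` are required with a carrier-count input", call. = FALSE)
    if (L <= 0) stop("`L` must be positive", call. = FALSE)
    if (length(counts) && (any(counts < 1) || any(counts > n - 1)))
      stop("carrier counts must lie in 1..(n-1)", call. = FALSE)
  }
  a <- sum(1 / seq_len(n - 1L))
  pi <- sum(2 * counts * (n - counts)) / (n * (n - 1)) / L
  theta_w <- length(counts) / (a * L)
  list(pi = pi, theta_w = theta_w, S = length(counts),
       n = as.integer(n), L = as.integer(L))
}
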