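#' Compute per-window read-depth ratios for one genome
#'
#' Each fixed-size window's depth is divided by the genome-wide mean depth,
#' giving a copy-number proxy on a haploid baseline of 1.  The mean is taken
#' over windows not overlapping the repeat mask, mirroring depth estimation
#' against a repeat-masked reference, and is recalibrated by iteratively
#' excluding windows deviating more than `trim_sd` standard deviations from
#' the running mean (the control-region recalibration of read-depth
#' copy-number callers): without it, duplicated windows inflate the baseline
#' and bias every ratio below the true copy number.
#'
#' @param depth Data frame with columns `chrom`, `start` (window start,
#'   1-based) and `depth` for one genome, windows tiling the reference
#'   without overlap.
#' @param window Window size in bp.
#' @param masks Optional [build_masks()] result; windows overlapping
#'   `masks$repeats` are excluded from the genome mean (not from the output).
#' @param trim_sd Outlier cutoff for the baseline recalibration (standard
#'   deviations); `Inf` disables trimming.
#' @return A list of class `"depth_profile"`: `windows` (data frame with
#'   `chrom`, `start`, `end`, `depth`, `ratio`), `genome_mean`, `window`.
#' @examples
#' d <- data.frame(chrom = "ref", start = seq(1, by = 200, length.out = 20),
#'                 depth = c(rep(30, 19), 60))
#' compute_depth_profile(d)$windows$ratio
#' @export
compute_depth_profile <- function(depth, window = 200L, masks = NULL,
                                  trim_sd = 3) {
  if (nrow(depth) == 0L) stop("empty depth track", call. = FALSE)
  use <- rep(TRUE, nrow(depth))
  if (!is.null(masks) && length(masks$repeats)) {
    use <- !IRanges::overlapsAny(
      IRanges::IRanges(depth$start, depth$start + window - 1L), masks$repeats)
  }
  keep <- use
  if (is.finite(trim_sd) && sum(keep) > 2L) {
    for (it in 1:20) {
      m <- mean(depth$depth[keep]); s <- stats::sd(depth$depth[keep])
      if (!is.finite(s) || s == 0) break
      nxt <- use & abs(depth$depth - m) <= trim_sd * s
      if (sum(nxt) < 3L || identical(nxt, keep)) break
      keep <- nxt
    }
  }
  gmean <- mean(depth$depth[keep])
  if (!is.finite(gmean) || gmean <= 0)
    stop("genome-wide mean depth is zero; cannot form ratios", call. = FALSE)
  windows <- data.frame(chrom = depth$chrom, start = depth$start,
                        end = depth$start + window - 1L,
                        depth = depth$depth, ratio = depth$depth / gmean,
                        stringsAsFactors = FALSE)
  structure(list(windows = windows, genome_mean = gmean,
                 window = as.integer(window)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile: %d windows of %d bp, genome mean %.2f\n",
              nrow(x$windows), x$window, x$genome_mean))
  invisible(x)
}

#' Call high-copy regions from a depth profile
#'
#' A high-copy region is a maximal run of consecutive windows whose depth
#' ratio exceeds `run_ratio` (default 1.25) containing at least one window
#' whose ratio exceeds `peak_ratio` (default 2); both thresholds are strict.
#'
#' @param profile A [compute_depth_profile()] result, or a plain numeric
#'   vector of window ratios (then `chrom = "ref"` and `window` bp windows
#'   starting at 1 are assumed).
#' @param peak_ratio At least one window must exceed this ratio.
#' @param run_ratio Every window of the region must exceed this ratio.
#' @param window Window size when `profile` is a bare ratio vector.
#' @return Data frame of regions: `chrom`, `start`, `end` (1-based closed,
#'   window-aligned), `n_windows`, `max_ratio`, `mean_ratio`.
#' @examples
#' call_high_copy_regions(c(1, 2.2, 1.33, 1))
#' @export
call_high_copy_regions <- function(profile, peak_ratio = 2, run_ratio = 1.25,
                                   window = 200L) {
  if (is.numeric(profile)) {
    n <- length(profile)
    profile <- structure(list(
      windows = data.frame(chrom = "ref",
                           start = (seq_len(n) - 1L) * window + 1L,
                           end = seq_len(n) * window,
                           ratio = profile, stringsAsFactors = FALSE),
      window = as.integer(window)), class = "depth_profile")
  }
  w <- profile$windows
  proto <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), max_ratio = numeric(),
                      mean_ratio = numeric(), stringsAsFactors = FALSE)
  if (nrow(w) == 0L) return(proto)
  runs <- rle(w$ratio > run_ratio)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  cand <- which(runs$values)
  out <- lapply(cand, function(i) {
    idx <- run_start[i]:run_end[i]
    if (max(w$ratio[idx]) <= peak_ratio) return(NULL)
    data.frame(chrom = w$chrom[idx[1]], start = w$start[idx[1]],
               end = w$end[idx[length(idx)]], n_windows = length(idx),
               max_ratio = max(w$ratio[idx]), mean_ratio = mean(w$ratio[idx]),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(proto)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call tandem duplications from split-read clusters
#'
#' Clusters of reads whose two fragments map to the reference in reverse
#' order mark a tandem-duplication junction.  To avoid strand bias, a cluster
#' is accepted when its S1 score, `(n_forward + 1) * (n_reverse + 1)`,
#' strictly exceeds `min_s1` (default 15).
#'
#' @param clusters Data frame with columns `genome_id` (optional), `chrom`,
#'   `bp1`, `bp2` (left/right breakpoints, 1-based, `bp1 <= bp2`),
#'   `n_forward`, `n_reverse`.
#' @param min_s1 S1 must be strictly greater than this.
#' @param reference_length Optional; breakpoints beyond it raise an error.
#' @return The accepted clusters with columns `start = bp1`, `end = bp2` and
#'   `s1` appended.
#' @examples
#' call_tandem_duplications(data.frame(chrom = "ref", bp1 = 100, bp2 = 400,
#'                                     n_forward = 3, n_reverse = 3))
#' @export
call_tandem_duplications <- function(clusters, min_s1 = 15,
                                     reference_length = NULL) {
  proto <- data.frame(genome_id = character(), chrom = character(),
                      bp1 = integer(), bp2 = integer(), n_forward = integer(),
                      n_reverse = integer(), start = integer(),
                      end = integer(), s1 = numeric(), stringsAsFactors = FALSE)
  if (is.null(clusters) || nrow(clusters) == 0L) return(proto)
  if (any(clusters$n_forward < 0 | clusters$n_reverse < 0))
    stop("strand support counts must be nonnegative", call. = FALSE)
  if (any(clusters$bp1 > clusters$bp2) || any(clusters$bp1 < 1))
    stop("breakpoints must satisfy 1 <= bp1 <= bp2", call. = FALSE)
  if (!is.null(reference_length) && any(clusters$bp2 > reference_length))
    stop("breakpoints beyond the reference length", call. = FALSE)
  if (is.null(clusters$genome_id)) clusters$genome_id <- "g1"
  clusters$start <- clusters$bp1
  clusters$end <- clusters$bp2
  clusters$s1 <- (clusters$n_forward + 1) * (clusters$n_reverse + 1)
  out <- clusters[clusters$s1 > min_s1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate copy numbers from qPCR Ct tables
#'
#' Relative quantification against a single-copy reference fragment and a
#' single-copy calibrator strain: per strain,
#' `dCt = mean(target Ct) - mean(reference-fragment Ct)` over the technical
#' replicates; `ddCt = dCt(calibrator) - dCt(test)`; `copy_number = 2^ddCt`.
#' An amplicon is flagged as duplicated when its copy number strictly exceeds
#' `2^0.5` (~1.41).  Z-scores of ddCt across amplicons within each strain are
#' reported alongside; with `z_normalize = TRUE` the threshold is instead
#' applied to `2^z`.
#'
#' @param ct Data frame with columns `amplicon`, `strain`, `target` (`TRUE`
#'   for the target amplicon, `FALSE` for the single-copy reference
#'   fragment), `ct`.  Three technical replicates per amplicon/strain/role
#'   are expected; other counts draw a warning.
#' @param calibrator Name of the calibrator strain (single-copy standard).
#' @param threshold Copy-number cutoff (strict) for the duplication flag.
#' @param z_normalize Apply the duplication threshold to `2^z(ddCt)` instead
#'   of the raw fold change.
#' @return Data frame with one row per amplicon and non-calibrator strain:
#'   `amplicon`, `strain`, `dct`, `ddct`, `z_ddct`, `copy_number`,
#'   `duplicated`.
#' @examples
#' ct <- expand.grid(amplicon = "a1", strain = c("cal", "test"),
#'                   target = c(TRUE, FALSE), rep = 1:3)
#' ct$ct <- ifelse(ct$target & ct$strain == "test", 19, 20)
#' qpcr_copy_number(ct, calibrator = "cal")
#' @export
qpcr_copy_number <- function(ct, calibrator, threshold = 2^0.5,
                             z_normalize = FALSE) {
  if (!all(c("amplicon", "strain", "target", "ct") %in% names(ct)))
    stop("`ct` needs columns amplicon, strain, target, ct", call. = FALSE)
  if (!calibrator %in% ct$strain)
    stop(sprintf("calibrator strain '%s' absent from the Ct table", calibrator),
         call. = FALSE)
  reps <- aggregate(ct$ct, by = list(amplicon = ct$amplicon,
                                     strain = ct$strain, target = ct$target),
                    FUN = length)
  if (any(reps$x != 3L))
    warning("expected 3 technical replicates per amplicon/strain; proceeding",
            call. = FALSE)
  m <- aggregate(ct$ct, by = list(amplicon = ct$amplicon, strain = ct$strain,
                                  target = ct$target), FUN = mean)
  tgt <- m[m$target == TRUE, c("amplicon", "strain", "x")]
  ref <- m[m$target == FALSE, c("amplicon", "strain", "x")]
  names(tgt)[3] <- "ct_target"; names(ref)[3] <- "ct_ref"
  dct <- merge(tgt, ref, by = c("amplicon", "strain"))
  dct$dct <- dct$ct_target - dct$ct_ref

  cal <- dct[dct$strain == calibrator, c("amplicon", "dct")]
  names(cal)[2] <- "dct_cal"
  test <- merge(dct[dct$strain != calibrator, ], cal, by = "amplicon")
  if (nrow(test) == 0L)
    stop("no test strains besides the calibrator", call. = FALSE)
  test$ddct <- test$dct_cal - test$dct
  test$z_ddct <- stats::ave(test$ddct, test$strain, FUN = function(v)
    if (length(v) > 1L && stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else
      v * 0)
  test$copy_number <- 2^test$ddct
  basis <- if (z_normalize) 2^test$z_ddct else test$copy_number
  test$duplicated <- basis > threshold
  out <- test[order(test$strain, test$amplicon),
              c("amplicon", "strain", "dct", "ddct", "z_ddct",
                "copy_number", "duplicated")]
  rownames(out) <- NULL
  out
}
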