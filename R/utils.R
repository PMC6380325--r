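# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# data.frame(start, end) [1-based closed] -> IRanges
.as_iranges <- function(df) {
  if (nrow(df) == 0L) return(IRanges::IRanges())
  IRanges::IRanges(start = df$start, end = df$end)
}

# overlap width of each query interval with the union of subject intervals
.overlap_bp <- function(q_start, q_end, subject) {
  if (length(q_start) == 0L) return(integer(0))
  q <- IRanges::IRanges(q_start, q_end)
  s <- IRanges::reduce(subject)
  hits <- IRanges::findOverlaps(q, s)
  ov <- IRanges::width(IRanges::pintersect(
    q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]
  ))
  out <- integer(length(q))
  if (length(hits)) {
    agg <- rowsum(ov, S4Vectors::queryHits(hits))
    out[as.integer(rownames(agg))] <- as.integer(agg[, 1L])
  }
  out
}

.stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %s", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %s", name, lower), call. = FALSE)
  invisible(x)
}

.check_rate <- function(x, name) {
  .stopifnot_scalar_number(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# empty prototypes keep column types stable on empty results
.empty_df <- function(proto) proto[0L, , drop = FALSE]
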