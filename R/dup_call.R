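#' Merge linked PHS into PHS-duplication calls
#'
#' Single-linkage chaining within each genome and chromosome: consecutive
#' PHS at most `gap` bp apart join one call, so every input PHS belongs to
#' exactly one call.  A call spans its first to last PHS; a call holding a
#' single PHS has length 1.
#'
#' @param phs Data frame of PHS records (columns `genome_id`, `chrom`,
#'   `pos`), e.g. from [filter_phs()].
#' @param gap Maximum distance (bp) between consecutive PHS of one call.
#' @return Data frame of calls: `call_id`, `genome_id`, `chrom`, `start`,
#'   `end` (1-based, positions of the first/last PHS), `phs_count`, `length`.
#' @examples
#' phs <- data.frame(genome_id = "g1", chrom = "ref",
#'                   pos = c(1000, 1350, 1800))
#' merge_phs(phs, gap = 400)
#' @export
merge_phs <- function(phs, gap = 400) {
  proto <- data.frame(call_id = character(), genome_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      phs_count = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(phs) || nrow(phs) == 0L) return(proto)
  if (gap < 0) stop("`gap` must be nonnegative", call. = FALSE)
  ord <- order(phs$genome_id, phs$chrom, phs$pos)
  p <- phs[ord, , drop = FALSE]
  grp <- paste(p$genome_id, p$chrom, sep = "\r")
  new_grp <- c(TRUE, grp[-1L] != grp[-nrow(p)])
  dist <- c(Inf, diff(p$pos))
  dist[new_grp] <- Inf
  call_idx <- cumsum(new_grp | dist > gap)
  first <- !duplicated(call_idx)
  out <- data.frame(
    genome_id = p$genome_id[first],
    chrom = p$chrom[first],
    start = as.integer(tapply(p$pos, call_idx, min)),
    end = as.integer(tapply(p$pos, call_idx, max)),
    phs_count = tabulate(call_idx),
    stringsAsFactors = FALSE
  )
  out$call_id <- paste0(out$genome_id, ":", out$chrom, ":", out$start)
  out$length <- pmax(out$end - out$start + 1L, 1L)
  out <- out[, c("call_id", "genome_id", "chrom", "start", "end",
                 "phs_count", "length")]
  rownames(out) <- NULL
  out
}

#' Remove calls in excluded regions and flag oversized spans
#'
#' Drops every call overlapping an excluded interval (for example large,
#' manually curated duplication blocks) and flags calls whose span exceeds
#' `flag_span` bp for exclusion review.
#'
#' @param calls Data frame of calls from [merge_phs()].
#' @param exclude Optional data frame of excluded intervals (`chrom`,
#'   `start`, `end`, 1-based closed).
#' @param flag_span Spans strictly larger than this (bp) are flagged.
#' @return `calls` without excluded rows, with a logical column
#'   `span_flagged` appended.
#' @export
apply_exclusions <- function(calls, exclude = NULL, flag_span = 28000) {
  if (nrow(calls) == 0L) {
    calls$span_flagged <- logical(0)
    return(calls)
  }
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(exclude) && nrow(exclude)) {
    for (ch in unique(calls$chrom)) {
      ex <- exclude[exclude$chrom == ch, , drop = FALSE]
      if (nrow(ex) == 0L) next
      i <- which(calls$chrom == ch)
      keep[i] <- !IRanges::overlapsAny(
        IRanges::IRanges(calls$start[i], calls$end[i]), .as_iranges(ex))
    }
  }
  out <- calls[keep, , drop = FALSE]
  out$span_flagged <- (out$end - out$start + 1L) > flag_span
  rownames(out) <- NULL
  out
}

#' Classify PHS-duplication calls against independent duplication evidence
#'
#' A call is classified `high_copy` when more than half of its span overlaps
#' high-copy regions of the same genome, `tandem` when more than half
#' overlaps tandem-duplication intervals, `both` when both hold and
#' `undetermined` otherwise.  The 50% rule is strict and measured against
#' the call's own span (first to last PHS, minimum 1 bp); breakpoints of
#' interspersed duplications are unobservable, so the span is the only
#' usable call length.
#'
#' @param calls Data frame of calls from [merge_phs()].
#' @param high_copy Data frame of high-copy regions (`genome_id`, `chrom`,
#'   `start`, `end`), e.g. pooled [call_high_copy_regions()] output.
#' @param tandem Data frame of tandem calls (`genome_id`, `chrom`, `start`,
#'   `end`), e.g. [call_tandem_duplications()] output.
#' @param min_overlap Overlap fraction that must be strictly exceeded.
#' @return `calls` with columns `hc_frac`, `td_frac` and `class` appended.
#' @examples
#' calls <- data.frame(call_id = "c", genome_id = "g1", chrom = "ref",
#'                     start = 101, end = 500, phs_count = 3, length = 400)
#' hc <- data.frame(genome_id = "g1", chrom = "ref", start = 1, end = 400)
#' classify_duplications(calls, high_copy = hc)$class
#' @export
classify_duplications <- function(calls, high_copy = NULL, tandem = NULL,
                                  min_overlap = 0.5) {
  if (nrow(calls) == 0L) {
    calls$hc_frac <- numeric(0); calls$td_frac <- numeric(0)
    calls$class <- character(0)
    return(calls)
  }
  frac_for <- function(evidence) {
    frac <- numeric(nrow(calls))
    if (is.null(evidence) || nrow(evidence) == 0L) return(frac)
    if (is.null(evidence$genome_id)) evidence$genome_id <- calls$genome_id[1]
    groups <- unique(calls[, c("genome_id", "chrom")])
    for (r in seq_len(nrow(groups))) {
      i <- which(calls$genome_id == groups$genome_id[r] &
                   calls$chrom == groups$chrom[r])
      ev <- evidence[evidence$genome_id == groups$genome_id[r] &
                       evidence$chrom == groups$chrom[r], , drop = FALSE]
      if (nrow(ev) == 0L) next
      ov <- .overlap_bp(calls$start[i], calls$end[i], .as_iranges(ev))
      frac[i] <- ov / (calls$end[i] - calls$start[i] + 1L)
    }
    frac
  }
  calls$hc_frac <- frac_for(high_copy)
  calls$td_frac <- frac_for(tandem)
  hc <- calls$hc_frac > min_overlap
  td <- calls$td_frac > min_overlap
  calls$class <- ifelse(hc & td, "both",
                        ifelse(td, "tandem",
                               ifelse(hc, "high_copy", "undetermined")))
  calls
}

#' Collate per-genome calls into population duplication events
#'
#' Calls in different genomes sharing at least one PHS position are unioned
#' into one population event (transitively); alternatively any interval
#' overlap can be used as the identity rule.  Event frequency is the number
#' of distinct carrier genomes; evidence classes of member calls are pooled,
#' so an event counts as tandem or high-copy if any member call carries that
#' evidence.
#'
#' @param calls Classified calls ([classify_duplications()] output; an
#'   unclassified [merge_phs()] result is accepted and yields class
#'   `undetermined`).
#' @param phs The PHS records the calls were merged from; required for
#'   `identity = "shared_phs"` to recover call membership.
#' @param identity `"shared_phs"` (default, most conservative) or
#'   `"overlap"`.
#' @return A list of class `"dup_catalog"`: `events` (data frame `event_id`,
#'   `chrom`, `start`, `end`, `frequency`, `n_calls`, `class`, `singleton`),
#'   `calls` (input calls with `event_id` appended) and `summary` (list with
#'   `per_genome` call counts, `size_classes` span fractions for < 500 bp,
#'   500 bp - 1 kb and > 1 kb, and the two duplication tallies
#'   `n_events` / `n_genome_calls`).
#' @export
collate_population <- function(calls, phs = NULL,
                               identity = c("shared_phs", "overlap")) {
  identity <- match.arg(identity)
  if (nrow(calls) == 0L) stop("no calls to collate", call. = FALSE)
  if (length(unique(calls$genome_id)) < 2L && identity == "shared_phs" &&
      is.null(phs))
    stop("`phs` records are required for shared_phs identity", call. = FALSE)
  n <- nrow(calls)

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  if (identity == "shared_phs") {
    if (is.null(phs))
      stop("`phs` records are required for shared_phs identity", call. = FALSE)
    # assign every PHS to its covering call within its genome, then union
    # calls that share a (chrom, pos) key across genomes
    assign_call <- integer(nrow(phs))
    groups <- unique(calls[, c("genome_id", "chrom")])
    for (r in seq_len(nrow(groups))) {
      i <- which(calls$genome_id == groups$genome_id[r] &
                   calls$chrom == groups$chrom[r])
      pi <- which(phs$genome_id == groups$genome_id[r] &
                    phs$chrom == groups$chrom[r])
      if (length(pi) == 0L) next
      hit <- IRanges::findOverlaps(
        IRanges::IRanges(phs$pos[pi], phs$pos[pi]),
        IRanges::IRanges(calls$start[i], calls$end[i]))
      assign_call[pi[S4Vectors::queryHits(hit)]] <- i[S4Vectors::subjectHits(hit)]
    }
    covered <- assign_call > 0L
    key <- paste(phs$chrom[covered], phs$pos[covered], sep = "\r")
    for (idx in split(assign_call[covered], key)) {
      u <- unique(idx)
      if (length(u) > 1L) for (j in u[-1L]) link(u[1L], j)
    }
  } else {
    for (ch in unique(calls$chrom)) {
      i <- which(calls$chrom == ch)
      ir <- IRanges::IRanges(calls$start[i], calls$end[i])
      hit <- IRanges::findOverlaps(ir, ir)
      q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
      for (h in which(q < s)) link(i[q[h]], i[s[h]])
    }
  }

  root <- vapply(seq_len(n), find, integer(1))
  event_id <- match(root, sort(unique(root)))
  calls$event_id <- paste0("e", event_id)

  has_class <- !is.null(calls$class)
  ev_list <- lapply(split(seq_len(n), event_id), function(i) {
    cls <- if (has_class) calls$class[i] else "undetermined"
    td <- any(cls %in% c("tandem", "both"))
    hc <- any(cls %in% c("high_copy", "both"))
    data.frame(
      chrom = calls$chrom[i[1L]],
      start = min(calls$start[i]), end = max(calls$end[i]),
      frequency = length(unique(calls$genome_id[i])),
      n_calls = length(i),
      class = if (td && hc) "both" else if (td) "tandem" else
        if (hc) "high_copy" else "undetermined",
      stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, ev_list)
  events <- cbind(event_id = paste0("e", sort(unique(event_id))), events,
                  stringsAsFactors = FALSE)
  events$singleton <- events$frequency == 1L
  rownames(events) <- NULL

  spans <- calls$end - calls$start + 1L
  size_classes <- c(
    lt500 = mean(spans < 500),
    b500_1k = mean(spans >= 500 & spans <= 1000),
    gt1k = mean(spans > 1000)
  )
  summary <- list(
    per_genome = table(calls$genome_id),
    size_classes = size_classes,
    n_events = nrow(events),
    n_genome_calls = nrow(calls)
  )
  structure(list(events = events, calls = calls, summary = summary),
            class = "dup_catalog")
}

#' @export
print.dup_catalog <- function(x, ...) {
  cat(sprintf("Duplication catalog: %d population events from %d per-genome calls\n",
              x$summary$n_events, x$summary$n_genome_calls))
  cat(sprintf("  singletons: %d/%d (%.1f%%)\n",
              sum(x$events$singleton), nrow(x$events),
              100 * mean(x$events$singleton)))
  cat(sprintf("  classes: %s\n",
              paste(names(table(x$events$class)), table(x$events$class),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  call spans: %.1f%% < 500 bp, %.1f%% 500 bp-1 kb, %.1f%% > 1 kb\n",
              100 * x$summary$size_classes["lt500"],
              100 * x$summary$size_classes["b500_1k"],
              100 * x$summary$size_classes["gt1k"]))
  invisible(x)
}

#' Score recovery of simulated duplications by a catalog
#'
#' Compares a duplication catalog against the truth set of a
#' [simulate_population()] run.  A truth event is recovered when a call from
#' one of its carrier genomes overlaps its source interval.  A recovered
#' event's class is correct when a tandem event carries tandem evidence
#' (class `tandem` or `both`) and an interspersed event is classified
#' `high_copy` (depth evidence and no spurious split-read evidence).
#'
#' @param sim A `"phs_sim"` object (or any list with an `events` truth data
#'   frame).
#' @param catalog A [collate_population()] result.
#' @param min_length Only truth events at least this long (bp) are scored.
#' @return A list: `n_scored`, `n_recovered`, `recovery`, `n_class_correct`,
#'   `class_accuracy`, and the scored truth table with `recovered` and
#'   `class_correct` columns.
#' @export
score_recovery <- function(sim, catalog, min_length = 200L) {
  truth <- sim$events[sim$events$length >= min_length, , drop = FALSE]
  if (nrow(truth) == 0L) stop("no truth events to score", call. = FALSE)
  calls <- catalog$calls
  carriers <- strsplit(truth$carriers, ",", fixed = TRUE)
  recovered <- logical(nrow(truth))
  cls_td <- logical(nrow(truth)); cls_hc <- logical(nrow(truth))
  for (j in seq_len(nrow(truth))) {
    gids <- paste0("g", carriers[[j]])
    cc <- calls[calls$genome_id %in% gids &
                  calls$end >= truth$start[j] &
                  calls$start <= truth$end[j], , drop = FALSE]
    if (nrow(cc) == 0L) next
    recovered[j] <- TRUE
    if (!is.null(cc$class)) {
      cls_td[j] <- any(cc$class %in% c("tandem", "both"))
      cls_hc[j] <- any(cc$class %in% c("high_copy", "both"))
    }
  }
  class_correct <- ifelse(truth$kind == "tandem", cls_td, cls_hc & !cls_td)
  class_correct[!recovered] <- NA
  truth$recovered <- recovered
  truth$class_correct <- class_correct
  list(
    n_scored = nrow(truth),
    n_recovered = sum(recovered),
    recovery = mean(recovered),
    n_class_correct = sum(class_correct, na.rm = TRUE),
    class_accuracy = if (any(recovered))
      mean(class_correct[recovered]) else NA_real_,
    truth = truth
  )
}
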