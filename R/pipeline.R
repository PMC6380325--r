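#' Run the PHS-duplication pipeline end to end
#'
#' Executes simulate -> mask -> call PHS -> detect (read depth + split
#' read) -> merge/classify -> collate -> frequency statistics on synthetic
#' data, or on caller-supplied tracks.  All thresholds default to the
#' pipeline's canonical values: Q25 base quality, 15-bp read-end distance,
#' at least 5 qualified reads per allele, depth > 8, 6-bp homopolymer and
#' 30-mer repeat masks, 5-bp indel flanks, 400-bp PHS merging, 200-bp depth
#' windows with the strict 2x peak / 1.25x run rule, S1 > 15 split-read
#' support, and the strict 50% overlap classification rule.
#'
#' @param config A [sim_config()]; its seed drives every random draw.
#' @param tracks Optional precomputed `"phs_tracks"` (disables the simulate
#'   stage; a reference must then be given too).
#' @param reference Optional reference sequence when `tracks` are supplied.
#' @param exclude Optional excluded intervals (`chrom`, `start`, `end`).
#' @param gap PHS merge distance in bp.
#' @param stages Character vector of stages to run, in order; later stages
#'   error when an earlier product is missing.
#' @return A list of class `"phs_pipeline"`: `sim` (when simulated), `masks`,
#'   `phs`, `profiles`, `high_copy`, `tandem`, `calls`, `catalog`, `sfs`,
#'   `tests` and `report` (record counts, filter attrition and the applied
#'   thresholds).
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(genome_length = 50000, n_genomes = 6,
#'                                dup_rate = 3, seed = 2))
#' res$report$counts
#' }
#' @export
run_pipeline <- function(config = sim_config(), tracks = NULL,
                         reference = NULL, exclude = NULL, gap = 400,
                         stages = c("simulate", "phs", "detect", "dupcall",
                                    "stats")) {
  t0 <- Sys.time()
  set.seed(config$seed)
  out <- list(config = config)

  if ("simulate" %in% stages) {
    sim <- simulate_population(config)
    out$sim <- sim
    reference <- sim$reference
    tracks <- sim$tracks
  } else if (is.null(tracks) || is.null(reference)) {
    stop("stage 'phs' requires observation tracks and a reference; ",
         "enable the 'simulate' stage or supply `tracks` and `reference`",
         call. = FALSE)
  }

  counts <- c(pileup_observations = nrow(tracks$pileup))
  attrition <- NULL

  if ("phs" %in% stages) {
    out$masks <- build_masks(reference)
    genomes <- unique(tracks$depth$genome_id)
    phs_list <- list()
    n_candidates <- 0L; n_support_fail <- 0L; n_depth_fail <- 0L
    n_masked <- 0L
    for (g in genomes) {
      pp <- tracks$pileup[tracks$pileup$genome_id == g, , drop = FALSE]
      cand <- call_candidate_sites(pp)
      n_candidates <- n_candidates + nrow(cand)
      det <- filter_phs(cand, pp, out$masks, details = TRUE)
      # telescoped attrition: support, then depth, then masks
      n_support_fail <- n_support_fail + sum(!det$pass_support)
      n_depth_fail <- n_depth_fail + sum(det$pass_support & !det$pass_depth)
      n_masked <- n_masked +
        sum(det$pass_support & det$pass_depth & det$masked)
      rec <- det[det$pass, c("genome_id", "chrom", "pos", "allele1",
                             "allele2", "support1", "support2",
                             "total_depth")]
      rownames(rec) <- NULL
      phs_list[[g]] <- rec
    }
    out$phs <- do.call(rbind, phs_list)
    rownames(out$phs) <- NULL
    counts["candidate_sites"] <- n_candidates
    counts["phs"] <- nrow(out$phs)
    attrition <- data.frame(
      filter = c("allele support/quality/position", "total depth", "masks"),
      input = c(n_candidates, n_candidates - n_support_fail,
                n_candidates - n_support_fail - n_depth_fail),
      removed = c(n_support_fail, n_depth_fail, n_masked),
      stringsAsFactors = FALSE)
    attrition$retained <- attrition$input - attrition$removed
  }

  if ("detect" %in% stages) {
    genomes <- unique(tracks$depth$genome_id)
    out$profiles <- lapply(stats::setNames(genomes, genomes), function(g)
      compute_depth_profile(
        tracks$depth[tracks$depth$genome_id == g, , drop = FALSE],
        window = tracks$window_size, masks = out$masks))
    hc <- lapply(genomes, function(g) {
      r <- call_high_copy_regions(out$profiles[[g]])
      if (nrow(r)) r$genome_id <- g
      r
    })
    out$high_copy <- do.call(rbind, hc[vapply(hc, nrow, 0L) > 0])
    if (is.null(out$high_copy))
      out$high_copy <- data.frame(chrom = character(), start = integer(),
                                  end = integer(), genome_id = character(),
                                  stringsAsFactors = FALSE)
    out$tandem <- call_tandem_duplications(tracks$splits,
                                           reference_length = nchar(reference))
    counts["high_copy_regions"] <- nrow(out$high_copy)
    counts["tandem_calls"] <- nrow(out$tandem)
  }

  if ("dupcall" %in% stages) {
    if (is.null(out$phs))
      stop("stage 'dupcall' requires PHS records; enable the 'phs' stage",
           call. = FALSE)
    calls <- merge_phs(out$phs, gap = gap)
    calls <- apply_exclusions(calls, exclude)
    calls <- classify_duplications(calls, out$high_copy, out$tandem)
    out$calls <- calls
    if (nrow(calls)) {
      out$catalog <- collate_population(calls, out$phs)
      counts["phs_duplications"] <- nrow(calls)
      counts["population_events"] <- nrow(out$catalog$events)
    }
  }

  if ("stats" %in% stages && !is.null(out$catalog)) {
    ev <- out$catalog$events
    out$sfs <- sfs(ev$frequency, config$n_genomes)
    out$tests <- list(
      singleton_excess = singleton_excess_test(
        sum(ev$singleton), sum(!ev$singleton), nrow(ev), config$n_genomes)
    )
    counts["singleton_events"] <- sum(ev$singleton)
  }

  thresholds <- c(min_qual = 25, min_end_dist = 15, min_support = 5,
                  min_depth = 8, homopolymer_min = 6, repeat_kmer = 30,
                  indel_flank = 5, gap = gap, window = tracks$window_size,
                  peak_ratio = 2, run_ratio = 1.25, min_s1 = 15,
                  min_overlap = 0.5)
  out$report <- list(counts = counts, attrition = attrition,
                     thresholds = thresholds, seed = config$seed,
                     elapsed = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  structure(out, class = "phs_pipeline")
}

#' @export
print.phs_pipeline <- function(x, ...) {
  cat("PHS-duplication pipeline run (seed", x$report$seed, ")\n")
  for (k in names(x$report$counts))
    cat(sprintf("  %-22s %d\n", k, x$report$counts[[k]]))
  if (!is.null(x$tests$singleton_excess)) {
    cat("  singleton excess: ")
    cat(sprintf("chi-square = %.1f, p = %.3g\n",
                x$tests$singleton_excess$statistic,
                x$tests$singleton_excess$p_value))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$report$elapsed))
  invisible(x)
}
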