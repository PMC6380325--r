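#' Configuration for the haploid-population duplication simulator
#'
#' Bundles all parameters of the synthetic-data generator.  The defaults
#' emulate a desk-scale haploid-embryo resequencing study: 29 haploid genomes,
#' 73-bp effective reads at 30x depth, duplications mostly shorter than 500 bp
#' with post-duplication divergence, and a singleton-skewed population
#' frequency spectrum.  The duplication length distribution is log-normal with
#' `size_meanlog`/`size_sdlog` chosen so that 83.4% of draws fall below
#' 500 bp, 11.3% between 500 bp and 1 kb and 5.3% above 1 kb.
#'
#' @param genome_length Reference length in bp.
#' @param n_genomes Number of haploid genomes in the population (>= 2).
#' @param dup_rate Expected number of duplications carried per genome.
#' @param size_meanlog,size_sdlog Parameters of the log-normal duplication
#'   length distribution (bp scale).
#' @param size_min,size_max Hard bounds on duplication length (bp); draws are
#'   clamped.
#' @param tandem_fraction Probability that a duplication is tandem (copy
#'   adjacent to its source) rather than interspersed.
#' @param divergence_rate Per-bp substitution probability between the two
#'   copies of a duplication.
#' @param frequency_model `"neutral"` draws carrier counts with probability
#'   proportional to 1/i (the standard neutral site frequency spectrum over
#'   i = 1..n-1 carriers); `"singleton_excess"` mixes a point mass at one
#'   carrier (weight `singleton_weight`) with the neutral draw.
#' @param singleton_weight Mixture weight of the singleton point mass.
#' @param read_length Effective read length in bp (default 73, i.e. halved
#'   146-bp reads).
#' @param mean_depth Haploid sequencing depth (reads per bp per copy).
#' @param base_error_rate Per-base sequencing error probability.
#' @param qual_range Integer range base qualities are drawn from (uniform).
#' @param window_size Read-depth window size in bp.
#' @param seed RNG seed used by [simulate_population()].
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(genome_length = 50000, n_genomes = 5, seed = 1)
#' @export
sim_config <- function(genome_length = 3e5,
                       n_genomes = 29,
                       dup_rate = 13,
                       size_meanlog = 5.2446,
                       size_sdlog = 1,
                       size_min = 50,
                       size_max = 5000,
                       tandem_fraction = 0.5,
                       divergence_rate = 0.01,
                       frequency_model = c("singleton_excess", "neutral"),
                       singleton_weight = 0.63,
                       read_length = 73,
                       mean_depth = 30,
                       base_error_rate = 5e-4,
                       qual_range = c(25L, 40L),
                       window_size = 200,
                       seed = 1L) {
  frequency_model <- match.arg(frequency_model)
  .stopifnot_scalar_number(genome_length, "genome_length", 0, strict = TRUE)
  .stopifnot_scalar_number(n_genomes, "n_genomes", 2)
  .stopifnot_scalar_number(dup_rate, "dup_rate", 0, strict = TRUE)
  .stopifnot_scalar_number(size_min, "size_min", 1)
  .stopifnot_scalar_number(size_max, "size_max", size_min)
  .check_rate(tandem_fraction, "tandem_fraction")
  .check_rate(divergence_rate, "divergence_rate")
  .check_rate(singleton_weight, "singleton_weight")
  .check_rate(base_error_rate, "base_error_rate")
  .stopifnot_scalar_number(read_length, "read_length", 1)
  .stopifnot_scalar_number(mean_depth, "mean_depth", 0, strict = TRUE)
  .stopifnot_scalar_number(window_size, "window_size", 1)
  if (genome_length < 10 * size_max)
    stop("`genome_length` must be at least 10 times `size_max`", call. = FALSE)
  if (length(qual_range) != 2L || qual_range[1] > qual_range[2])
    stop("`qual_range` must be c(min, max) with min <= max", call. = FALSE)
  structure(list(
    genome_length = as.integer(genome_length),
    n_genomes = as.integer(n_genomes),
    dup_rate = dup_rate,
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    size_min = as.integer(size_min), size_max = as.integer(size_max),
    tandem_fraction = tandem_fraction,
    divergence_rate = divergence_rate,
    frequency_model = frequency_model,
    singleton_weight = singleton_weight,
    read_length = as.integer(read_length),
    mean_depth = mean_depth,
    base_error_rate = base_error_rate,
    qual_range = as.integer(qual_range),
    window_size = as.integer(window_size),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  genome: %d bp, %d haploid genomes\n",
              x$genome_length, x$n_genomes))
  cat(sprintf("  duplications: %.3g per genome, tandem fraction %.2f, divergence %.3g/bp\n",
              x$dup_rate, x$tandem_fraction, x$divergence_rate))
  cat(sprintf("  frequency model: %s%s\n", x$frequency_model,
              if (x$frequency_model == "singleton_excess")
                sprintf(" (weight %.2f)", x$singleton_weight) else ""))
  cat(sprintf("  reads: %d bp at %gx, error rate %.2g, Q%d-Q%d\n",
              x$read_length, x$mean_depth, x$base_error_rate,
              x$qual_range[1], x$qual_range[2]))
  invisible(x)
}

#' Draw duplication lengths from the configured size distribution
#'
#' Log-normal draws rounded to integer bp and clamped to
#' `[size_min, size_max]`.  With the default parameters 83.4% of draws are
#' shorter than 500 bp.
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Integer vector of lengths in bp.
#' @export
rdup_length <- function(n, config = sim_config()) {
  len <- round(stats::rlnorm(n, config$size_meanlog, config$size_sdlog))
  pmin(pmax(as.integer(len), config$size_min), config$size_max)
}

#' Draw carrier counts from the configured population frequency model
#'
#' Under the neutral model the probability of i carriers (i = 1..n-1) is
#' proportional to 1/i; `"singleton_excess"` adds a point mass at i = 1 with
#' weight `singleton_weight`.
#'
#' @param n Number of draws.
#' @param n_genomes Population size.
#' @param model `"neutral"` or `"singleton_excess"`.
#' @param weight Singleton mixture weight (used by `"singleton_excess"`).
#' @return Integer vector of carrier counts in 1..(n_genomes - 1).
#' @export
draw_carrier_counts <- function(n, n_genomes,
                                model = c("neutral", "singleton_excess"),
                                weight = 0.63) {
  model <- match.arg(model)
  if (n_genomes < 2) stop("`n_genomes` must be >= 2", call. = FALSE)
  i <- seq_len(n_genomes - 1L)
  p <- (1 / i) / sum(1 / i)
  k <- sample.int(n_genomes - 1L, n, replace = TRUE, prob = p)
  if (model == "singleton_excess") {
    k[stats::runif(n) < weight] <- 1L
  }
  k
}

# expected carriers per event under the configured frequency model
.mean_carriers <- function(config) {
  i <- seq_len(config$n_genomes - 1L)
  a <- sum(1 / i)
  e_neutral <- (config$n_genomes - 1L) / a
  switch(config$frequency_model,
    neutral = e_neutral,
    singleton_excess = config$singleton_weight +
      (1 - config$singleton_weight) * e_neutral
  )
}

#' Generate a random reference sequence
#'
#' Uniform random sequence over A/C/G/T, optionally with embedded homopolymer
#' runs and exact repeated segments so that the site masks of
#' [build_masks()] have something to find.
#'
#' @param config A [sim_config()] or a single integer length in bp.
#' @param seed Optional seed; defaults to `config$seed` when a config is
#'   given.  `NULL` leaves the RNG state untouched (used inside
#'   [simulate_population()]).
#' @param homopolymer_runs Number of homopolymer runs to embed.
#' @param homopolymer_length Length of each embedded run (>= 6 to be maskable).
#' @param repeat_copies Number of extra copies of one `repeat_length`-bp
#'   segment to paste elsewhere in the sequence (creates exact repeats).
#' @param repeat_length Length of the repeated segment in bp.
#' @return A single character string.
#' @examples
#' s <- generate_reference(1000, seed = 1)
#' identical(s, generate_reference(1000, seed = 1))
#' @export
generate_reference <- function(config, seed = NULL,
                               homopolymer_runs = 0, homopolymer_length = 8,
                               repeat_copies = 0, repeat_length = 100) {
  if (inherits(config, "sim_config")) {
    len <- config$genome_length
    if (is.null(seed)) seed <- config$seed
  } else {
    len <- config
  }
  if (!is.numeric(len) || length(len) != 1L || is.na(len) || len < 1)
    stop("reference length must be a positive integer", call. = FALSE)
  len <- as.integer(len)
  if (!is.null(seed)) set.seed(seed)
  s <- sample(DNA_BASES, len, replace = TRUE)
  if (homopolymer_runs > 0) {
    if (homopolymer_length > len)
      stop("homopolymer run longer than the reference", call. = FALSE)
    for (i in seq_len(homopolymer_runs)) {
      at <- sample.int(len - homopolymer_length + 1L, 1L)
      s[at:(at + homopolymer_length - 1L)] <- sample(DNA_BASES, 1L)
    }
  }
  if (repeat_copies > 0) {
    if (2 * repeat_length > len)
      stop("repeat segment too long for the reference", call. = FALSE)
    src <- sample.int(len - repeat_length + 1L, 1L)
    unit <- s[src:(src + repeat_length - 1L)]
    for (i in seq_len(repeat_copies)) {
      at <- sample.int(len - repeat_length + 1L, 1L)
      s[at:(at + repeat_length - 1L)] <- unit
    }
  }
  paste(s, collapse = "")
}

#' Inject segmental duplications into a haploid population
#'
#' Draws duplication events (length, tandem/interspersed kind, carrier set,
#' divergent sites), places them without overlap on the reference, and builds
#' the mutated carrier genomes.  Each event's copy differs from its source at
#' `Binomial(L, divergence_rate)` positions; all derived alleles are placed on
#' the new copy.  Source intervals are separated by at least `min_gap` bp so
#' that distinct events stay distinguishable under downstream PHS merging.
#'
#' @param reference Reference sequence (single character string).
#' @param config A [sim_config()].
#' @param n_events Number of population events; by default derived from
#'   `config$dup_rate` and the mean carrier count of the frequency model.
#' @param min_gap Minimum bp between placed source intervals.
#' @return A list with elements `events` (one row per event: `event_id`,
#'   `start`, `end`, `length`, `kind`, `dest`, `n_carriers`, `carriers`
#'   (comma-separated genome ids), `n_divergent`), `div_sites` (one row per
#'   divergent site: `event_id`, `offset`, `pos`, `ref_allele`,
#'   `alt_allele`), and `genomes` (list of mutated sequences named
#'   `g1..gn`).
#' @export
inject_duplications <- function(reference, config, n_events = NULL,
                                min_gap = 600L) {
  L <- nchar(reference)
  if (L < config$genome_length)
    stop("reference shorter than `config$genome_length`", call. = FALSE)
  if (is.null(n_events)) {
    n_events <- max(1L, as.integer(round(
      config$dup_rate * config$n_genomes / .mean_carriers(config))))
  }
  lens <- rdup_length(n_events, config)
  if (any(lens > L))
    stop("duplication length exceeds the genome length", call. = FALSE)

  # non-overlapping placement with a minimum separation
  placed <- IRanges::IRanges()
  starts <- integer(n_events)
  for (j in seq_len(n_events)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      st <- sample.int(L - lens[j] + 1L, 1L)
      cand <- IRanges::IRanges(max(1L, st - min_gap),
                               min(L, st + lens[j] - 1L + min_gap))
      if (!any(IRanges::overlapsAny(cand, placed))) {
        placed <- c(placed, IRanges::IRanges(st, st + lens[j] - 1L))
        starts[j] <- st
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place all duplications; lower `dup_rate` or enlarge the genome",
           call. = FALSE)
  }
  ends <- starts + lens - 1L
  kind <- ifelse(stats::runif(n_events) < config$tandem_fraction,
                 "tandem", "interspersed")
  # interspersed copies land at a random position outside any source interval
  dest <- integer(n_events)
  for (j in seq_len(n_events)) {
    if (kind[j] == "tandem") {
      dest[j] <- ends[j] + 1L   # copy adjoins the source end
    } else {
      repeat {
        d <- sample.int(L, 1L)
        if (!any(d >= starts & d <= ends)) break
      }
      dest[j] <- d
    }
  }
  carriers_n <- draw_carrier_counts(n_events, config$n_genomes,
                                    config$frequency_model,
                                    config$singleton_weight)
  carrier_sets <- lapply(carriers_n, function(k)
    sort(sample.int(config$n_genomes, k)))

  # divergent sites between the two copies
  n_div <- stats::rbinom(n_events, lens, config$divergence_rate)
  div_list <- vector("list", n_events)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  for (j in seq_len(n_events)) {
    if (n_div[j] == 0L) next
    off <- sort(sample.int(lens[j], n_div[j]))
    pos <- starts[j] + off - 1L
    ra <- ref_chars[pos]
    aa <- vapply(ra, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    div_list[[j]] <- data.frame(event_id = j, offset = off, pos = pos,
                                ref_allele = ra, alt_allele = unname(aa),
                                stringsAsFactors = FALSE)
  }
  div_sites <- if (any(n_div > 0L)) do.call(rbind, div_list) else
    .empty_df(data.frame(event_id = integer(), offset = integer(),
                         pos = integer(), ref_allele = character(),
                         alt_allele = character(), stringsAsFactors = FALSE))
  rownames(div_sites) <- NULL

  events <- data.frame(
    event_id = seq_len(n_events),
    start = starts, end = ends, length = lens,
    kind = kind, dest = dest,
    n_carriers = carriers_n,
    carriers = vapply(carrier_sets, paste, "", collapse = ","),
    n_divergent = n_div,
    stringsAsFactors = FALSE
  )

  # mutated genomes: insert the (diverged) copy after its destination point
  genomes <- vector("list", config$n_genomes)
  names(genomes) <- paste0("g", seq_len(config$n_genomes))
  for (g in seq_len(config$n_genomes)) {
    carried <- which(vapply(carrier_sets, function(s) g %in% s, logical(1)))
    if (length(carried) == 0L) {
      genomes[[g]] <- reference
      next
    }
    pieces <- character(0)
    cursor <- 1L
    ins_at <- dest[carried]   # insert after this reference position
    ord <- order(ins_at)
    for (j in carried[ord]) {
      copy <- ref_chars[starts[j]:ends[j]]
      ds <- div_list[[j]]
      if (!is.null(ds)) copy[ds$offset] <- ds$alt_allele
      pieces <- c(pieces,
                  substr(reference, cursor, dest[j]),
                  paste(copy, collapse = ""))
      cursor <- dest[j] + 1L
    }
    pieces <- c(pieces, substr(reference, cursor, L))
    genomes[[g]] <- paste(pieces, collapse = "")
  }

  list(events = events, div_sites = div_sites, genomes = genomes)
}

# per-genome list of carried event indices
.carried_index <- function(events, n_genomes) {
  sets <- strsplit(events$carriers, ",", fixed = TRUE)
  lapply(seq_len(n_genomes), function(g)
    which(vapply(sets, function(s) as.character(g) %in% s, logical(1))))
}

#' Simulate mapped-read observation tracks for a haploid population
#'
#' Emulates what a short-read mapper produces when every copy of a duplicated
#' segment maps back to its single reference locus: pileup columns carrying
#' both alleles at divergent sites (the pseudoheterozygosity mechanism),
#' split-read clusters at tandem breakpoints, and read-depth values per
#' window that scale with copy number.  Reads themselves are not emitted;
#' pileup columns are generated sparsely at informative positions (divergent
#' sites of carried duplications and positions hit by sequencing errors) -
#' fully reference-consistent columns carry no information for PHS calling.
#'
#' @param truth Result of [inject_duplications()] (only `events` and
#'   `div_sites` are used).
#' @param reference The reference sequence.
#' @param config A [sim_config()].
#' @return A list of class `"phs_tracks"` with data frames `pileup`
#'   (`genome_id`, `chrom`, `pos`, `base`, `qual`, `off5`, `off3`; one row per
#'   read observation), `splits` (`genome_id`, `chrom`, `bp1`, `bp2`,
#'   `n_forward`, `n_reverse`) and `depth` (`genome_id`, `chrom`, `start`,
#'   `depth`; one row per `window_size` window).
#' @export
simulate_observations <- function(truth, reference, config) {
  events <- truth$events
  div <- truth$div_sites
  L <- config$genome_length
  rl <- config$read_length
  qr <- config$qual_range
  carried <- .carried_index(events, config$n_genomes)
  ref_chars <- strsplit(substr(reference, 1L, L), "", fixed = TRUE)[[1]]

  rand_other <- function(base) {
    # random base different from `base`, vectorised
    idx <- match(base, DNA_BASES)
    shift <- sample.int(3L, length(base), replace = TRUE)
    DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  obs_df <- function(genome, pos, base) {
    n <- length(pos)
    err <- stats::runif(n) < config$base_error_rate
    if (any(err)) base[err] <- rand_other(base[err])
    off5 <- sample.int(rl, n, replace = TRUE) - 1L
    data.frame(genome_id = genome, chrom = "ref", pos = pos, base = base,
               qual = sample(seq(qr[1], qr[2]), n, replace = TRUE),
               off5 = off5, off3 = rl - 1L - off5,
               stringsAsFactors = FALSE)
  }

  pile <- list(); spl <- list(); dep <- list()
  n_win <- L %/% config$window_size
  win_start <- (seq_len(n_win) - 1L) * config$window_size + 1L
  win_ir <- IRanges::IRanges(win_start, win_start + config$window_size - 1L)
  efflen <- config$window_size + rl - 1L
  flank <- 10L  # bp required on each side of a junction to split-map a read

  for (g in seq_len(config$n_genomes)) {
    ev <- carried[[g]]
    src <- .as_iranges(events[ev, c("start", "end"), drop = FALSE])

    # pileup at divergent sites: one read set per copy
    dg <- div[div$event_id %in% ev, , drop = FALSE]
    if (nrow(dg)) {
      n1 <- stats::rpois(nrow(dg), config$mean_depth)
      n2 <- stats::rpois(nrow(dg), config$mean_depth)
      pile[[length(pile) + 1L]] <- obs_df(
        paste0("g", g),
        c(rep(dg$pos, n1), rep(dg$pos, n2)),
        c(rep(dg$ref_allele, n1), rep(dg$alt_allele, n2))
      )
    }

    # pileup at error-hit positions (plus their reference-supporting reads)
    n_err <- stats::rpois(1L, L * config$mean_depth * config$base_error_rate)
    if (n_err > 0L) {
      epos <- sample.int(L, n_err, replace = TRUE)
      epos <- setdiff(epos, dg$pos)
      if (length(epos)) {
        cn <- 1L + IRanges::countOverlaps(IRanges::IRanges(epos, epos), src)
        nref <- stats::rpois(length(epos), cn * config$mean_depth)
        err_rows <- obs_df(paste0("g", g), epos, rand_other(ref_chars[epos]))
        ref_rows <- obs_df(paste0("g", g), rep(epos, nref),
                           rep(ref_chars[epos], nref))
        pile[[length(pile) + 1L]] <- rbind(err_rows, ref_rows)
      }
    }

    # split-read clusters at tandem junctions
    tev <- ev[events$kind[ev] == "tandem"]
    if (length(tev)) {
      lam <- config$mean_depth * max(rl - 2L * flank, 0L) / rl
      n_sup <- stats::rpois(length(tev), lam)
      keep <- n_sup > 0L
      if (any(keep)) {
        fwd <- stats::rbinom(sum(keep), n_sup[keep], 0.5)
        spl[[length(spl) + 1L]] <- data.frame(
          genome_id = paste0("g", g), chrom = "ref",
          bp1 = events$start[tev[keep]], bp2 = events$end[tev[keep]],
          n_forward = fwd, n_reverse = n_sup[keep] - fwd,
          stringsAsFactors = FALSE)
      }
    }

    # window read depth scaled by mean copy number over the window
    cnbar <- 1 + .overlap_bp(win_start, win_start + config$window_size - 1L,
                             src) / config$window_size
    k <- stats::rpois(n_win, config$mean_depth * cnbar * efflen / rl)
    dep[[length(dep) + 1L]] <- data.frame(
      genome_id = paste0("g", g), chrom = "ref", start = win_start,
      depth = k * rl / efflen, stringsAsFactors = FALSE)
  }

  pileup <- if (length(pile)) do.call(rbind, pile) else
    .empty_df(data.frame(genome_id = character(), chrom = character(),
                         pos = integer(), base = character(), qual = integer(),
                         off5 = integer(), off3 = integer(),
                         stringsAsFactors = FALSE))
  pileup <- pileup[order(pileup$genome_id, pileup$pos), , drop = FALSE]
  rownames(pileup) <- NULL
  splits <- if (length(spl)) do.call(rbind, spl) else
    .empty_df(data.frame(genome_id = character(), chrom = character(),
                         bp1 = integer(), bp2 = integer(),
                         n_forward = integer(), n_reverse = integer(),
                         stringsAsFactors = FALSE))
  rownames(splits) <- NULL
  depth <- do.call(rbind, dep)
  rownames(depth) <- NULL
  structure(list(pileup = pileup, splits = splits, depth = depth,
                 window_size = config$window_size), class = "phs_tracks")
}

#' @export
print.phs_tracks <- function(x, ...) {
  cat("Observation tracks:",
      nrow(x$pileup), "pileup observations,",
      nrow(x$splits), "split-read clusters,",
      nrow(x$depth), "depth windows\n")
  invisible(x)
}

#' Simulate a haploid population with segmental duplications
#'
#' End-to-end generator: reference, duplication truth set, mutated genomes and
#' observation tracks, all deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `"phs_sim"` with elements `reference`, `config`,
#'   `events`, `div_sites`, `genomes` and `tracks`.
#' @examples
#' sim <- simulate_population(sim_config(genome_length = 50000, n_genomes = 4,
#'                                       dup_rate = 2, seed = 7))
#' sim$events[, c("start", "end", "kind", "n_carriers")]
#' @export
simulate_population <- function(config = sim_config()) {
  set.seed(config$seed)
  reference <- generate_reference(config, seed = NULL)
  truth <- inject_duplications(reference, config)
  tracks <- simulate_observations(truth, reference, config)
  structure(list(reference = reference, config = config,
                 events = truth$events, div_sites = truth$div_sites,
                 genomes = truth$genomes, tracks = tracks),
            class = "phs_sim")
}

#' @export
print.phs_sim <- function(x, ...) {
  cat(sprintf("Synthetic haploid population: %d genomes, %d bp reference\n",
              x$config$n_genomes, x$config$genome_length))
  cat(sprintf("  %d duplication events (%d tandem, %d interspersed), %d divergent sites\n",
              nrow(x$events), sum(x$events$kind == "tandem"),
              sum(x$events$kind == "interspersed"), nrow(x$div_sites)))
  print(x$tracks)
  invisible(x)
}
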