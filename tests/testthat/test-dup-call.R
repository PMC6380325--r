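test_that("PHS merging applies the gap rule and keeps singleton calls", {
  phs <- data.frame(genome_id = "g1", chrom = "ref",
                    pos = c(1000, 1350, 1800))
  calls <- merge_phs(phs, gap = 400)
  expect_equal(nrow(calls), 2)        # 350 <= 400 joins; 450 > 400 splits
  expect_equal(calls$start, c(1000, 1800))
  expect_equal(calls$end, c(1350, 1800))
  expect_equal(calls$phs_count, c(2, 1))
  expect_equal(calls$length, c(351, 1))

  single <- merge_phs(data.frame(genome_id = "g1", chrom = "ref", pos = 500))
  expect_equal(nrow(single), 1)
  expect_equal(single$phs_count, 1)
  expect_equal(single$length, 1)
})

test_that("merging equals the brute-force gap partition on random input", {
  set.seed(41)
  for (i in 1:40) {
    pos <- sort(sample.int(5e5, 250))
    gap <- sample(c(100, 200, 300, 400, 500, 600), 1)
    phs <- data.frame(genome_id = "g1", chrom = "ref", pos = pos)
    calls <- merge_phs(phs, gap = gap)
    blocks <- oracle_gap_partition(pos, gap)
    expect_equal(nrow(calls), length(blocks))
    expect_equal(calls$start, vapply(blocks, min, numeric(1)))
    expect_equal(calls$end, vapply(blocks, max, numeric(1)))
    expect_equal(calls$phs_count, lengths(blocks))
    # partition property: every PHS in exactly one call
    expect_equal(sum(calls$phs_count), length(pos))
  }
  # one large input against the oracle
  pos <- sort(sample.int(2e7, 10000))
  calls <- merge_phs(data.frame(genome_id = "g1", chrom = "ref", pos = pos),
                     gap = 400)
  blocks <- oracle_gap_partition(pos, 400)
  expect_equal(calls$phs_count, lengths(blocks))
})

test_that("call counts are non-increasing in the merge gap", {
  set.seed(42)
  pos <- sort(sample.int(1e6, 2000))
  phs <- data.frame(genome_id = "g1", chrom = "ref", pos = pos)
  n <- vapply(c(0, 100, 200, 300, 400, 500, 600),
              function(g) nrow(merge_phs(phs, gap = g)), integer(1))
  expect_true(all(diff(n) <= 0))
  expect_equal(n[1], length(unique(pos)))   # gap 0: no merging
})

test_that("merging is per genome and per chromosome", {
  phs <- data.frame(genome_id = c("g1", "g2"), chrom = "ref",
                    pos = c(1000, 1100))
  expect_equal(nrow(merge_phs(phs, gap = 400)), 2)
  phs2 <- data.frame(genome_id = "g1", chrom = c("2L", "2R"),
                     pos = c(1000, 1100))
  expect_equal(nrow(merge_phs(phs2, gap = 400)), 2)
})

test_that("exclusions remove overlapping calls and flag giant spans", {
  calls <- merge_phs(data.frame(genome_id = "g1", chrom = "ref",
                                pos = c(1000, 1200, 50000)))
  ex <- data.frame(chrom = "ref", start = 900, end = 1500)
  kept <- apply_exclusions(calls, ex)
  expect_equal(kept$start, 50000)
  # empty exclusion list is the identity
  all_kept <- apply_exclusions(calls, NULL)
  expect_equal(all_kept[, names(calls)], calls)
  expect_false(any(all_kept$span_flagged))
  # a synthetic 30-kb span is flagged at the 28-kb threshold
  big <- merge_phs(data.frame(genome_id = "g1", chrom = "ref",
                              pos = seq(1000, 31000, by = 300)))
  expect_true(apply_exclusions(big)$span_flagged)
})

test_that("classification applies the strict 50% overlap rule", {
  calls <- data.frame(call_id = "c1", genome_id = "g1", chrom = "ref",
                      start = 101L, end = 500L, phs_count = 4L, length = 400L)
  hc300 <- data.frame(genome_id = "g1", chrom = "ref", start = 1, end = 400)
  expect_equal(classify_duplications(calls, hc300)$class, "high_copy")   # 75%
  hc200 <- data.frame(genome_id = "g1", chrom = "ref", start = 1, end = 300)
  expect_equal(classify_duplications(calls, hc200)$class, "undetermined") # 50%
  td <- data.frame(genome_id = "g1", chrom = "ref", start = 1, end = 450)
  expect_equal(classify_duplications(calls, hc300, td)$class, "both")
  expect_equal(classify_duplications(calls, NULL, td)$class, "tandem")
  # evidence from another genome does not classify this genome's call
  hc_other <- hc300
  hc_other$genome_id <- "g2"
  expect_equal(classify_duplications(calls, hc_other)$class, "undetermined")
})

test_that("classification is stable under coordinate translation", {
  set.seed(43)
  calls <- merge_phs(data.frame(genome_id = "g1", chrom = "ref",
                                pos = sort(sample.int(1e5, 300))))
  hc <- data.frame(genome_id = "g1", chrom = "ref",
                   start = seq(1, 9e4, by = 5000),
                   end = seq(1, 9e4, by = 5000) + 1999)
  base <- classify_duplications(calls, hc)$class
  shift <- 1000L
  calls2 <- calls
  calls2$start <- calls2$start + shift; calls2$end <- calls2$end + shift
  hc2 <- hc
  hc2$start <- hc2$start + shift; hc2$end <- hc2$end + shift
  expect_equal(classify_duplications(calls2, hc2)$class, base)
})

test_that("population collation unions calls sharing PHS positions", {
  phs <- rbind(
    data.frame(genome_id = "g1", chrom = "ref", pos = c(1000, 1200)),
    data.frame(genome_id = "g2", chrom = "ref", pos = c(1200, 1300)),
    data.frame(genome_id = "g3", chrom = "ref", pos = 9000)
  )
  calls <- merge_phs(phs)
  cat <- collate_population(calls, phs)
  expect_equal(nrow(cat$events), 2)
  shared <- cat$events[cat$events$start == 1000, ]
  expect_equal(shared$frequency, 2)
  expect_false(shared$singleton)
  lone <- cat$events[cat$events$start == 9000, ]
  expect_equal(lone$frequency, 1)
  expect_true(lone$singleton)

  # disjoint calls stay distinct singleton events
  phs2 <- rbind(
    data.frame(genome_id = "g1", chrom = "ref", pos = 1000),
    data.frame(genome_id = "g2", chrom = "ref", pos = 5000)
  )
  cat2 <- collate_population(merge_phs(phs2), phs2)
  expect_equal(cat2$events$frequency, c(1, 1))
})

test_that("shared-position identity is transitive across genomes", {
  phs <- rbind(
    data.frame(genome_id = "g1", chrom = "ref", pos = c(100, 200)),
    data.frame(genome_id = "g2", chrom = "ref", pos = c(200, 300)),
    data.frame(genome_id = "g3", chrom = "ref", pos = c(300, 400))
  )
  cat <- collate_population(merge_phs(phs), phs)
  expect_equal(nrow(cat$events), 1)
  expect_equal(cat$events$frequency, 3)
})

test_that("overlap identity is available behind a flag", {
  phs <- rbind(
    data.frame(genome_id = "g1", chrom = "ref", pos = c(1000, 1400)),
    data.frame(genome_id = "g2", chrom = "ref", pos = c(1200, 1600))
  )
  calls <- merge_phs(phs)
  # no shared positions: two events under the conservative rule
  expect_equal(nrow(collate_population(calls, phs)$events), 2)
  # interval overlap: one event
  expect_equal(nrow(collate_population(calls, identity = "overlap")$events), 1)
})

test_that("simulated frequencies are recovered exactly at full sensitivity", {
  cfg <- sim_config(genome_length = 1e5, n_genomes = 8, dup_rate = 4,
                    mean_depth = 60, divergence_rate = 0.02,
                    base_error_rate = 0, seed = 44)
  sim <- simulate_population(cfg)
  phs <- call_phs(sim$tracks$pileup, build_masks(sim$reference))
  calls <- merge_phs(phs)
  cat <- collate_population(calls, phs)
  # every truth event with at least one unmasked, recovered divergent site
  # must appear with its exact carrier frequency
  sets <- strsplit(sim$events$carriers, ",")
  for (j in seq_len(nrow(sim$events))) {
    sites <- sim$div_sites$pos[sim$div_sites$event_id == j]
    sites <- sites[sites %in% phs$pos]
    if (length(sites) == 0L) next
    ev <- cat$events[cat$events$start <= max(sites) &
                       cat$events$end >= min(sites), ]
    expect_equal(nrow(ev), 1)
    expect_equal(ev$frequency, length(sets[[j]]))
  }
})

test_that("undetermined fraction falls as depth improves split-read evidence", {
  frac_undet <- function(depth, seed) {
    cfg <- sim_config(genome_length = 1.5e5, n_genomes = 6, dup_rate = 5,
                      tandem_fraction = 1, mean_depth = depth, seed = seed)
    res <- run_pipeline(cfg)
    mean(res$catalog$events$class == "undetermined")
  }
  expect_lt(frac_undet(40, 45), frac_undet(12, 45))
})
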