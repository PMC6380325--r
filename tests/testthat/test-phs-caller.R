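test_that("homopolymer mask covers runs of six or more identical bases", {
  m <- build_masks(strrep("ACGT", 10))
  expect_equal(length(m$homopolymer), 0)
  s <- paste0(strrep("ACGT", 10), "AAAAAA", strrep("GTCA", 10))
  m <- build_masks(s)
  expect_equal(IRanges::start(m$homopolymer), 41)
  expect_equal(IRanges::end(m$homopolymer), 46)
  expect_error(build_masks(""), "non-empty")
})

test_that("repeat mask equals a hash-table k-mer counting oracle", {
  set.seed(21)
  # a random sequence with one duplicated 100-mer
  ref <- generate_reference(4000, seed = 21, repeat_copies = 1,
                            repeat_length = 100)
  m <- build_masks(ref, k = 30)
  got <- sort(unlist(mapply(seq, IRanges::start(m$repeats),
                            IRanges::end(m$repeats), SIMPLIFY = FALSE)))
  expect_equal(got, oracle_kmer_repeats(ref, 30))
  expect_gt(length(got), 0)
})

test_that("indel mask requires GQ > 30 and > 5 reads, extended by 5 bp", {
  ref <- generate_reference(500, seed = 22)
  indels <- data.frame(pos = c(100, 200, 300), length = c(2, 3, -4),
                       genotype_quality = c(50, 30, 50),
                       supporting_reads = c(10, 10, 5))
  m <- build_masks(ref, indels)
  # only the first indel qualifies (second fails GQ, third fails reads)
  expect_equal(length(m$indel), 1)
  expect_equal(IRanges::start(m$indel), 95)
  expect_equal(IRanges::end(m$indel), 107)
  expect_error(build_masks(ref, data.frame(pos = 1, length = 0,
                                           genotype_quality = 50,
                                           supporting_reads = 10)),
               "nonzero")
})

test_that("candidate calling keeps biallelic columns only", {
  mono <- pileup_column(10, list(list(base = "A", n = 10)))
  expect_equal(nrow(call_candidate_sites(mono)), 0)

  bi <- pileup_column(10, list(list(base = "A", n = 10),
                               list(base = "G", n = 10)))
  cand <- call_candidate_sites(bi)
  expect_equal(nrow(cand), 1)
  expect_equal(sort(c(cand$allele1, cand$allele2)), c("A", "G"))
  expect_equal(cand$total_depth, 20)

  tri <- pileup_column(10, list(list(base = "A", n = 8),
                                list(base = "G", n = 6),
                                list(base = "T", n = 3)))
  expect_equal(nrow(call_candidate_sites(tri)), 0)

  unsorted <- rbind(pileup_column(20, list(list(base = "A", n = 2))),
                    pileup_column(10, list(list(base = "A", n = 2))))
  expect_error(call_candidate_sites(unsorted), "sorted")
})

test_that("the PHS filter applies the support, depth and mask rules strictly", {
  col_at <- function(pos, n1 = 5, n2 = 5, qual = 30, off5 = 30, extra = 0) {
    alleles <- list(list(base = "A", n = n1, qual = qual, off5 = off5),
                    list(base = "G", n = n2, qual = qual, off5 = off5))
    if (extra > 0)
      alleles <- c(alleles, list(list(base = "A", n = extra, qual = 10,
                                      off5 = 0)))
    pileup_column(pos, alleles)
  }
  run <- function(pp, masks = NULL) filter_phs(call_candidate_sites(pp), pp,
                                               masks)

  # all thresholds met: depth 10 with 5+5 well-placed Q30 reads
  expect_equal(nrow(run(col_at(100))), 1)

  # depth exactly 8 is rejected ("larger than eight" is strict)
  expect_equal(nrow(run(col_at(100, n1 = 4, n2 = 4))), 0)
  # depth 9 with 5/4 support fails the 5-read rule instead
  expect_equal(nrow(run(col_at(100, n1 = 5, n2 = 4))), 0)
  # 4 well-positioned reads on one allele rejected even at high depth
  pp <- rbind(
    pileup_column(100, list(list(base = "A", n = 6, qual = 30, off5 = 30),
                            list(base = "G", n = 4, qual = 30, off5 = 30),
                            list(base = "G", n = 4, qual = 30, off5 = 5))))
  expect_equal(nrow(run(pp)), 0)
  # quality below Q25 does not count toward support
  expect_equal(nrow(run(col_at(100, qual = 24))), 0)
  # offsets under 15 bp from either end do not count
  expect_equal(nrow(run(col_at(100, off5 = 14))), 0)
  expect_equal(nrow(run(col_at(100, off5 = 58))), 0)  # 73-bp read: off3 = 14

  # a low-quality extra read raises depth but not support: still a PHS
  r <- run(col_at(100, n1 = 5, n2 = 5, extra = 3))
  expect_equal(nrow(r), 1)
  expect_equal(r$total_depth, 13)
  expect_equal(r$support1, 5)

  # masked positions are dropped
  ref <- generate_reference(200, seed = 26)
  substr(ref, 97, 102) <- "AAAAAA"   # homopolymer run at 97..102
  masks <- build_masks(ref)
  expect_equal(nrow(run(col_at(100), masks)), 0)
  expect_equal(nrow(run(col_at(50), masks)), 1)
})

test_that("the filter is a pure per-candidate function (order invariance)", {
  set.seed(23)
  cols <- lapply(seq(100, 1900, by = 100), function(p)
    pileup_column(p, list(list(base = "A", n = sample(3:8, 1)),
                          list(base = "C", n = sample(3:8, 1)))))
  pp <- do.call(rbind, cols)
  cand <- call_candidate_sites(pp)
  out1 <- filter_phs(cand, pp)
  perm <- sample(nrow(cand))
  out2 <- filter_phs(cand[perm, ], pp)
  out2 <- out2[order(out2$pos), ]
  rownames(out2) <- NULL
  expect_equal(out1, out2)
})

test_that("no PHS are called on error-free data without duplications", {
  cfg <- sim_config(genome_length = 30000, n_genomes = 3, dup_rate = 1, size_max = 3000,
                    divergence_rate = 0, base_error_rate = 0, seed = 24)
  sim <- simulate_population(cfg)
  masks <- build_masks(sim$reference)
  phs <- call_phs(sim$tracks$pileup, masks)
  expect_equal(nrow(phs), 0)
})

test_that("divergent sites of 2-copy duplications are retained at >= 90%", {
  cfg <- sim_config(genome_length = 2e5, n_genomes = 4, dup_rate = 6,
                    mean_depth = 30, divergence_rate = 0.01, seed = 25)
  sim <- simulate_population(cfg)
  masks <- build_masks(sim$reference)
  sets <- strsplit(sim$events$carriers, ",")
  hits <- 0L; total <- 0L
  for (g in seq_len(cfg$n_genomes)) {
    pp <- sim$tracks$pileup[sim$tracks$pileup$genome_id == paste0("g", g), ]
    phs <- call_phs(pp, masks)
    carried <- vapply(sets, function(s) as.character(g) %in% s, logical(1))
    want <- sim$div_sites$pos[sim$div_sites$event_id %in%
                                sim$events$event_id[carried]]
    # exclude truth sites that fall in masked regions: the filter is meant
    # to reject those
    if (length(want)) {
      masked <- IRanges::overlapsAny(IRanges::IRanges(want, want),
                                     c(masks$homopolymer, masks$repeats))
      want <- want[!masked]
    }
    total <- total + length(want)
    hits <- hits + sum(want %in% phs$pos)
  }
  expect_gt(total, 50)
  expect_gte(hits / total, 0.9)
})
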