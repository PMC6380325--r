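toy_annotation <- function() {
  # 100-kb chromosome: gene at 10k-20k with CDS/UTR/intron structure,
  # second gene at 50k-60k whose intron overlaps a CDS of a nested gene
  build_annotation(
    cds = data.frame(chrom = "chr1", start = c(11001, 15001, 52001),
                     end = c(12000, 16000, 53000)),
    utr5 = data.frame(chrom = "chr1", start = 10001, end = 11000),
    utr3 = data.frame(chrom = "chr1", start = 16001, end = 17000),
    intron = data.frame(chrom = "chr1", start = c(12001, 50001),
                        end = c(15000, 60000)),
    chrom_lengths = c(chr1 = 1e5)
  )
}

test_that("region assignment follows the CDS-first priority", {
  ann <- toy_annotation()
  items <- data.frame(chrom = "chr1",
                      pos = c(11500,  # CDS
                              10500,  # 5'UTR
                              16500,  # 3'UTR
                              13000,  # intron
                              52500,  # intron of one gene, CDS of another
                              90000)) # intergenic
  got <- assign_regions(items, ann)$region
  expect_equal(got, c("CDS", "5'UTR", "3'UTR", "intron", "CDS", "intergenic"))
  expect_error(assign_regions(data.frame(chrom = "chr1", pos = 2e5), ann),
               "bounds")
})

test_that("region lengths partition the genome", {
  ann <- toy_annotation()
  len <- region_lengths(ann)
  expect_equal(sum(len), 1e5)
  expect_equal(unname(len["cds"]), 3000)
  # the CDS bp nested in the intron are not double counted
  expect_equal(unname(len["intron"]), 3000 + 10000 - 1000)
})

test_that("region chi-square matches a hand-computed statistic", {
  # all 200 sites in a region covering 10% of the genome
  counts <- c(cds = 200, intergenic = 0)
  lengths <- c(cds = 1e4, intergenic = 9e4)
  res <- region_chi_square(counts, lengths)
  stat_hand <- (200 - 20)^2 / 20 + (0 - 180)^2 / 180
  expect_equal(res$statistic[res$region == "cds"], stat_hand)
  expect_equal(res$direction, c(1, -1))

  # counts exactly proportional to lengths: no deviation anywhere
  res0 <- region_chi_square(c(a = 10, b = 90), c(a = 1e4, b = 9e4))
  expect_true(all(res0$statistic < 1e-12))
  expect_true(all(res0$p > 0.999))

  expect_warning(region_chi_square(c(a = 1, b = 1), c(a = 0, b = 10)),
                 "zero-length")
})

test_that("region chi-square is calibrated on uniform random sites", {
  ann <- toy_annotation()
  len <- region_lengths(ann)
  set.seed(61)
  reject <- 0L
  for (r in 1:400) {
    sites <- data.frame(chrom = "chr1", pos = sample.int(1e5, 200))
    lab <- assign_regions(sites, ann)$region
    counts <- c(cds = sum(lab == "CDS"), utr5 = sum(lab == "5'UTR"),
                utr3 = sum(lab == "3'UTR"), intron = sum(lab == "intron"),
                intergenic = sum(lab == "intergenic"))
    res <- region_chi_square(counts, len)
    reject <- reject + (res$p[res$region == "intergenic"] < 0.05)
  }
  expect_gt(reject / 400, 0.02)
  expect_lt(reject / 400, 0.09)
})

test_that("permutation enrichment handles the degenerate tracks", {
  set.seed(62)
  calls <- data.frame(chrom = "chr1", start = c(100, 5000, 20000),
                      end = c(499, 5399, 20399))
  full <- data.frame(chrom = "chr1", start = 1, end = 1e5)
  r <- permutation_enrichment(calls, full, c(chr1 = 1e5), n_perm = 200)
  expect_equal(r$observed, 3)
  expect_equal(r$ratio, 1)
  expect_equal(r$p_upper, 1)  # cannot beat a full-coverage track

  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  r0 <- permutation_enrichment(calls, empty, c(chr1 = 1e5), n_perm = 200)
  expect_equal(r0$observed, 0)
  expect_equal(r0$ratio, 0)
  expect_equal(r0$p_lower, 1)
  expect_warning(permutation_enrichment(calls, full, c(chr1 = 1e5),
                                        n_perm = 50), "100")
})

test_that("planted depletion is detected with the empirical-p formula", {
  set.seed(63)
  # track covering half the genome; calls placed only outside it
  track <- data.frame(chrom = "chr1", start = seq(1, 9e4, by = 2e4),
                      end = seq(1, 9e4, by = 2e4) + 9999)
  starts <- sample(seq(12000, 92000, by = 2e4), 30, replace = TRUE)
  calls <- data.frame(chrom = "chr1", start = starts, end = starts + 399)
  r <- permutation_enrichment(calls, track, c(chr1 = 1e5), n_perm = 1000)
  expect_equal(r$observed, 0)
  expect_lt(r$p_lower, 0.005)
  expect_gte(r$p_lower, 1 / 1001)   # pseudocount floor: p is never 0
  expect_lte(r$p_two_sided, 1)
})

test_that("empirical p-values are near-uniform under the null", {
  set.seed(64)
  track <- data.frame(chrom = "chr1", start = seq(1, 9.6e4, by = 8000),
                      end = seq(1, 9.6e4, by = 8000) + 2399)  # 30% coverage
  pvals <- numeric(150)
  for (r in 1:150) {
    starts <- sample.int(99600, 25)
    calls <- data.frame(chrom = "chr1", start = starts, end = starts + 399)
    pvals[r] <- permutation_enrichment(calls, track, c(chr1 = 1e5),
                                       n_perm = 150)$p_upper
  }
  expect_true(all(pvals >= 1 / 151 & pvals <= 1))
  # rejection at 0.05 within a generous calibration band
  expect_lt(mean(pvals <= 0.05), 0.11)
  expect_gt(mean(pvals <= 0.25), 0.12)
})

test_that("permutation results are seed-reproducible and order-invariant", {
  track <- data.frame(chrom = "chr1", start = c(1000, 40000, 70000),
                      end = c(6000, 45000, 75000))
  calls <- data.frame(chrom = "chr1", start = c(2000, 50000),
                      end = c(2399, 50399))
  set.seed(65)
  r1 <- permutation_enrichment(calls, track, c(chr1 = 1e5), n_perm = 300)
  set.seed(65)
  r2 <- permutation_enrichment(calls, track[c(3, 1, 2), ], c(chr1 = 1e5),
                               n_perm = 300)
  expect_equal(r1$null, r2$null)
  expect_equal(r1$p_two_sided, r2$p_two_sided)
})

test_that("homolog-status permutation has the documented p floor", {
  set.seed(66)
  # constant status function: observed equals every null draw
  const_fun <- function(frags) rep("single_copy", nrow(frags))
  r <- homolog_fraction_permutation(rep("single_copy", 50), const_fun,
                                    c(chr1 = 1e5), n_perm = 200)
  expect_equal(r$observed, 0)
  expect_equal(r$p_lower, 1)
  expect_equal(r$p_upper, 1)

  # spatially biased status: calls all in the no-homolog half
  biased_fun <- function(frags)
    ifelse(frags$start < 5e4, "no_homolog", "single_copy")
  r2 <- homolog_fraction_permutation(rep("no_homolog", 50), biased_fun,
                                     c(chr1 = 1e5), n_perm = 1000)
  expect_lte(r2$p_upper, 0.05)
  expect_gte(r2$p_upper, 1 / 1001)
})

test_that("age-group trend recovers a planted depletion gradient", {
  set.seed(67)
  chrlen <- c(chr1 = 2e5)
  tracks <- lapply(1:10, function(i) {
    st <- sort(sample.int(190000, 20))
    data.frame(chrom = "chr1", start = st, end = st + 599)
  })
  names(tracks) <- paste0("t", 1:10)
  # groups with increasing avoidance of all tracks
  track_union <- do.call(rbind, tracks)
  place_calls <- function(n, p_avoid) {
    st <- integer(0)
    while (length(st) < n) {
      cand <- sample.int(199600, 1)
      inside <- any(cand <= track_union$end & cand + 399 >= track_union$start)
      if (!inside || runif(1) > p_avoid) st <- c(st, cand)
    }
    data.frame(chrom = "chr1", start = st, end = st + 399)
  }
  groups <- list(young = place_calls(80, 0),
                 old = place_calls(80, 0.5),
                 nonsingleton = place_calls(80, 0.95))
  tr <- age_group_trend(groups, tracks, chrlen, n_perm = 300)
  med <- apply(tr$ratios, 2, median)
  expect_true(med["young"] > med["old"] && med["old"] > med["nonsingleton"])
  expect_lt(tr$friedman_p, 0.05)
  # the most depleted group is significantly below expectation
  expect_lt(tr$sign_tests$nonsingleton$p_one_sided, 0.01)
})

test_that("sign test closed form: k tracks all below one", {
  set.seed(68)
  chrlen <- c(chr1 = 1e5)
  # all-equal ratios: flat trend, uninformative tests
  tracks <- lapply(1:6, function(i)
    data.frame(chrom = "chr1", start = 1, end = 1e5))
  names(tracks) <- paste0("t", 1:6)
  calls <- data.frame(chrom = "chr1", start = c(1000, 2000), end = c(1399, 2399))
  suppressWarnings({
    tr <- age_group_trend(list(a = calls, b = calls), tracks, chrlen,
                          n_perm = 100)
  })
  expect_true(all(tr$ratios == 1))
  expect_equal(tr$sign_tests$a$p_one_sided, 1)
  expect_equal(tr$pairwise["a", "b"], 1)
  # closed form: one-sided sign p = 2^-k when all k informative ratios < 1
  k <- 8
  expect_equal(binom.test(k, k, 0.5, alternative = "greater")$p.value, 2^-k)
})
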