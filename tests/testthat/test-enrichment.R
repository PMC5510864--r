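test_that("widening keeps midpoints and is idempotent at target width", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1010))
  w <- widen(g, 500)
  expect_equal(GenomicRanges::start(w), 756)   # 0-based (755, 1255)
  expect_equal(GenomicRanges::end(w), 1255)
  expect_equal(GenomicRanges::width(w), 500)
  # odd target width: floor/ceil split around the midpoint
  w2 <- widen(g, 501)
  expect_equal(GenomicRanges::width(w2), 501)
  expect_equal(GenomicRanges::start(w2), 756)
  # already at width: midpoint unchanged
  expect_equal(GenomicRanges::start(widen(w, 500)), GenomicRanges::start(w))
})

test_that("shuffling preserves lengths, respects gaps and the seed", {
  clen <- c(chr1 = 100000L)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 5000), width = c(100, 250)))
  gaps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20000, 90000))
  reps <- shuffle_sites(sites, clen, gaps, n = 50, seed = 3)
  for (rp in reps) {
    expect_equal(unname(rp[, "end"] - rp[, "start"] + 1L), c(100L, 250L))
    expect_true(all(rp[, "end"] <= 100000L))
    # never intersecting the gap
    expect_true(all(rp[, "end"] < 20000 | rp[, "start"] > 90000))
  }
  expect_identical(shuffle_sites(sites, clen, gaps, n = 5, seed = 3)[[1]],
                   reps[[1]])
  # chromosome fully gapped except one slot -> deterministic placement
  clen2 <- c(chr1 = 1000L)
  gap2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 151), c(100, 1000)))
  s2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, width = 50))
  rep2 <- shuffle_sites(s2, clen2, gap2, n = 10, seed = 4)
  for (rp in rep2) expect_equal(unname(rp[, "start"]), 101L)
})

test_that("null overlap of a half-covering track is about half the sites", {
  clen <- c(chr1 = 200000L)
  # track tiles the first half of the chromosome
  track <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100000))
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1000, 191000, length.out = 20),
                                                           width = 10))
  reps <- shuffle_sites(sites, clen, NULL, n = 400, seed = 5)
  null <- vapply(reps, function(rp)
    sum(GenomicRanges::countOverlaps(shuffled_granges(rp, attr(reps, "chroms")),
                                     track) > 0), numeric(1))
  expect_equal(mean(null), 10, tolerance = 0.05)
})

test_that("partial overlap counts elements once, with closed-interval semantics", {
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 180), width = 30))
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1100))
  expect_equal(partial_overlap_count(far, sites), 0L)
  touched_twice <- GenomicRanges::GRanges("chr1", IRanges::IRanges(120, 190))
  expect_equal(partial_overlap_count(touched_twice, sites), 1L)
  # adjacency without shared bases is not overlap
  adjacent <- GenomicRanges::GRanges("chr1", IRanges::IRanges(130, 179))
  expect_equal(partial_overlap_count(adjacent,
    GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 129))), 0L)
})

test_that("enrichment is calibrated on the trivial and planted extremes", {
  clen <- c(chr1 = 50000L)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(2000, 48000, by = 5000),
                                                           width = 20))
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50000))
  r1 <- enrichment_test(sites, whole, clen, n_perm = 99,
                        statistic = "site_in_region_count", seed = 6)
  expect_equal(r1$fold, 1)
  expect_equal(r1$p_empirical, 1)
  # sites planted inside a narrow track: maximal enrichment, minimal p
  narrow <- GenomicRanges::GRanges("chr1", IRanges::IRanges(GenomicRanges::start(sites) - 5,
                                                            width = 40))
  r2 <- enrichment_test(sites, narrow, clen, n_perm = 99,
                        statistic = "site_in_region_count", seed = 7)
  expect_gt(r2$fold, 5)
  expect_equal(r2$p_empirical, 1 / 100)
  expect_equal(r2$direction, "enriched")
})

test_that("empirical p-values are uniform for random sites against a random track", {
  set.seed(8)
  clen <- c(chr1 = 100000L)
  track <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sort(sample.int(95000, 40)), width = 500))
  ps <- replicate(60, {
    sites <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(sample.int(99000, 10), width = 50))
    enrichment_test(sites, track, clen, n_perm = 60,
                    statistic = "site_in_region_count")$p_empirical
  })
  # two-sided smaller-tail p concentrates below 0.5 by construction; check
  # it is not degenerate and respects its floor
  expect_true(all(ps >= 1 / 61 & ps <= 1))
  expect_gt(stats::sd(ps), 0.05)
})

test_that("Bonferroni spans exactly the tracks of one invocation", {
  clen <- c(chr1 = 50000L)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(2000, 48000, by = 5000),
                                                           width = 20))
  tracks <- list(
    a = GenomicRanges::GRanges("chr1", IRanges::IRanges(GenomicRanges::start(sites) - 5,
                                                        width = 40)),
    b = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 25000)))
  res <- enrichment_tests(sites, tracks, clen, n_perm = 49, seed = 9)
  expect_equal(res$p_bonferroni, pmin(res$p_empirical * 2, 1))
})

test_that("aggregation profiles are flat on uniform signal and peaked on deltas", {
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(50000, 250000, by = 50000),
                                                           width = 10))
  # uniform signal: tile the whole span
  uniform <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400000))
  pr <- aggregate_profile(uniform, sites, flank = 10000, bin = 200)
  expect_true(all(abs(pr$normalized - 1) < 1e-6))
  # delta signal at the midpoints: central peak, width set by smoothing
  mids <- GenomicRanges::start(sites) + 5L
  delta <- GenomicRanges::GRanges("chr1", IRanges::IRanges(mids - 10, width = 20))
  pr2 <- aggregate_profile(delta, sites, flank = 10000, bin = 200)
  central <- which.max(pr2$smoothed)
  expect_true(abs(pr2$offset[central]) <= 200 * 10)     # near the midpoint
  # raw signal occupies one or two bins; smoothing spreads it over <= 11
  expect_lte(sum(pr2$raw > 0), 2L)
  expect_lte(sum(pr2$smoothed > 0), 11L)
  # empty signal: all-zero profile, normalization guarded
  none <- GenomicRanges::GRanges()
  pr3 <- aggregate_profile(none, sites, flank = 10000, bin = 200)
  expect_true(all(pr3$normalized == 0))
})

test_that("retrodeletions require half the deletion covered by a pseudogene", {
  del <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 5000), width = 1000))
  pg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1000, 5601), width = c(600, 250)))
  res <- retrodeletion_overlap(pg, del)
  expect_equal(res$pairs$deletion, 1L)       # 60% covered in; 25% out
  expect_equal(res$n_deletions, 1L)
  # several pseudogenes over one deletion: all pairs, one event
  pg2 <- c(pg[1], GenomicRanges::GRanges("chr1", IRanges::IRanges(1100, 1900)))
  res2 <- retrodeletion_overlap(pg2, del)
  expect_equal(nrow(res2$pairs), 2L)
  expect_equal(res2$n_deletions, 1L)
})
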