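test_that("average-linkage clustering matches the hand example and brute force", {
  expect_equal(cluster_positions(c(100, 200, 1200), 500),
               list(c(100, 200), 1200))
  expect_equal(cluster_positions(42, 500), list(42))
  expect_equal(cluster_positions(numeric(0), 500), list())
  # n <= 12 random cases against the from-scratch agglomeration oracle
  set.seed(31)
  for (case in 1:25) {
    n <- sample(2:12, 1)
    pos <- sample.int(5000, n)
    cutoff <- sample(c(100, 300, 500, 800), 1)
    expect_equal(cluster_positions(pos, cutoff),
                 brute_average_linkage(pos, cutoff))
  }
})

test_that("clustering is invariant to permutation of the input", {
  set.seed(13)
  pos <- sample.int(10000, 30)
  ref <- cluster_positions(pos, 500)
  for (i in 1:5)
    expect_equal(cluster_positions(sample(pos), 500), ref)
})

test_that("expected support distance matches the uniform-placement oracle", {
  expect_equal(expected_support_distance(300, 100), 401 / 3)
  expect_equal(expected_support_distance(100, 100), 1 / 3)
  # Monte-Carlo oracle: two supporting-read offsets uniform on
  # [-(IS-RL), +(IS-RL)]
  set.seed(17)
  for (par in list(c(300, 100), c(250, 76))) {
    span <- par[1] - par[2]
    x <- sample(-span:span, 2e5, replace = TRUE)
    y <- sample(-span:span, 2e5, replace = TRUE)
    expect_equal(mean(abs(x - y)), expected_support_distance(par[1], par[2]),
                 tolerance = 0.01)
  }
  # stays under the 500 bp cutoff for realistic insert/read geometries
  for (IS in seq(200, 400, by = 50)) for (RL in seq(70, 100, by = 10))
    expect_lt(expected_support_distance(IS, RL), 500)
})

test_that("discordant collection enforces the mapq and distance rules", {
  genes <- GenomicRanges::GRangesList(
    G1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 12000), strand = "+"))
  rec <- function(id, chrom, pos, mapq, mate_chrom, mate_pos, mate_mapq,
                  strand2 = "+") {
    data.frame(read_id = id, flag = c(1L + 64L, 1L + 128L), mapped = TRUE,
               chrom = c(chrom, mate_chrom), pos = c(pos, mate_pos),
               mapq = c(mapq, mate_mapq), cigar = "100M",
               strand = c("+", strand2), mate_chrom = c(mate_chrom, chrom),
               mate_pos = c(mate_pos, pos), is_read1 = c(TRUE, FALSE),
               n_mismatch = 0L, seq = strrep("A", 100),
               stringsAsFactors = FALSE)
  }
  al <- rbind(
    rec("near", "chr1", 10500, 60, "chr1", 12600, 60),   # 500 bp away: kept out
    rec("far", "chr1", 10500, 60, "chr1", 50000, 60),    # > 1 kb: in
    rec("xchrom", "chr1", 10500, 60, "chr2", 700, 60),   # cross-chromosome: in
    rec("lowq", "chr1", 10500, 60, "chr1", 50000, 14),   # mapq 14: out
    rec("edgeq", "chr1", 10500, 15, "chr1", 50000, 15))  # mapq 15: in
  dp <- collect_discordant(al, genes)
  expect_equal(unique(dp$gene_id), "G1")
  expect_setequal(unique(dp$distal_chrom), c("chr1", "chr2"))
  expect_equal(nrow(dp), 3L)
})

test_that("two-sided calls need two reads on each side", {
  lc <- list(list(positions = c(100, 150, 180), inner = 300))
  rc <- list(list(positions = c(320, 390), inner = 310))
  res <- call_sites(lc, rc, "G1", "chr1")
  expect_equal(res$calls$call_type, "two_sided")
  expect_equal(res$calls$left_support, 3L)
  expect_equal(res$calls$right_support, 2L)
  # one read on the left is never enough for a two-sided call, and the
  # opposite-side read also disqualifies the deep cluster as single-sided
  lc1 <- list(list(positions = 100, inner = 300))
  rc5 <- list(list(positions = c(320, 330, 340, 350, 360), inner = 310))
  res2 <- call_sites(lc1, rc5, "G1", "chr1")
  expect_equal(nrow(res2$calls), 0L)
  expect_length(res2$unpaired, 0L)
  expect_equal(nrow(call_single_sided(res2$unpaired, "G1", "chr1")), 0L)
})

test_that("overlapping clusters from a target-site duplication still pair", {
  # TSD makes the right cluster start before the left cluster's inner edge
  lc <- list(list(positions = c(100, 160), inner = 315))
  rc <- list(list(positions = c(305, 350), inner = 300))   # overlaps by 15
  res <- call_sites(lc, rc, "G1", "chr1")
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$start, 300)
  expect_equal(res$calls$end, 315)
})

test_that("single-sided calls need at least four reads", {
  mk <- function(n) list(positions = seq(100, by = 10, length.out = n),
                         inner = 100 + 10 * n, side = "left")
  expect_equal(nrow(call_single_sided(list(mk(4)), "G1", "chr1")), 1L)
  expect_equal(nrow(call_single_sided(list(mk(3)), "G1", "chr1")), 0L)
})

test_that("cross-population merging respects gene, orientation and distance", {
  two <- function(pop, start, end, orient = "+", type = "two_sided") {
    data.frame(gene_id = "G1", chrom = "chr1", start = start, end = end,
               orientation = orient, left_support = 3L, right_support = 3L,
               call_type = type, populations = pop, stringsAsFactors = FALSE)
  }
  m <- merge_across_populations(rbind(two("YRI", 1000, 1200),
                                      two("CEU", 1100, 1300)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$populations, "CEU,YRI")
  expect_equal(c(m$start, m$end), c(1000, 1300))
  # opposite orientation never merges
  m2 <- merge_across_populations(rbind(two("YRI", 1000, 1200),
                                       two("CEU", 1100, 1300, orient = "-")))
  expect_equal(nrow(m2), 2L)
  # single-sided events merge within 500 bp but not at 600 bp
  ss <- function(pop, pos) two(pop, pos, pos + 1, type = "single_sided")
  expect_equal(nrow(merge_across_populations(rbind(ss("YRI", 1000),
                                                   ss("CEU", 1400)))), 1L)
  expect_equal(nrow(merge_across_populations(rbind(ss("YRI", 1000),
                                                   ss("CEU", 1601)))), 2L)
  # alternative loci are excluded
  alt <- two("YRI", 1000, 1200)
  alt$chrom <- "chr1_alt"
  expect_equal(nrow(merge_across_populations(alt, primary_chroms = "chr1")), 0L)
})

test_that("planted insertions are recovered from simulated discordant pairs", {
  w <- toy_world()
  g <- names(w$genes)[lengths(w$genes) >= 4]
  ev <- retrocopy_event(g[1], "chr2", 150000L)
  evl1 <- retrocopy_event(g[2], "chr1", 60000L, l1_len = 6000L)
  prs <- simulate_wgs_pairs(w$genome, w$genes, list(ev, evl1),
                            n_carriers = 12L, coverage = 8,
                            population = "YRI", seed = 21)
  dp <- collect_discordant(prs, w$genes[g[1:2]])
  expect_gte(nrow(dp), 1L)
  calls <- detect_insertion_sites(dp, "YRI")
  c1 <- calls[calls$gene_id == g[1], ]
  expect_equal(c1$call_type, "two_sided")
  expect_lt(abs((c1$start + c1$end) / 2 - 150000), 500)
  # the L1 co-insertion masks one flank: recovered single-sided
  c2 <- calls[calls$gene_id == g[2], ]
  expect_equal(c2$call_type, "single_sided")
  # and zero planted events give zero discordant pairs and zero calls
  none <- simulate_wgs_pairs(w$genome, w$genes, list(), n_carriers = 10L,
                             population = "CEU", seed = 22)
  expect_equal(nrow(collect_discordant(none, w$genes)), 0L)
})
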