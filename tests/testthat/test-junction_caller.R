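# shared small library: first toy gene, exons >= 250 bp so adjacent
# junctions have disjoint flank segments
toy_lib <- function() {
  w <- toy_world()
  build_true_library(w$genes, w$genome)
}

test_that("side lengths follow the cigar walk across the junction offset", {
  # 76 bp read centered on offset 100 of a 200 bp junction
  s <- score_hit("76M", pos = 63L, offset = 100L, n_mismatch = 0L)
  expect_equal(c(s$d1, s$d2), c(38L, 38L))
  expect_equal(s$r, 0)
  # fully within the upstream flank
  s2 <- score_hit("76M", pos = 10L, offset = 100L, n_mismatch = 0L)
  expect_equal(s2$d2, 0L)
  # mismatch rate is mismatches over aligned bases
  s3 <- score_hit("76M", pos = 63L, offset = 100L, n_mismatch = 2L)
  expect_equal(s3$r, 2 / 76)
  # clipped bases are excluded; deletions consume reference only
  s4 <- score_hit("10S30M2D36M", pos = 71L, offset = 100L, n_mismatch = 0L)
  expect_equal(s4$d1, 30L)        # 71..100 aligned upstream
  expect_equal(s4$d2, 36L)        # after the deletion, downstream only
})

test_that("the (d, r_max) filter is inclusive on both boundaries", {
  hits <- data.frame(read_id = c("a", "b"), junction_id = "j", pos = 1L,
                     n_mismatch = 0L, cigar = "76M", sample_id = "s",
                     gene_id = "g", d1 = c(5L, 6L), d2 = c(40L, 40L),
                     r = c(0, 0.05), stringsAsFactors = FALSE)
  expect_equal(nrow(filter_hits(hits, list(d = 6L, r_max = 0.05))), 1L)
  expect_equal(filter_hits(hits, list(d = 6L, r_max = 0.05))$read_id, "b")
  # random hit set against the brute-force predicate
  set.seed(7)
  rh <- data.frame(read_id = paste0("r", 1:200), junction_id = "j",
                   pos = 1L, n_mismatch = 0L, cigar = "76M", sample_id = "s",
                   gene_id = "g", d1 = sample(0:40, 200, TRUE),
                   d2 = sample(0:40, 200, TRUE),
                   r = round(stats::runif(200, 0, 0.08), 3),
                   stringsAsFactors = FALSE)
  par <- list(d = 6L, r_max = 0.03)
  want <- rh[vapply(seq_len(200), function(i)
    min(rh$d1[i], rh$d2[i]) >= par$d && rh$r[i] <= par$r_max, logical(1)), ]
  expect_equal(filter_hits(rh, par), want)
})

test_that("the two-junction call rule matches the hand-applied definition", {
  lib <- toy_lib()
  g <- lib$junctions$gene_id[1]
  jid <- function(i, j) sprintf("%s:e%d-e%d", g, i, j)
  mk <- function(junctions, reads_per) {
    do.call(rbind, lapply(seq_along(junctions), function(i) {
      data.frame(sample_id = "s1",
                 read_id = sprintf("%s_%d", junctions[i], seq_len(reads_per[i])),
                 junction_id = junctions[i], stringsAsFactors = FALSE)
    }))
  }
  # (e1,e2) x2 + (e3,e4) x1 -> called (disjoint junctions, one with 2 reads)
  h1 <- mk(c(jid(1, 2), jid(3, 4)), c(2L, 1L))
  expect_equal(call_sample(h1, lib)$gene_id, g)
  # a single junction, however deep, is not enough
  h2 <- mk(jid(1, 2), 5L)
  expect_equal(nrow(call_sample(h2, lib)), 0L)
  # shared segment e1 donor AND no junction with 2 reads
  h3 <- mk(c(jid(1, 2), jid(1, 3)), c(1L, 1L))
  expect_equal(nrow(call_sample(h3, lib)), 0L)
  # shared segment with depth still fails the non-overlap requirement
  h4 <- mk(c(jid(1, 2), jid(1, 3)), c(3L, 3L))
  expect_equal(nrow(call_sample(h4, lib)), 0L)
  # empty input -> empty output
  expect_equal(nrow(call_sample(h1[0, ], lib)), 0L)
})

test_that("supporting reads are counted by distinct read id", {
  lib <- toy_lib()
  g <- lib$junctions$gene_id[1]
  jid <- function(i, j) sprintf("%s:e%d-e%d", g, i, j)
  h <- data.frame(sample_id = "s1",
                  read_id = c("r1", "r1", "r2"),     # r1 duplicated
                  junction_id = c(jid(1, 2), jid(1, 2), jid(3, 4)),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(call_sample(h, lib)), 0L)        # max distinct reads = 1
})

test_that("tuning prefers the strictest parameters among equal-call optima", {
  lib <- toy_lib()
  w <- toy_world()
  decs <- build_decoy_libraries(w$genes, w$genome)
  ev <- retrocopy_event(lib$junctions$gene_id[1], "chr1", 150000L)
  sim <- simulate_wes(w$genome, w$genes, list(ev), coverage = 40,
                      error_rate = 0, sample_id = "s1", seed = 5)
  th <- score_hits(align_to_junctions(sim$unmapped, lib), lib, "s1")
  dh <- lapply(decs, function(d)
    score_hits(align_to_junctions(sim$unmapped, d), d, "s1"))
  par <- tune_parameters(th, dh, lib, decs)
  expect_true(par$feasible)
  expect_gte(par$n_true_calls, 1L)
  # exhaustive oracle: recompute best point directly
  grid <- expand.grid(d = 1:15, r_max = seq(0, 0.05, by = 0.005))
  calls_at <- vapply(seq_len(nrow(grid)), function(i) {
    p <- list(d = grid$d[i], r_max = grid$r_max[i])
    for (k in seq_along(dh)) {
      f <- filter_hits(dh[[k]], p)
      if (nrow(f) > 0L && nrow(call_sample(f, decs[[k]])) > 0L) return(-1L)
    }
    nrow(call_sample(filter_hits(th, p), lib))
  }, integer(1))
  best <- max(calls_at)
  cand <- which(calls_at == best)
  cand <- cand[order(-grid$d[cand], grid$r_max[cand])][1]
  expect_equal(par$d, grid$d[cand])
  expect_equal(par$r_max, grid$r_max[cand])
  expect_equal(par$n_true_calls, best)
})

test_that("tuning is invariant to sample order and blocks noisy decoy hits", {
  lib <- toy_lib()
  w <- toy_world()
  decs <- build_decoy_libraries(w$genes, w$genome)[1]
  th <- data.frame(read_id = paste0("r", 1:4), junction_id = lib$junctions$junction_id[1],
                   pos = 63L, n_mismatch = 0L, cigar = "76M",
                   sample_id = c("s1", "s1", "s2", "s2"),
                   gene_id = lib$junctions$gene_id[1],
                   d1 = 38L, d2 = 38L, r = 0, stringsAsFactors = FALSE)
  p1 <- tune_parameters(th, list(th[0, ]), lib, decs)
  p2 <- tune_parameters(th[4:1, ], list(th[0, ]), lib, decs)
  expect_equal(p1$d, p2$d)
  expect_equal(p1$r_max, p2$r_max)
  # a planted decoy call surviving only at r_max = 0.05 forces r_max below it
  dlib <- decs[[1]]
  dg <- dlib$junctions$gene_id[1]
  djs <- dlib$junctions$junction_id[dlib$junctions$gene_id == dg]
  exd <- expand.grid(j = djs[c(1, length(djs))], rd = 1:2)
  dh <- data.frame(read_id = sprintf("d%d", seq_len(nrow(exd))),
                   junction_id = as.character(exd$j), pos = 63L,
                   n_mismatch = 4L, cigar = "76M", sample_id = "s1",
                   gene_id = dg, d1 = 38L, d2 = 38L, r = 4 / 80,
                   stringsAsFactors = FALSE)
  p3 <- tune_parameters(th, list(dh), lib, decs)
  expect_lt(p3$r_max, 0.05)
})

test_that("raising d or tightening r_max never yields more calls", {
  lib <- toy_lib()
  w <- toy_world()
  set.seed(11)
  ev <- retrocopy_event(lib$junctions$gene_id[2], "chr2", 120000L)
  sim <- simulate_wes(w$genome, w$genes, list(ev), coverage = 30,
                      sample_id = "s1", seed = 11)
  th <- score_hits(align_to_junctions(sim$unmapped, lib), lib, "s1")
  counts <- sapply(1:15, function(d)
    nrow(call_sample(filter_hits(th, list(d = d, r_max = 0.05)), lib)))
  expect_true(all(diff(counts) <= 0))
  counts_r <- sapply(seq(0.05, 0, by = -0.005), function(r)
    nrow(call_sample(filter_hits(th, list(d = 1L, r_max = r)), lib)))
  expect_true(all(diff(counts_r) <= 0))
})

test_that("the zero-decoy Poisson model reproduces the closed-form rates", {
  est <- estimate_fdr(2533L, 0.95)
  expect_equal(est$lambda_per_sample, 1.2e-3, tolerance = 0.05)
  expect_equal(est$projected_false_calls, 3, tolerance = 0.01)
  # lambda * n is -log(1 - confidence), independent of n
  expect_equal(estimate_fdr(10L, 0.95)$projected_false_calls,
               est$projected_false_calls)
  expect_equal(estimate_fdr(1L, 1 - exp(-1))$lambda_per_sample, 1)
})

test_that("the parent-gene FDR bound stays under 2% at 99% confidence", {
  expect_equal(callset_fdr_bound(3, 503), 0.006, tolerance = 0.01)
  expect_equal(callset_fdr_bound(0, 100), 0)
  proj99 <- estimate_fdr(2533L, 0.99)$projected_false_calls
  expect_lt(callset_fdr_bound(proj99, 503), 0.02)
})

test_that("the built-in matcher finds planted junction reads on both strands", {
  lib <- toy_lib()
  j <- lib$junctions[1, ]
  read <- substr(j$seq, j$offset - 37, j$offset + 38)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  mut <- read
  substr(mut, 10, 10) <- if (substr(mut, 10, 10) == "A") "C" else "A"
  hits <- align_to_junctions(c(fwd = read, rev = rc, mm = mut), lib)
  expect_setequal(hits$read_id, c("fwd", "rev", "mm"))
  expect_true(all(hits$junction_id == j$junction_id))
  expect_equal(sort(hits$n_mismatch), c(0L, 0L, 1L))
  expect_setequal(hits$strand[hits$read_id %in% c("fwd", "rev")], c("+", "-"))
})
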