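test_that("carrier frequencies are tabulated per population", {
  manifest <- data.frame(
    sample_id = sprintf("I%02d", 1:18),
    population = rep(c("P1", "P2"), c(10, 8)),
    superpop = rep(c("A", "B"), c(10, 8)),
    stringsAsFactors = FALSE)
  calls <- data.frame(sample_id = c("I01", "I02", "I03"), gene_id = "G1",
                      stringsAsFactors = FALSE)
  fm <- build_frequency_matrix(calls, manifest)
  expect_equal(unname(fm$freq["G1", ]), c(0.3, 0))
  expect_equal(unname(fm$counts["G1", ]), c(3L, 0L))
  expect_equal(unname(fm$pop_sizes), c(10L, 8L))
  # empty calls -> all-zero matrix
  fm0 <- build_frequency_matrix(calls[0, ], manifest)
  expect_equal(nrow(fm0$freq), 0L)
  # duplicated calls for one individual count once
  calls2 <- rbind(calls, calls[1, ])
  expect_equal(unname(build_frequency_matrix(calls2, manifest)$counts["G1", 1]),
               3L)
})

test_that("the fixation index matches its closed form and stays in [0,1]", {
  expect_equal(fst(c(0.2, 0.8), c(0.5, 0.5)), 0.36)
  expect_equal(fst(rep(0.37, 5), rep(0.2, 5)), 0)
  expect_equal(fst(c(0, 1, 0, 1, 0), rep(0.2, 5)), 1)
  expect_equal(fst(c(0, 0, 0, 0, 0), rep(0.2, 5)), 0)   # degenerate p = 0
  expect_equal(fst(rep(1, 5), rep(0.2, 5)), 0)          # degenerate p = 1
  set.seed(3)
  for (i in 1:200) {
    p <- stats::runif(5)
    c5 <- stats::rgamma(5, 2); c5 <- c5 / sum(c5)
    v <- fst(p, c5)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("a strongly superpopulation-private gene reaches adjusted p < 0.001", {
  set.seed(9)
  n_per <- 100L
  superpop <- rep(c("AFR", "AMR", "EAS", "EUR", "SAS"), each = n_per)
  carriers <- matrix(0L, length(superpop), 1L,
                     dimnames = list(NULL, "G1"))
  carriers[superpop == "AFR", 1] <- stats::rbinom(n_per, 1, 0.8)
  res <- fst_permutation_test(carriers, superpop, n_perm = 1000, seed = 10)
  expect_lt(res$p_adjusted, 0.001)
  # a constant gene differentiates nothing
  const <- matrix(1L, length(superpop), 1L, dimnames = list(NULL, "G1"))
  res0 <- fst_permutation_test(const, superpop, n_perm = 200, seed = 11)
  expect_equal(res0$fst, 0)
  expect_gt(res0$p_empirical, 0.9)
})

test_that("permutation p-values are uniform under the null", {
  des <- make_cohort_design(n_genes = 200, structure = "uniform",
                            base_freq = 0.3, seed = 12)
  coh <- simulate_cohort(des)
  res <- fst_permutation_test(coh$carriers, coh$manifest$superpop,
                              n_perm = 400, seed = 13)
  expect_lt(dkw_stat(res$p_empirical), dkw_band(nrow(res)) + 1 / 401)
  # type-I rate at alpha = 0.05 within a binomial band over 200 genes
  rate <- mean(res$p_empirical <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 1 / 401)
})

test_that("Manhattan distances are symmetric, zero-diagonal, and merge ties first", {
  m <- cbind(P1 = c(0.5, 0.1), P2 = c(0.5, 0.1), P3 = c(0, 0.9))
  d <- manhattan_distances(m)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(P1 = 0, P2 = 0, P3 = 0))
  expect_equal(d["P1", "P2"], 0)
  tree <- average_linkage_tree(m)
  expect_equal(tree$clusters[[1]], c("P1", "P2"))
  # 3-population hand example: first merge P1/P2 at 0, then P3 at the
  # average of its distances to P1 and P2
  expect_equal(tree$hclust$height[2], mean(c(d["P1", "P3"], d["P2", "P3"])))
})

test_that("tree topology ignores gene row order and bootstrap respects the seed", {
  des <- make_cohort_design(n_genes = 60, structure = "superpop", seed = 14)
  coh <- simulate_cohort(des)
  fm <- build_frequency_matrix(coh$calls, coh$manifest)
  t1 <- average_linkage_tree(fm$freq)
  t2 <- average_linkage_tree(fm$freq[sample(nrow(fm$freq)), ])
  key <- function(tr) vapply(tr$clusters, paste, character(1), collapse = "|")
  expect_setequal(key(t1), key(t2))
  b1 <- bootstrap_support(fm, n_boot = 50, seed = 15)
  b2 <- bootstrap_support(fm, n_boot = 50, seed = 15)
  expect_equal(b1$bp, b2$bp)
  expect_true(all(b1$bp >= 0 & b1$bp <= 1))
  expect_error(bootstrap_support(fm, n_boot = 0), "n_boot")
})

test_that("the multiscale model recovers planted (v, c) and reduces to BP when c = 0", {
  scales <- seq(0.5, 1.4, by = 0.1)
  v <- 0.7
  bp_flat <- 1 - stats::pnorm(v * sqrt(scales))   # curvature-free profile
  fit <- fit_au_model(bp_flat, scales)
  expect_equal(fit$c, 0, tolerance = 1e-6)
  expect_equal(fit$au, bp_flat[which.min(abs(scales - 1))], tolerance = 1e-6)
  # known (v, c) recovery
  v <- 1.1; cc <- 0.4
  bp <- 1 - stats::pnorm(v * sqrt(scales) + cc / sqrt(scales))
  fit2 <- fit_au_model(bp, scales)
  expect_equal(fit2$v, v, tolerance = 1e-6)
  expect_equal(fit2$c, cc, tolerance = 1e-6)
  expect_equal(fit2$au, 1 - stats::pnorm(v - cc), tolerance = 1e-6)
})

test_that("AU support lies in [0,1] on simulated cohorts", {
  des <- make_cohort_design(n_genes = 60, structure = "superpop", seed = 16)
  coh <- simulate_cohort(des)
  fm <- build_frequency_matrix(coh$calls, coh$manifest)
  tr <- suppressWarnings(au_support(fm, n_boot_per_scale = 50, seed = 17))
  expect_true(all(tr$au >= 0 & tr$au <= 1))
  expect_true(all(tr$bp >= 0 & tr$bp <= 1))
})

test_that("the private-superpopulation fraction counts gene presence patterns", {
  manifest <- data.frame(sample_id = sprintf("I%02d", 1:20),
                         population = rep(c("P1", "P2", "P3", "P4"), each = 5),
                         superpop = rep(c("A", "A", "B", "B"), each = 5),
                         stringsAsFactors = FALSE)
  # 10 genes: 6 private to one superpop, 4 shared
  calls <- rbind(
    data.frame(sample_id = "I01", gene_id = sprintf("G%02d", 1:6)),
    data.frame(sample_id = "I01", gene_id = sprintf("G%02d", 7:10)),
    data.frame(sample_id = "I11", gene_id = sprintf("G%02d", 7:10)))
  fm <- build_frequency_matrix(calls, manifest)
  expect_equal(private_superpop_fraction(fm), 0.6)
  # everything shared -> 0; everything private -> 1
  fm_all <- build_frequency_matrix(
    rbind(data.frame(sample_id = "I01", gene_id = "G1"),
          data.frame(sample_id = "I11", gene_id = "G1")), manifest)
  expect_equal(private_superpop_fraction(fm_all), 0)
  fm_priv <- build_frequency_matrix(
    data.frame(sample_id = "I01", gene_id = c("G1", "G2")), manifest)
  expect_equal(private_superpop_fraction(fm_priv), 1)
})
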