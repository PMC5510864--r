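#' Simulate a pileup at a parent-gene SNP contaminated by a retrocopy
#'
#' The parent locus contributes two chromosomes carrying the true genotype's
#' alleles; a retrocopy contributes `retrocopy_copies` extra chromosomes
#' carrying `retrocopy_allele`, all of whose reads cross-map back to the
#' parent locus (the worst case; `mappability` relaxes it by thinning the
#' retrocopy's contribution). Each of `depth` reads draws its chromosome
#' uniformly from this pool and is then flipped to the other allele with
#' probability `error_rate`.
#'
#' @param true_genotype `"RR"`, `"RA"` or `"AA"`.
#' @param retrocopy_allele `"R"` or `"A"`.
#' @param retrocopy_copies Retrocopy chromosomes in the pool (0 = absent).
#' @param depth Read depth at the SNP.
#' @param error_rate Per-base sequencing error in [0, 0.5).
#' @param mappability Fraction of retrocopy reads that cross-map
#'   (default 1).
#' @return Integer vector `c(ref_count, alt_count)`.
#' @export
simulate_pileup <- function(true_genotype = c("RR", "RA", "AA"),
                            retrocopy_allele = c("A", "R"),
                            retrocopy_copies = 1L, depth = 30L,
                            error_rate = 0.01, mappability = 1) {
  true_genotype <- match.arg(true_genotype)
  retrocopy_allele <- match.arg(retrocopy_allele)
  stopifnot(depth >= 1L, error_rate >= 0, error_rate < 0.5)
  n_alt_parent <- c(RR = 0, RA = 1, AA = 2)[[true_genotype]]
  eff_copies <- retrocopy_copies * mappability
  pool <- 2 + eff_copies
  p_alt_chrom <- (n_alt_parent +
                    eff_copies * (retrocopy_allele == "A")) / pool
  p_alt <- p_alt_chrom * (1 - error_rate) + (1 - p_alt_chrom) * error_rate
  alt <- stats::rbinom(1L, depth, p_alt)
  c(ref_count = depth - alt, alt_count = alt)
}

#' Diploid genotype call from allele counts
#'
#' Binomial likelihoods with alt-read probabilities `error`, 1/2 and
#' `1 - error` for RR, RA and AA under a uniform genotype prior; the call is
#' the maximum-likelihood genotype and the quality is the log10 ratio of the
#' best to the second-best likelihood.
#'
#' @param ref_count,alt_count Observed allele counts.
#' @param error_rate Assumed per-base error.
#' @return List with `genotype` and `quality`.
#' @export
genotype_call <- function(ref_count, alt_count, error_rate = 0.01) {
  n <- ref_count + alt_count
  p_alt <- c(RR = error_rate, RA = 0.5, AA = 1 - error_rate)
  ll <- stats::dbinom(alt_count, n, p_alt, log = TRUE)
  ord <- order(ll, decreasing = TRUE)
  list(genotype = names(p_alt)[ord[1]],
       quality = (ll[ord[1]] - ll[ord[2]]) / log(10))
}

#' Genotyping erosion as a function of depth
#'
#' Repeated pileup simulation and genotype calling across a depth grid,
#' reporting the miscall rate and mean call quality. With an alt-carrying
#' retrocopy the allele fraction converges to a value (e.g. 1/3 for RR plus
#' one alt copy) that the diploid model attributes to the wrong genotype, so
#' the miscall rate rises toward 1 as depth grows — deeper sequencing makes
#' the contaminated call more confidently wrong.
#'
#' @inheritParams simulate_pileup
#' @param depths Integer vector of depths.
#' @param n_reps Replicates per depth (default 1000).
#' @param seed Optional RNG seed.
#' @return An `erosion_curve` (`data.frame`): `depth`, `miscall_rate`,
#'   `mean_quality`.
#' @export
erosion_curve <- function(depths = c(5L, 10L, 20L, 40L, 80L), n_reps = 1000L,
                          true_genotype = "RR", retrocopy_allele = "A",
                          retrocopy_copies = 1L, error_rate = 0.01,
                          mappability = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(depths, function(dp) {
    wrong <- 0L; qual <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      cnt <- simulate_pileup(true_genotype, retrocopy_allele,
                             retrocopy_copies, dp, error_rate, mappability)
      call <- genotype_call(cnt[1], cnt[2], error_rate)
      if (call$genotype != true_genotype) wrong <- wrong + 1L
      qual[i] <- call$quality
    }
    data.frame(depth = dp, miscall_rate = wrong / n_reps,
               mean_quality = mean(qual))
  })
  res <- do.call(rbind, rows)
  class(res) <- c("erosion_curve", class(res))
  attr(res, "scenario") <- list(true_genotype = true_genotype,
                                retrocopy_allele = retrocopy_allele,
                                retrocopy_copies = retrocopy_copies,
                                error_rate = error_rate)
  res
}

#' @export
plot.erosion_curve <- function(x, ...) {
  sc <- attr(x, "scenario")
  plot(x$depth, x$miscall_rate, type = "b", log = "x",
       xlab = "sequencing depth", ylab = "miscall rate", ylim = c(0, 1),
       main = sprintf("Genotype erosion: %s + %d retrocopy cop(ies) of %s",
                      sc$true_genotype, sc$retrocopy_copies,
                      sc$retrocopy_allele), ...)
  invisible(x)
}
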