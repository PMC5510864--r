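#' Widen intervals around their midpoints
#'
#' Site intervals are enlarged to a fixed width while keeping the middle
#' point unchanged (odd widths put the extra base on the right). Used to
#' neutralize differences in location precision before overlap testing:
#' 500 bp for feature tracks, 1000 bp for genomic elements.
#'
#' @param sites A `GRanges`.
#' @param width Target width in bases.
#' @return The widened `GRanges`.
#' @export
widen <- function(sites, width) {
  mid <- GenomicRanges::start(sites) + GenomicRanges::width(sites) %/% 2L
  GenomicRanges::ranges(sites) <- IRanges::IRanges(
    start = mid - width %/% 2L, width = width)
  sites
}

#' Shuffle site locations on their own chromosomes
#'
#' Each site is placed uniformly at random on its chromosome, preserving its
#' length and chromosome, never intersecting the excluded (gap) regions and
#' never overhanging the chromosome end (the allowed placement interval is
#' shrunk, sites are not clipped). Placement is by rejection sampling.
#'
#' @param sites `GRanges` of observed sites.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gaps `GRanges` of excluded regions (assembly gaps); may be empty.
#' @param n Number of shuffled replicates.
#' @param seed Optional RNG seed.
#' @return A list of `n` matrices with columns `chrom` (integer index into
#'   `names(chrom_lengths)`), `start`, `end` — a compact representation the
#'   permutation statistics consume. Use [shuffled_granges()] to convert a
#'   replicate back to `GRanges`.
#' @export
shuffle_sites <- function(sites, chrom_lengths, gaps = NULL, n = 1000,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(chrom_lengths)
  ci <- match(as.character(GenomeInfoDb::seqnames(sites)), chroms)
  if (anyNA(ci)) stop("site on chromosome absent from chrom_lengths")
  w <- GenomicRanges::width(sites)
  # per-chromosome sorted gap tables for vectorized overlap rejection
  gap_tab <- lapply(chroms, function(ch) {
    if (is.null(gaps)) return(NULL)
    g <- gaps[as.character(GenomeInfoDb::seqnames(gaps)) == ch]
    if (length(g) == 0L) return(NULL)
    g <- IRanges::reduce(GenomicRanges::ranges(g))
    list(start = GenomicRanges::start(g),
         maxend = cummax(GenomicRanges::end(g)))
  })
  max_start <- chrom_lengths[ci] - w + 1L
  if (any(max_start < 1L)) stop("site longer than its chromosome")
  hits_gap <- function(ci, s, e) {
    bad <- logical(length(s))
    for (ch in unique(ci)) {
      gt <- gap_tab[[ch]]
      if (is.null(gt)) next
      sel <- ci == ch
      idx <- findInterval(e[sel], gt$start)  # gaps starting at/before e
      bad[sel] <- idx >= 1L & gt$maxend[pmax(idx, 1L)] >= s[sel]
    }
    bad
  }
  out <- vector("list", n)
  for (b in seq_len(n)) {
    s <- as.integer(floor(stats::runif(length(w), 1, max_start + 1)))
    e <- s + w - 1L
    bad <- hits_gap(ci, s, e)
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      if (tries > 10000L) stop("no gap-free placement found for some site")
      s[bad] <- as.integer(floor(stats::runif(sum(bad), 1, max_start[bad] + 1)))
      e[bad] <- s[bad] + w[bad] - 1L
      bad[bad] <- hits_gap(ci[bad], s[bad], e[bad])
    }
    out[[b]] <- cbind(chrom = ci, start = s, end = e)
  }
  attr(out, "chroms") <- chroms
  out
}

#' @rdname shuffle_sites
#' @param replicate One element of the [shuffle_sites()] result.
#' @param chroms The `chroms` attribute of the result.
#' @export
shuffled_granges <- function(replicate, chroms) {
  GenomicRanges::GRanges(chroms[replicate[, "chrom"]],
                         IRanges::IRanges(replicate[, "start"],
                                          replicate[, "end"]))
}

#' Count elements partially overlapped by sites
#'
#' The partial overlap statistic: the number of genomic elements with at
#' least 1 bp overlap with any site. An element touched by several sites
#' counts once.
#'
#' @param elements,sites `GRanges`.
#' @return Integer count.
#' @export
partial_overlap_count <- function(elements, sites) {
  sum(GenomicRanges::countOverlaps(elements, sites,
                                   ignore.strand = TRUE) > 0L)
}

overlap_statistic <- function(statistic, track, sites) {
  switch(statistic,
         partial_overlap = partial_overlap_count(track, sites),
         base_overlap = sum(GenomicRanges::width(GenomicRanges::intersect(
           IRanges::reduce(track), IRanges::reduce(sites),
           ignore.strand = TRUE))),
         site_in_region_count = sum(GenomicRanges::countOverlaps(
           sites, track, ignore.strand = TRUE) > 0L),
         stop("unknown statistic: ", statistic))
}

#' Permutation enrichment test of sites against a track
#'
#' The observed overlap statistic is compared with its null distribution
#' from same-chromosome, gap-excluded shuffles. Enrichment is reported as
#' the log2 fold change of the observed statistic over the null mean;
#' two-sided significance is the smaller empirical tail with the
#' `(r + 1) / (n + 1)` floor.
#'
#' @param sites `GRanges` of (optionally pre-widened) insertion sites.
#' @param track `GRanges` of the feature/element track.
#' @param chrom_lengths,gaps,seed See [shuffle_sites()].
#' @param n_perm Number of shuffles (10000 for feature tracks, 1000 for
#'   genomic elements in the standard protocol).
#' @param statistic One of `"partial_overlap"`, `"base_overlap"`,
#'   `"site_in_region_count"`.
#' @param widen_to Optional width to apply via [widen()] first.
#' @param track_name Label carried into the result.
#' @return An `enrichment_result` (one-row `data.frame`): `track`,
#'   `observed`, `null_mean`, `fold`, `log2_fold`, `direction`,
#'   `p_empirical`.
#' @export
enrichment_test <- function(sites, track, chrom_lengths, gaps = NULL,
                            n_perm = 1000, statistic = "partial_overlap",
                            widen_to = NULL, seed = NULL,
                            track_name = "track") {
  if (!is.null(widen_to)) sites <- widen(sites, widen_to)
  obs <- overlap_statistic(statistic, track, sites)
  reps <- shuffle_sites(sites, chrom_lengths, gaps, n = n_perm, seed = seed)
  chroms <- attr(reps, "chroms")
  null <- vapply(reps, function(rp)
    overlap_statistic(statistic, track, shuffled_granges(rp, chroms)),
    numeric(1))
  null_mean <- mean(null)
  p_up <- (sum(null >= obs) + 1) / (n_perm + 1)
  p_dn <- (sum(null <= obs) + 1) / (n_perm + 1)
  res <- data.frame(track = track_name, observed = obs,
                    null_mean = null_mean,
                    fold = if (null_mean > 0) obs / null_mean else NA_real_,
                    log2_fold = if (null_mean > 0 && obs > 0)
                      log2(obs / null_mean) else NA_real_,
                    direction = if (obs >= null_mean) "enriched" else "depleted",
                    p_empirical = min(p_up, p_dn),
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Enrichment tests over several tracks with Bonferroni correction
#'
#' @inheritParams enrichment_test
#' @param tracks Named list of `GRanges` tracks tested in one invocation;
#'   Bonferroni correction spans exactly this set.
#' @return Row-bound `enrichment_result` with `p_bonferroni` appended.
#' @export
enrichment_tests <- function(sites, tracks, chrom_lengths, gaps = NULL,
                             n_perm = 1000, statistic = "partial_overlap",
                             widen_to = NULL, seed = NULL) {
  res <- do.call(rbind, lapply(names(tracks), function(nm)
    enrichment_test(sites, tracks[[nm]], chrom_lengths, gaps, n_perm,
                    statistic, widen_to, seed = seed, track_name = nm)))
  res$p_bonferroni <- pmin(res$p_empirical * length(tracks), 1)
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation enrichment test\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Aggregated signal profile around insertion sites
#'
#' Base overlap between a signal track and fixed-width bins tiled around
#' each site midpoint, summed over sites, smoothed with a running mean, and
#' normalized against the flank background (the mean of the first and last
#' `background_bins` smoothed bins, floored at `eps` to guard sparse
#' tracks).
#'
#' @param signal `GRanges` of the signal track (e.g. well-positioned
#'   nucleosomes, GC-rich windows).
#' @param sites `GRanges` of insertion sites; midpoints anchor the windows.
#' @param flank Half-window in bases around each midpoint (default 10000).
#' @param bin Bin width in bases (default 200).
#' @param smooth_window Running-mean window in bins (default 10).
#' @param background_bins Bins at each end used as background (default 20).
#' @param eps Background floor (default 1e-9).
#' @return `data.frame`: `offset` (bin center relative to the midpoint),
#'   `raw`, `smoothed`, `normalized`.
#' @export
aggregate_profile <- function(signal, sites, flank = 10000L, bin = 200L,
                              smooth_window = 10L, background_bins = 20L,
                              eps = 1e-9) {
  n_bins <- (2L * flank) %/% bin
  stopifnot(n_bins > 2L * background_bins)
  mids <- GenomicRanges::start(sites) + GenomicRanges::width(sites) %/% 2L
  chrom <- as.character(GenomeInfoDb::seqnames(sites))
  total <- numeric(n_bins)
  red <- IRanges::reduce(signal)
  for (i in seq_along(mids)) {
    starts <- mids[i] - flank + (seq_len(n_bins) - 1L) * bin
    bins <- GenomicRanges::GRanges(chrom[i],
                                   IRanges::IRanges(starts, width = bin))
    ov <- GenomicRanges::findOverlaps(bins, red, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      qi <- S4Vectors::queryHits(ov)
      inter <- IRanges::pintersect(GenomicRanges::ranges(bins)[qi],
                                   GenomicRanges::ranges(red)[S4Vectors::subjectHits(ov)])
      add <- tapply(IRanges::width(inter), qi, sum)
      total[as.integer(names(add))] <- total[as.integer(names(add))] + add
    }
  }
  # centered running mean with partial windows at the edges
  half <- smooth_window %/% 2L
  smoothed <- vapply(seq_len(n_bins), function(i) {
    lo <- max(1L, i - half); hi <- min(n_bins, i - half + smooth_window - 1L)
    mean(total[lo:hi])
  }, numeric(1))
  bg <- mean(c(smoothed[seq_len(background_bins)],
               smoothed[(n_bins - background_bins + 1L):n_bins]))
  data.frame(offset = -flank + (seq_len(n_bins) - 0.5) * bin,
             raw = total, smoothed = smoothed,
             normalized = smoothed / max(bg, eps))
}

#' Retroduplication deletions: processed pseudogenes over deletion calls
#'
#' A deletion (relative to the reference) is explained by a reference
#' retrocopy when an annotated processed pseudogene covers at least half of
#' the deleted interval. All qualifying (deletion, pseudogene) pairs are
#' reported; a deletion covered by several pseudogenes still counts once in
#' the event total.
#'
#' @param pseudogenes `GRanges` of annotated processed pseudogenes.
#' @param deletions `GRanges` of deletion calls.
#' @param min_fraction Minimum fraction of the deletion covered
#'   (default 0.5).
#' @return List with `pairs` (`data.frame` of qualifying pairs with the
#'   covered fraction) and `n_deletions` (distinct deletions explained).
#' @export
retrodeletion_overlap <- function(pseudogenes, deletions,
                                  min_fraction = 0.5) {
  ov <- GenomicRanges::findOverlaps(deletions, pseudogenes,
                                    ignore.strand = TRUE)
  pairs <- data.frame(deletion = integer(), pseudogene = integer(),
                      fraction = numeric())
  if (length(ov) > 0L) {
    di <- S4Vectors::queryHits(ov); pi <- S4Vectors::subjectHits(ov)
    inter <- IRanges::pintersect(GenomicRanges::ranges(deletions)[di],
                                 GenomicRanges::ranges(pseudogenes)[pi])
    frac <- IRanges::width(inter) / GenomicRanges::width(deletions)[di]
    keep <- frac >= min_fraction
    pairs <- data.frame(deletion = di[keep], pseudogene = pi[keep],
                        fraction = frac[keep])
  }
  list(pairs = pairs, n_deletions = length(unique(pairs$deletion)))
}
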