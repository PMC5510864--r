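#' Collect discordant read pairs anchored in parent genes
#'
#' A discordant pair has one read correctly mapped inside a parent gene
#' (identified beforehand from exon-junction evidence) and its mate mapped
#' either on a different chromosome or at least `min_distance` away from the
#' gene. Both reads must reach the mapping-quality threshold.
#'
#' @param alignments `data.frame` of paired alignment records as produced by
#'   [read_sam()] or [simulate_wgs_pairs()]; mate records share a
#'   `read_id`.
#' @param parent_genes Named `GRangesList` (or `GRanges` with `gene_id`
#'   metadata) of the parent genes to anchor on.
#' @param min_mapq Minimum mapping quality on both reads (default 15).
#' @param min_distance Minimum distance from the gene for a same-chromosome
#'   distal mate (default 1000).
#' @return `data.frame` of discordant pairs: `population`, `gene_id`,
#'   anchor and distal coordinates, `distal_strand`, `mapq` (minimum of the
#'   two mates).
#' @export
collect_discordant <- function(alignments, parent_genes, min_mapq = 15L,
                               min_distance = 1000L) {
  empty <- data.frame(population = character(), gene_id = character(),
                      anchor_chrom = character(), anchor_start = integer(),
                      anchor_end = integer(), distal_chrom = character(),
                      distal_start = integer(), distal_end = integer(),
                      distal_strand = character(), mapq = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L) return(empty)
  gene_gr <- if (methods::is(parent_genes, "GRangesList")) {
    r <- base::range(parent_genes)
    g <- unlist(r, use.names = FALSE)
    g$gene_id <- rep(names(parent_genes), lengths(r))
    g
  } else parent_genes
  al <- alignments[alignments$mapped & !is.na(alignments$pos), , drop = FALSE]
  if (nrow(al) == 0L) return(empty)
  rl <- nchar(al$seq)
  rl[is.na(rl) | rl <= 1L] <- cigar_ref_width(al$cigar)[is.na(rl) | rl <= 1L]
  al$end <- al$pos + rl - 1L
  # split mates
  a <- al[al$is_read1, , drop = FALSE]
  b <- al[!al$is_read1, , drop = FALSE]
  m <- match(a$read_id, b$read_id)
  ok <- !is.na(m)
  a <- a[ok, , drop = FALSE]; b <- b[m[ok], , drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  pairs_ok <- pmin(a$mapq, b$mapq) >= min_mapq
  a <- a[pairs_ok, , drop = FALSE]; b <- b[pairs_ok, , drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  out <- list()
  classify <- function(anchor, distal) {
    agr <- GenomicRanges::GRanges(anchor$chrom,
                                  IRanges::IRanges(anchor$pos, anchor$end))
    hit <- GenomicRanges::findOverlaps(agr, gene_gr, ignore.strand = TRUE)
    if (length(hit) == 0L) return(NULL)
    qi <- S4Vectors::queryHits(hit)
    gi <- S4Vectors::subjectHits(hit)
    gene <- gene_gr[gi]
    anchor <- anchor[qi, , drop = FALSE]
    distal <- distal[qi, , drop = FALSE]
    far <- distal$chrom != anchor$chrom |
      pmax(GenomicRanges::start(gene) - distal$end,
           distal$pos - GenomicRanges::end(gene), 0L) >= min_distance
    keep <- far
    if (!any(keep)) return(NULL)
    data.frame(population = if ("population" %in% names(anchor)) anchor$population[keep] else NA_character_,
               gene_id = gene$gene_id[keep],
               anchor_chrom = anchor$chrom[keep],
               anchor_start = anchor$pos[keep], anchor_end = anchor$end[keep],
               distal_chrom = distal$chrom[keep],
               distal_start = distal$pos[keep], distal_end = distal$end[keep],
               distal_strand = distal$strand[keep],
               mapq = pmin(anchor$mapq, distal$mapq)[keep],
               stringsAsFactors = FALSE)
  }
  out[[1]] <- classify(a, b)
  out[[2]] <- classify(b, a)
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty else res
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- cigar_ops(cg)
    sum(ops$n[ops$op %in% c("M", "=", "X", "D", "N")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Expected distance between reads supporting one insertion point
#'
#' Under uniform read placement, the 5' positions of reads whose pairs
#' straddle a given insertion point range over a window of
#' `2 * (IS - RL) + 1` bases around it, so the expected absolute distance
#' between two supporting reads is `(2 * (IS - RL) + 1) / 3`. For insert
#' sizes of 200-400 bp and read lengths of 70-100 bp this stays well below
#' 500 bp, which motivates the 500 bp average-linkage cutoff (with room for
#' insert-size deviation and target-site duplications).
#'
#' @param insert_size Mean insert size IS in bases.
#' @param read_length Read length RL in bases.
#' @return Expected distance in bases.
#' @export
expected_support_distance <- function(insert_size, read_length) {
  (2 * (insert_size - read_length) + 1) / 3
}

#' Average-linkage clustering of read positions
#'
#' Agglomerative clustering of 1-D positions, merging the closest pair of
#' clusters by average linkage until the minimum inter-cluster average
#' distance exceeds `cutoff`. Deterministic and invariant to input order.
#'
#' @param positions Integer/numeric vector of read positions on one
#'   chromosome and side.
#' @param cutoff Stop merging when the closest clusters are further apart
#'   than this average distance (default 500).
#' @return List of sorted numeric vectors, one per cluster, ordered by
#'   leftmost member.
#' @export
cluster_positions <- function(positions, cutoff = 500) {
  if (length(positions) == 0L) return(list())
  positions <- sort(as.numeric(positions))
  if (length(positions) == 1L) return(list(positions))
  hc <- stats::hclust(stats::dist(positions, method = "manhattan"),
                      method = "average")
  grp <- stats::cutree(hc, h = cutoff)
  cl <- split(positions, grp)
  cl <- cl[order(vapply(cl, min, numeric(1)))]
  names(cl) <- NULL
  cl
}

#' Pair left/right read clusters into insertion-site calls
#'
#' Left-side support is reads on the + strand pointing right toward the
#' insertion; right-side support is reads on the − strand pointing left. A
#' valid two-sided site needs at least two reads on both sides; a left and a
#' right cluster are paired when their inner edges are within `cutoff` of
#' each other (overlap is allowed — target-site duplications make the two
#' clusters overlap). Each cluster is used at most once, pairing nearest
#' compatible clusters first.
#'
#' @param left_clusters,right_clusters Lists of cluster descriptors, each a
#'   list/row with `positions` (read 5' coordinates) and `inner` (inner edge
#'   coordinate: rightmost aligned base for left clusters, leftmost for
#'   right clusters). The convenience builder [side_clusters()] produces
#'   them from discordant pairs.
#' @param gene_id,chrom,orientation,populations Metadata attached to calls.
#' @param cutoff Maximum inner-edge gap (default 500).
#' @return List with `calls` (two-sided `data.frame`) and `unpaired` (the
#'   clusters left over, fed to [call_single_sided()]).
#' @export
call_sites <- function(left_clusters, right_clusters, gene_id, chrom,
                       orientation = "+", populations = NA_character_,
                       cutoff = 500) {
  nl <- length(left_clusters); nr <- length(right_clusters)
  calls <- list()
  used_l <- logical(nl); used_r <- logical(nr)
  if (nl > 0L && nr > 0L) {
    gaps <- outer(seq_len(nl), seq_len(nr), Vectorize(function(i, j)
      abs(right_clusters[[j]]$inner - left_clusters[[i]]$inner)))
    repeat {
      gaps[used_l, ] <- Inf; gaps[, used_r] <- Inf
      if (all(is.infinite(gaps)) || min(gaps) > cutoff) break
      ix <- which(gaps == min(gaps), arr.ind = TRUE)[1, ]
      i <- ix[1]; j <- ix[2]
      used_l[i] <- TRUE; used_r[j] <- TRUE
      lc <- left_clusters[[i]]; rc <- right_clusters[[j]]
      if (length(lc$positions) >= 2L && length(rc$positions) >= 2L) {
        span <- sort(c(lc$inner, rc$inner))
        calls[[length(calls) + 1L]] <- data.frame(
          gene_id = gene_id, chrom = chrom,
          start = span[1], end = max(span[2], span[1] + 1),
          orientation = orientation,
          left_support = length(lc$positions),
          right_support = length(rc$positions),
          call_type = "two_sided",
          populations = paste(sort(unique(stats::na.omit(populations))),
                              collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  unpaired <- c(lapply(which(!used_l), function(i)
                  c(left_clusters[[i]], side = "left")),
                lapply(which(!used_r), function(j)
                  c(right_clusters[[j]], side = "right")))
  list(calls = if (length(calls)) do.call(rbind, calls) else empty_site_calls(),
       unpaired = unpaired)
}

empty_site_calls <- function() {
  data.frame(gene_id = character(), chrom = character(), start = numeric(),
             end = numeric(), orientation = character(),
             left_support = integer(), right_support = integer(),
             call_type = character(), populations = character(),
             stringsAsFactors = FALSE)
}

#' Call single-sided insertion events
#'
#' Clusters with no compatible partner on the other side are called as
#' incomplete single-side events when they have at least four supporting
#' reads — the signature of an L1 co-insertion long enough to push the
#' opposite-flank mates into the repeat (where they cannot be placed).
#'
#' @param unpaired_clusters The `unpaired` element of [call_sites()].
#' @inheritParams call_sites
#' @param min_reads Minimum supporting reads (default 4).
#' @return Single-sided calls `data.frame` in the [call_sites()] layout.
#' @export
call_single_sided <- function(unpaired_clusters, gene_id, chrom,
                              orientation = "+", populations = NA_character_,
                              min_reads = 4L) {
  rows <- lapply(unpaired_clusters, function(cl) {
    if (length(cl$positions) < min_reads) return(NULL)
    data.frame(gene_id = gene_id, chrom = chrom,
               start = cl$inner, end = cl$inner + 1,
               orientation = orientation,
               left_support = if (cl$side == "left") length(cl$positions) else 0L,
               right_support = if (cl$side == "right") length(cl$positions) else 0L,
               call_type = "single_sided",
               populations = paste(sort(unique(stats::na.omit(populations))),
                                   collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) empty_site_calls() else do.call(rbind, rows)
}

#' Build side clusters from discordant pairs of one gene and population
#'
#' Splits distal reads by chromosome and side (left = + strand distal reads,
#' right = − strand), clusters each side with [cluster_positions()], and
#' records cluster inner edges (rightmost aligned base of left clusters,
#' leftmost of right clusters). Read position is its 5' mapped coordinate.
#'
#' @param pairs Discordant pairs for one gene in one population (see
#'   [collect_discordant()]).
#' @param cutoff Average-linkage cutoff (default 500).
#' @return Named list by chromosome, each with `left` and `right` cluster
#'   lists suitable for [call_sites()].
#' @export
side_clusters <- function(pairs, cutoff = 500) {
  by_chrom <- split(pairs, pairs$distal_chrom)
  lapply(by_chrom, function(p) {
    left <- p[p$distal_strand == "+", , drop = FALSE]
    right <- p[p$distal_strand == "-", , drop = FALSE]
    mk <- function(side_pairs, side) {
      pos5 <- if (side == "left") side_pairs$distal_start else side_pairs$distal_end
      cl <- cluster_positions(pos5, cutoff)
      lapply(cl, function(x) {
        members <- side_pairs[pos5 %in% x, , drop = FALSE]
        inner <- if (side == "left") max(members$distal_end) else min(members$distal_start)
        list(positions = sort(x), inner = inner)
      })
    }
    list(left = mk(left, "left"), right = mk(right, "right"))
  })
}

#' Detect insertion sites for one population
#'
#' Pools the population's discordant pairs per parent gene, clusters each
#' side, pairs clusters into two-sided calls and emits single-sided calls
#' from the remainder.
#'
#' @param pairs Discordant pairs (see [collect_discordant()]).
#' @param population Population label attached to the calls.
#' @param cutoff Average-linkage cutoff (default 500).
#' @param orientation_by_gene Optional named character vector giving the
#'   insertion orientation per gene (from anchor-strand bookkeeping);
#'   defaults to `"+"`.
#' @return Insertion calls `data.frame`.
#' @export
detect_insertion_sites <- function(pairs, population = NA_character_,
                                   cutoff = 500, orientation_by_gene = NULL) {
  out <- list()
  for (gp in split(pairs, pairs$gene_id)) {
    gid <- gp$gene_id[1]
    orient <- if (!is.null(orientation_by_gene) && gid %in% names(orientation_by_gene))
      orientation_by_gene[[gid]] else "+"
    scs <- side_clusters(gp, cutoff)
    for (chrom in names(scs)) {
      sc <- scs[[chrom]]
      paired <- call_sites(sc$left, sc$right, gid, chrom, orient, population,
                           cutoff)
      single <- call_single_sided(paired$unpaired, gid, chrom, orient,
                                  population)
      out[[length(out) + 1L]] <- rbind(paired$calls, single)
    }
  }
  if (length(out) == 0L) return(empty_site_calls())
  do.call(rbind, out)
}

#' Merge insertion calls across populations
#'
#' Two-sided sites with identical parent gene and orientation whose
#' intervals overlap are merged into one event (interval union, population
#' union). Single-sided events are merged when they share gene and
#' orientation and lie within `single_side_distance` of each other.
#' Calls on non-primary chromosomes (alternative loci) are excluded.
#'
#' @param calls Row-bound per-population insertion calls.
#' @param primary_chroms Character vector of primary chromosome names;
#'   `NULL` (default) keeps all.
#' @param single_side_distance Merge radius for single-sided events
#'   (default 500).
#' @return Merged calls `data.frame`.
#' @export
merge_across_populations <- function(calls, primary_chroms = NULL,
                                     single_side_distance = 500) {
  if (nrow(calls) == 0L) return(calls)
  if (!is.null(primary_chroms))
    calls <- calls[calls$chrom %in% primary_chroms, , drop = FALSE]
  if (nrow(calls) == 0L) return(calls)
  merge_group <- function(g, gap) {
    g <- g[order(g$start), , drop = FALSE]
    cl <- integer(nrow(g)); cl[1] <- 1L
    cur_end <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] <= cur_end + gap) {
        cl[i] <- cl[i - 1L]
        cur_end <- max(cur_end, g$end[i])
      } else {
        cl[i] <- cl[i - 1L] + 1L
        cur_end <- g$end[i]
      }
    }
    do.call(rbind, lapply(split(g, cl), function(s) {
      data.frame(gene_id = s$gene_id[1], chrom = s$chrom[1],
                 start = min(s$start), end = max(s$end),
                 orientation = s$orientation[1],
                 left_support = max(s$left_support),
                 right_support = max(s$right_support),
                 call_type = s$call_type[1],
                 populations = paste(sort(unique(unlist(
                   strsplit(s$populations, ",")))), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  keys <- interaction(calls$gene_id, calls$chrom, calls$orientation,
                      calls$call_type, drop = TRUE)
  out <- lapply(split(calls, keys), function(g) {
    gap <- if (g$call_type[1] == "single_sided") single_side_distance else 0
    merge_group(g, gap)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Write insertion calls as BED
#'
#' BED columns: chrom, start, end (converted to 0-based half-open), name
#' `gene|call_type|orientation`, score = total support, strand.
#'
#' @param calls Insertion calls.
#' @param path Output path.
#' @export
write_sites_bed <- function(calls, path) {
  gr <- GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(calls$start, pmax(calls$end, calls$start)),
    strand = calls$orientation)
  gr$name <- sprintf("%s|%s|%s", calls$gene_id, calls$call_type,
                     calls$orientation)
  gr$score <- calls$left_support + calls$right_support
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
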