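#' Align reads to a junction library
#'
#' End-to-end (unclipped, gap-free) alignment of reads against the junction
#' sequences of a library, allowing up to `max_mismatch` substitutions, on
#' both strands. A seed-and-extend strategy is used: each read is cut into
#' `max_mismatch + 1` non-overlapping seeds, so at least one seed matches
#' exactly wherever the read aligns within the mismatch budget; seed matches
#' are verified by direct comparison. Each read reports at most one hit (the
#' fewest mismatches; ties resolved to the first junction in library order).
#'
#' This is the built-in matcher used to re-align reads that failed to map to
#' the genome; it consumes the same library FASTA an external aligner would.
#'
#' @param reads Named character vector or `DNAStringSet` of read sequences
#'   (names are read ids).
#' @param lib A `junction_library`.
#' @param max_mismatch Maximum substitutions; default `floor(0.05 * L)` for
#'   read length L, the largest mismatch count the calling filter can accept.
#' @return `data.frame` of hits: `read_id`, `junction_id`, `pos` (1-based
#'   start on the junction sequence), `strand`, `n_mismatch`, `cigar`.
#' @export
align_to_junctions <- function(reads, lib, max_mismatch = NULL) {
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads); reads <- as.character(reads); names(reads) <- nm
  }
  empty <- data.frame(read_id = character(), junction_id = character(),
                      pos = integer(), strand = character(),
                      n_mismatch = integer(), cigar = character(),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0L || nrow(lib$junctions) == 0L) return(empty)
  lens <- nchar(reads)
  if (length(unique(lens)) != 1L)
    stop("align_to_junctions expects constant read length")
  L <- lens[1]
  if (is.null(max_mismatch)) max_mismatch <- floor(0.05 * L)
  subj <- lib$junctions$seq
  slen <- nchar(subj)
  k <- max(8L, L %/% (max_mismatch + 1L))
  # subject k-mer index
  n_pos <- pmax(slen - k + 1L, 0L)
  jrep <- rep.int(seq_along(subj), n_pos)
  prep <- unlist(lapply(n_pos, seq_len), use.names = FALSE)
  sindex <- data.frame(seed = substring(subj[jrep], prep, prep + k - 1L),
                       j = jrep, p = prep, stringsAsFactors = FALSE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  hit_pass <- function(seqs, strand_lab) {
    offs <- seq(1L, L - k + 1L, by = k)
    rrep <- rep(seq_along(seqs), each = length(offs))
    orep <- rep(offs, times = length(seqs))
    rindex <- data.frame(seed = substring(seqs[rrep], orep, orep + k - 1L),
                         read = rrep, o = orep, stringsAsFactors = FALSE)
    cand <- merge(rindex, sindex, by = "seed")
    if (nrow(cand) == 0L) return(NULL)
    cand$start <- cand$p - cand$o + 1L
    cand <- cand[cand$start >= 1L & cand$start + L - 1L <= slen[cand$j], ]
    if (nrow(cand) == 0L) return(NULL)
    cand <- unique(cand[, c("read", "j", "start")])
    sub_seq <- substring(subj[cand$j], cand$start, cand$start + L - 1L)
    read_seq <- seqs[cand$read]
    mm <- vapply(seq_len(nrow(cand)), function(i)
      sum(charToRaw(read_seq[i]) != charToRaw(sub_seq[i])), integer(1))
    cand$mm <- mm
    cand <- cand[cand$mm <= max_mismatch, ]
    if (nrow(cand) == 0L) return(NULL)
    cand$strand <- strand_lab
    cand
  }
  cand <- rbind(hit_pass(reads, "+"), hit_pass(rc, "-"))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$read, cand$mm, cand$j, cand$start), ]
  best <- cand[!duplicated(cand$read), ]
  data.frame(read_id = names(reads)[best$read],
             junction_id = lib$junctions$junction_id[best$j],
             pos = best$start,
             strand = best$strand,
             n_mismatch = best$mm,
             cigar = sprintf("%dM", L),
             stringsAsFactors = FALSE)
}

#' Score a junction alignment into side lengths and mismatch rate
#'
#' For a read aligned to a junction sequence, `d1` is the number of aligned
#' bases on the upstream exon segment (reference positions up to the junction
#' offset) and `d2` the number on the downstream segment; soft/hard-clipped
#' and inserted bases are excluded, and deletions/skips consume reference
#' only. The mismatch rate is `r = n_mismatch / (d1 + d2)`.
#'
#' @param cigar CIGAR string of the alignment.
#' @param pos 1-based alignment start on the junction sequence.
#' @param offset Junction offset: bases contributed by the upstream segment.
#' @param n_mismatch Substitution count of the alignment.
#' @return List with `d1`, `d2`, `r`.
#' @export
score_hit <- function(cigar, pos, offset, n_mismatch) {
  ops <- cigar_ops(cigar)
  ref <- pos
  d1 <- 0L; d2 <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; n <- ops$n[i]
    if (op %in% c("M", "=", "X")) {
      up <- max(0L, min(ref + n - 1L, offset) - ref + 1L)
      d1 <- d1 + up
      d2 <- d2 + (n - up)
      ref <- ref + n
    } else if (op %in% c("D", "N")) {
      ref <- ref + n
    }
    # S, H, I, P consume no reference and contribute no aligned bases
  }
  r <- if (d1 + d2 > 0L) n_mismatch / (d1 + d2) else NA_real_
  list(d1 = d1, d2 = d2, r = r)
}

cigar_ops <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  data.frame(n = as.integer(sub("[A-Z=]$", "", tok)),
             op = sub("^\\d+", "", tok), stringsAsFactors = FALSE)
}

#' Score a table of junction hits
#'
#' Vectorized [score_hit()] over the hits produced by
#' [align_to_junctions()] (or parsed from a junction-space SAM).
#'
#' @param hits `data.frame` with `read_id`, `junction_id`, `pos`,
#'   `n_mismatch`, `cigar`.
#' @param lib The `junction_library` the hits refer to.
#' @param sample_id Sample label attached to every hit.
#' @return The hits with `sample_id`, `gene_id`, `d1`, `d2`, `r` columns
#'   appended.
#' @export
score_hits <- function(hits, lib, sample_id) {
  if (nrow(hits) == 0L) {
    return(cbind(hits, data.frame(sample_id = character(), gene_id = character(),
                                  d1 = integer(), d2 = integer(), r = numeric())))
  }
  idx <- match(hits$junction_id, lib$junctions$junction_id)
  if (anyNA(idx)) stop("hits refer to junctions absent from the library")
  offset <- lib$junctions$offset[idx]
  simple <- grepl("^\\d+M$", hits$cigar)
  d1 <- d2 <- integer(nrow(hits))
  if (any(simple)) {
    L <- as.integer(sub("M$", "", hits$cigar[simple]))
    p <- hits$pos[simple]; o <- offset[simple]
    u <- pmax(0L, pmin(p + L - 1L, o) - p + 1L)
    d1[simple] <- u; d2[simple] <- L - u
  }
  for (i in which(!simple)) {
    s <- score_hit(hits$cigar[i], hits$pos[i], offset[i], hits$n_mismatch[i])
    d1[i] <- s$d1; d2[i] <- s$d2
  }
  hits$sample_id <- sample_id
  hits$gene_id <- lib$junctions$gene_id[idx]
  hits$d1 <- d1
  hits$d2 <- d2
  hits$r <- ifelse(d1 + d2 > 0L, hits$n_mismatch / (d1 + d2), NA_real_)
  hits
}

#' Filter junction hits by side length and mismatch rate
#'
#' A hit is kept iff `min(d1, d2) >= d` and `r <= r_max`; both boundaries are
#' inclusive.
#'
#' @param hits Scored hits (see [score_hits()]).
#' @param params List with `d` and `r_max` (see [tune_parameters()]).
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, params) {
  if (nrow(hits) == 0L) return(hits)
  keep <- pmin(hits$d1, hits$d2) >= params$d &
    !is.na(hits$r) & hits$r <= params$r_max
  hits[keep, , drop = FALSE]
}

# Closure that counts parent-gene calls at a (d, r_max) grid point without
# re-deriving the grouping each time; hits are assumed to carry one row per
# (sample, read) as produced by align_to_junctions (best hit per read).
make_call_counter <- function(hits, lib) {
  compat <- junction_compatibility(lib)
  if (nrow(hits) == 0L) return(function(d, r_max) 0L)
  uh <- unique(hits[, c("sample_id", "read_id", "junction_id", "d1", "d2", "r")])
  j_row <- match(uh$junction_id, lib$junctions$junction_id)
  genes <- unique(lib$junctions$gene_id)
  g_idx <- match(lib$junctions$gene_id, genes)[j_row]
  s_idx <- match(uh$sample_id, unique(uh$sample_id))
  nJ <- nrow(lib$junctions)
  grp <- (s_idx - 1L) * length(genes) + g_idx
  code <- as.numeric(grp) * (nJ + 1) + j_row
  mind <- pmin(uh$d1, uh$d2)
  r <- uh$r
  function(d, r_max) {
    keep <- mind >= d & !is.na(r) & r <= r_max
    if (!any(keep)) return(0L)
    cs <- sort(code[keep])
    rl <- rle(cs)
    ucode <- rl$values
    counts <- rl$lengths
    ugrp <- floor(ucode / (nJ + 1))
    ujr <- as.integer(ucode - ugrp * (nJ + 1))
    calls <- 0L
    for (ix in split(seq_along(ucode), ugrp)) {
      if (max(counts[ix]) < 2L || length(ix) < 2L) next
      gid <- lib$junctions$gene_id[ujr[ix[1]]]
      cm <- compat[[gid]]
      sel <- match(as.character(ujr[ix]), rownames(cm))
      if (any(cm[sel, sel, drop = FALSE])) calls <- calls + 1L
    }
    calls
  }
}

# Genomic intervals of the two flank segments of every junction; two
# junctions are "non-overlapping" iff all four cross-wise segment pairs are
# genomically disjoint (this subsumes "share no exon segment").
junction_segments <- function(lib) {
  j <- lib$junctions
  dlen <- nchar(j$seq) - j$offset
  plus <- j$strand == "+"
  up_s <- ifelse(plus, j$up_end - j$offset + 1L, j$up_start)
  up_e <- ifelse(plus, j$up_end, j$up_start + j$offset - 1L)
  dn_s <- ifelse(plus, j$down_start, j$down_end - dlen + 1L)
  dn_e <- ifelse(plus, j$down_start + dlen - 1L, j$down_end)
  cbind(up_s = up_s, up_e = up_e, dn_s = dn_s, dn_e = dn_e)
}

# Per-gene compatibility: for each gene, which junction pairs are
# non-overlapping. Returns a list keyed by gene id, each element a logical
# matrix over that gene's junction rows (library row indices as dimnames).
junction_compatibility <- function(lib) {
  seg <- junction_segments(lib)
  genes <- split(seq_len(nrow(lib$junctions)), lib$junctions$gene_id)
  disjoint <- function(s1, e1, s2, e2) e1 < s2 | e2 < s1
  lapply(genes, function(rows) {
    n <- length(rows)
    m <- matrix(FALSE, n, n, dimnames = list(rows, rows))
    if (n >= 2L) {
      for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
        ra <- rows[a]; rb <- rows[b]
        ok <- disjoint(seg[ra, "up_s"], seg[ra, "up_e"], seg[rb, "up_s"], seg[rb, "up_e"]) &&
          disjoint(seg[ra, "up_s"], seg[ra, "up_e"], seg[rb, "dn_s"], seg[rb, "dn_e"]) &&
          disjoint(seg[ra, "dn_s"], seg[ra, "dn_e"], seg[rb, "up_s"], seg[rb, "up_e"]) &&
          disjoint(seg[ra, "dn_s"], seg[ra, "dn_e"], seg[rb, "dn_s"], seg[rb, "dn_e"])
        m[a, b] <- m[b, a] <- ok
      }
    }
    m
  })
}

#' Call parent genes with novel retroduplications in one sample
#'
#' A gene is reported iff it has at least two non-overlapping supporting
#' exon-exon junctions (junctions whose four flank segments are pairwise
#' genomically disjoint, i.e. sharing no exon segment) and at least one
#' junction supported by at least two distinct reads (read ids; mates count
#' once per junction).
#'
#' @param hits Filtered, scored hits for one sample.
#' @param lib The `junction_library` the hits refer to.
#' @param compat Optional precomputed [junction_compatibility()] (for
#'   repeated calls during tuning).
#' @return `data.frame` of parent-gene calls: `sample_id`, `gene_id`,
#'   `n_junctions`, `max_reads`, `supporting_junctions`
#'   (`"junction_id:count"` comma-collapsed).
#' @export
call_sample <- function(hits, lib, compat = NULL) {
  out0 <- data.frame(sample_id = character(), gene_id = character(),
                     n_junctions = integer(), max_reads = integer(),
                     supporting_junctions = character(),
                     stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out0)
  if (is.null(compat)) compat <- junction_compatibility(lib)
  uh <- unique(hits[, c("sample_id", "read_id", "junction_id")])
  cnt <- stats::aggregate(list(reads = uh$read_id),
                          by = list(junction_id = uh$junction_id,
                                    sample_id = uh$sample_id),
                          FUN = function(x) length(unique(x)))
  cnt$row <- match(cnt$junction_id, lib$junctions$junction_id)
  cnt$gene_id <- lib$junctions$gene_id[cnt$row]
  out <- list()
  for (grp in split(cnt, list(cnt$sample_id, cnt$gene_id), drop = TRUE)) {
    if (max(grp$reads) < 2L) next
    cm <- compat[[grp$gene_id[1]]]
    sel <- match(as.character(grp$row), rownames(cm))
    if (length(sel) < 2L || !any(cm[sel, sel, drop = FALSE])) next
    out[[length(out) + 1L]] <- data.frame(
      sample_id = grp$sample_id[1], gene_id = grp$gene_id[1],
      n_junctions = nrow(grp), max_reads = max(grp$reads),
      supporting_junctions = paste(sprintf("%s:%d", grp$junction_id, grp$reads),
                                   collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(out0)
  do.call(rbind, out)
}

#' Tune the calling parameters (d, r_max) against decoy libraries
#'
#' Grid search over `d` in 1..15 and `r_max` in 0 to 0.05 (step 0.005). A
#' grid point is feasible when, in every sample, every decoy library yields
#' zero parent-gene calls. Among feasible points the total number of calls
#' from the true library is maximized; among equal-call optima the strictest
#' criteria are preferred (largest `d`, then smallest `r_max`). If no point
#' is feasible, the strictest corner (d = 15, r_max = 0) is returned with a
#' warning.
#'
#' @param true_hits Scored hits against the true library, all samples
#'   (column `sample_id` distinguishes them).
#' @param decoy_hits List of scored hit tables, one per decoy library.
#' @param lib_true,decoy_libs The corresponding libraries.
#' @param d_grid,r_grid Search grids.
#' @return A `calling_parameters` object: list with `d`, `r_max`,
#'   `n_true_calls`, `feasible`.
#' @export
tune_parameters <- function(true_hits, decoy_hits, lib_true, decoy_libs,
                            d_grid = 1:15, r_grid = seq(0, 0.05, by = 0.005)) {
  compat_dec <- lapply(decoy_libs, junction_compatibility)
  counter <- make_call_counter(true_hits, lib_true)
  grid <- expand.grid(d = d_grid, r_max = r_grid)
  n_calls <- integer(nrow(grid))
  feasible <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    par <- list(d = grid$d[g], r_max = grid$r_max[g])
    ok <- TRUE
    for (k in seq_along(decoy_hits)) {
      dh <- filter_hits(decoy_hits[[k]], par)
      if (nrow(dh) > 0L &&
          nrow(call_sample(dh, decoy_libs[[k]], compat_dec[[k]])) > 0L) {
        ok <- FALSE; break
      }
    }
    feasible[g] <- ok
    if (ok) n_calls[g] <- counter(par$d, par$r_max)
  }
  if (!any(feasible)) {
    warning("no feasible (d, r_max) grid point; returning strictest corner")
    sel <- which(grid$d == max(d_grid) & grid$r_max == min(r_grid))
    best_calls <- 0L
  } else {
    best_calls <- max(n_calls[feasible])
    cand <- which(feasible & n_calls == best_calls)
    cand <- cand[order(-grid$d[cand], grid$r_max[cand])]
    sel <- cand[1]
  }
  structure(list(d = grid$d[sel], r_max = grid$r_max[sel],
                 n_true_calls = best_calls, feasible = any(feasible)),
            class = "calling_parameters")
}

#' @export
print.calling_parameters <- function(x, ...) {
  cat(sprintf("Calling parameters: d = %d, r_max = %.3f (%d true-library call(s)%s)\n",
              x$d, x$r_max, x$n_true_calls,
              if (x$feasible) "" else "; NO feasible grid point"))
  invisible(x)
}

#' Poisson zero-decoy-call model of the callset FDR
#'
#' After tuning, no false call is seen in any of `n_samples` samples. If the
#' per-sample false-call count is Poisson with rate lambda, the chance of
#' observing zero false calls in all samples is `exp(-lambda)^n_samples`.
#' Setting this to `1 - confidence` bounds the per-sample rate:
#' `lambda = -log(1 - confidence) / n_samples`, projecting to
#' `lambda * n_samples = -log(1 - confidence)` false calls over the whole
#' callset.
#'
#' @param n_samples Number of samples in which zero decoy calls were seen.
#' @param confidence Confidence level (default 0.95).
#' @return An `fdr_estimate` object: list with `confidence`,
#'   `lambda_per_sample`, `projected_false_calls`, `n_samples`.
#' @export
estimate_fdr <- function(n_samples, confidence = 0.95) {
  stopifnot(n_samples >= 1, confidence > 0, confidence < 1)
  lambda <- -log(1 - confidence) / n_samples
  structure(list(confidence = confidence,
                 lambda_per_sample = lambda,
                 projected_false_calls = lambda * n_samples,
                 n_samples = n_samples),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(paste0("Zero-decoy FDR model (%d samples, %.0f%% confidence):\n",
                     "  per-sample rate lambda = %.3g\n",
                     "  projected false calls  = %.3g\n"),
              x$n_samples, 100 * x$confidence, x$lambda_per_sample,
              x$projected_false_calls))
  invisible(x)
}

#' Bound the callset FDR at the parent-gene level
#'
#' @param projected_false_calls Projected false calls (see [estimate_fdr()]).
#' @param n_unique_parent_genes Number of unique parent genes called.
#' @return Fraction `projected_false_calls / n_unique_parent_genes`.
#' @export
callset_fdr_bound <- function(projected_false_calls, n_unique_parent_genes) {
  stopifnot(n_unique_parent_genes >= 1)
  projected_false_calls / n_unique_parent_genes
}

#' Run the exon-junction calling stage end-to-end
#'
#' Aligns each sample's unmapped reads to the true and decoy libraries,
#' scores the hits, tunes `(d, r_max)` on the whole cohort, and emits
#' per-sample parent-gene calls under the tuned parameters.
#'
#' @param unmapped_reads Named list (by sample id) of named character vectors
#'   (or `DNAStringSet`s) of unmapped read sequences.
#' @param lib_true True `junction_library`.
#' @param decoy_libs List of decoy libraries (see
#'   [build_decoy_libraries()]).
#' @param params Optional fixed `calling_parameters`; when `NULL` (default)
#'   parameters are tuned.
#' @return List with `params` (`calling_parameters`), `calls` (row-bound
#'   [call_sample()] output for all samples) and `n_decoy_calls` (should be
#'   zero by construction of the tuning).
#' @export
run_junction_pipeline <- function(unmapped_reads, lib_true, decoy_libs,
                                  params = NULL) {
  samples <- names(unmapped_reads)
  score_all <- function(lib) {
    do.call(rbind, lapply(samples, function(s) {
      score_hits(align_to_junctions(unmapped_reads[[s]], lib), lib, s)
    }))
  }
  true_hits <- score_all(lib_true)
  decoy_hits <- lapply(decoy_libs, score_all)
  if (is.null(params))
    params <- tune_parameters(true_hits, decoy_hits, lib_true, decoy_libs)
  compat <- junction_compatibility(lib_true)
  calls <- call_sample(filter_hits(true_hits, params), lib_true, compat)
  n_decoy <- 0L
  for (k in seq_along(decoy_hits)) {
    dh <- filter_hits(decoy_hits[[k]], params)
    if (nrow(dh) > 0L)
      n_decoy <- n_decoy + nrow(call_sample(dh, decoy_libs[[k]]))
  }
  list(params = params, calls = calls, n_decoy_calls = n_decoy)
}
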