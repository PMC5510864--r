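#' The 26-population / 5-superpopulation cohort layout
#'
#' Standard population codes grouped into the five continental
#' superpopulations (AFR, AMR, EAS, EUR, SAS).
#'
#' @return `data.frame` with `population` and `superpop`.
#' @export
default_populations <- function() {
  data.frame(
    population = c("ACB", "ASW", "ESN", "GWD", "LWK", "MSL", "YRI",
                   "CLM", "MXL", "PEL", "PUR",
                   "CDX", "CHB", "CHS", "JPT", "KHV",
                   "CEU", "FIN", "GBR", "IBS", "TSI",
                   "BEB", "GIH", "ITU", "PJL", "STU"),
    superpop = rep(c("AFR", "AMR", "EAS", "EUR", "SAS"),
                   times = c(7L, 4L, 5L, 5L, 5L)),
    stringsAsFactors = FALSE)
}

#' Generate a toy genome with assembly gaps
#'
#' Uniform random bases (GC fraction 0.5) with a few N-run gaps per
#' chromosome, plus the matching gap track.
#'
#' @param seed RNG seed.
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_len Chromosome length in bases (default 1e6).
#' @param n_gaps Gaps per chromosome (default 2).
#' @param gap_len Gap length in bases (default 5000).
#' @return List with `genome` (`DNAStringSet`) and `gaps` (`GRanges`).
#' @export
make_genome <- function(seed = 1L, n_chrom = 2L, chrom_len = 1e6L,
                        n_gaps = 2L, gap_len = 5000L) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  seqs <- character(n_chrom)
  gap_rows <- list()
  for (i in seq_len(n_chrom)) {
    s <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    if (n_gaps > 0L) {
      slots <- floor(seq(chrom_len * 0.3, chrom_len * 0.7,
                         length.out = n_gaps))
      for (g in slots) {
        s[g:(g + gap_len - 1L)] <- "N"
        gap_rows[[length(gap_rows) + 1L]] <-
          data.frame(chrom = chroms[i], start = g, end = g + gap_len - 1L)
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  gaps <- if (length(gap_rows)) {
    gg <- do.call(rbind, gap_rows)
    GenomicRanges::GRanges(gg$chrom, IRanges::IRanges(gg$start, gg$end))
  } else GenomicRanges::GRanges()
  list(genome = genome, gaps = gaps)
}

#' Generate a toy multi-exon gene annotation
#'
#' Non-overlapping protein-coding genes with several exons each, placed
#' clear of assembly gaps, on random strands.
#'
#' @param genome Named `DNAStringSet`.
#' @param gaps `GRanges` of gaps to avoid.
#' @param n_genes Number of genes (default 30).
#' @param exons_per_gene Range of exon counts sampled per gene
#'   (default 4:8).
#' @param exon_len Range of exon lengths (default c(150, 300)).
#' @param intron_len Range of intron lengths (default c(500, 2000)).
#' @param seed RNG seed.
#' @return List with `genes` (named `GRangesList` of exons, the
#'   [read_annotation()] layout) and `features` (flat `GRanges` with
#'   gene/transcript/exon rows, exportable as GTF).
#' @export
make_annotation <- function(genome, gaps = NULL, n_genes = 30L,
                            exons_per_gene = 4:8, exon_len = c(150L, 300L),
                            intron_len = c(500L, 2000L), seed = 1L) {
  set.seed(seed)
  chroms <- names(genome)
  occupied <- if (is.null(gaps)) GenomicRanges::GRanges() else gaps
  gene_list <- list()
  feat <- list()
  placed <- 0L
  tries <- 0L
  while (placed < n_genes && tries < 50L * n_genes) {
    tries <- tries + 1L
    k <- sample(exons_per_gene, 1L)
    el <- sample(exon_len[1]:exon_len[2], k, replace = TRUE)
    il <- sample(intron_len[1]:intron_len[2], k - 1L, replace = TRUE)
    span <- sum(el) + sum(il)
    chrom <- sample(chroms, 1L)
    start <- sample.int(length(genome[[chrom]]) - span - 200L, 1L)
    cand <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(start, start + span - 1L))
    if (length(GenomicRanges::findOverlaps(cand, occupied)) > 0L) next
    occupied <- c(occupied, GenomicRanges::resize(cand, span + 2000L,
                                                  fix = "center"))
    placed <- placed + 1L
    gid <- sprintf("G%03d", placed)
    strand <- sample(c("+", "-"), 1L)
    starts <- start + cumsum(c(0L, el[-k] + il))
    ex <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(starts, width = el),
                                 strand = strand)
    gene_list[[gid]] <- ex
    gene_row <- GenomicRanges::GRanges(chrom,
                                       IRanges::IRanges(start, start + span - 1L),
                                       strand = strand)
    gr_all <- c(gene_row, gene_row, ex)
    gr_all$type <- c("gene", "transcript", rep("exon", k))
    gr_all$gene_id <- gid
    gr_all$transcript_id <- c(NA, paste0(gid, ".1"),
                              rep(paste0(gid, ".1"), k))
    gr_all$gene_type <- "protein_coding"
    feat[[gid]] <- gr_all
  }
  genes <- GenomicRanges::GRangesList(gene_list)
  features <- unlist(GenomicRanges::GRangesList(feat), use.names = FALSE)
  list(genes = genes, features = features)
}

#' Write toy annotation features as GTF
#'
#' @param features The `features` element of [make_annotation()].
#' @param path Output path (.gtf).
#' @export
write_annotation_gtf <- function(features, path) {
  rtracklayer::export(features, path, format = "gtf")
  invisible(path)
}

#' Spliced transcript sequence of (part of) a gene
#'
#' Concatenates the included exons in transcription order, in transcript
#' orientation (reverse-complemented for minus-strand genes).
#'
#' @param genes Named `GRangesList` of exons.
#' @param genome Named `DNAStringSet`.
#' @param gene_id Gene to splice.
#' @param included_exons Transcription-order exon indices; `NULL` (default)
#'   means all. Retrocopies are 5'-truncated, so a non-trivial selection
#'   must be a suffix (e.g. `2:k`).
#' @return Character transcript sequence.
#' @export
retro_transcript <- function(genes, genome, gene_id, included_exons = NULL) {
  ex <- genes[[gene_id]]
  k <- length(ex)
  strand <- as.character(GenomicRanges::strand(ex))[1]
  ord <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
  if (is.null(included_exons)) included_exons <- seq_len(k)
  stopifnot(all(diff(included_exons) == 1L),
            included_exons[length(included_exons)] == k)
  chrom_seq <- genome[[as.character(GenomeInfoDb::seqnames(ex))[1]]]
  pieces <- vapply(included_exons, function(i) {
    g <- ord[i]
    s <- Biostrings::subseq(chrom_seq, GenomicRanges::start(ex)[g],
                            GenomicRanges::end(ex)[g])
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  paste(pieces, collapse = "")
}

#' Construct a retrocopy insertion event
#'
#' @param parent_gene Gene id.
#' @param insertion_chrom,insertion_pos Insertion point (the new sequence
#'   goes in after `insertion_pos`).
#' @param included_exons Transcription-order suffix of exons (`NULL` = all).
#' @param orientation Insert orientation relative to the genome.
#' @param polyA_len Poly-A tail length (default 30).
#' @param tsd_len Target-site duplication length (default 15).
#' @param l1_len Length of a co-inserted L1 fragment appended 3' of the
#'   tail, 0 for none.
#' @param l1_subfamily Label for the co-inserted L1.
#' @return A `retrocopy_event` list.
#' @export
retrocopy_event <- function(parent_gene, insertion_chrom, insertion_pos,
                            included_exons = NULL, orientation = "+",
                            polyA_len = 30L, tsd_len = 15L, l1_len = 0L,
                            l1_subfamily = "L1HS") {
  structure(list(parent_gene = parent_gene,
                 insertion_chrom = insertion_chrom,
                 insertion_pos = as.integer(insertion_pos),
                 included_exons = included_exons,
                 orientation = orientation,
                 polyA_len = as.integer(polyA_len),
                 tsd_len = as.integer(tsd_len),
                 l1_len = as.integer(l1_len),
                 l1_subfamily = l1_subfamily),
            class = "retrocopy_event")
}

#' Plant a retrocopy allele into the genome
#'
#' The inserted sequence is the spliced transcript (reverse-complemented
#' for orientation `-`), a poly-A tail, and an optional L1 fragment; the
#' `tsd_len` bases immediately left of the insertion point are duplicated on
#' the right flank (target-site duplication).
#'
#' @param genome Named `DNAStringSet`.
#' @param genes Named `GRangesList` of exons.
#' @param event A [retrocopy_event()].
#' @return List with `insert_seq`, `alt_seq` (the full alternate haplotype
#'   sequence of the affected chromosome), `transcript_len`, and `truth`
#'   (one-row `data.frame` describing the planted allele).
#' @export
plant_retrocopy <- function(genome, genes, event) {
  tx <- retro_transcript(genes, genome, event$parent_gene,
                         event$included_exons)
  body <- if (event$orientation == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  else tx
  l1 <- if (event$l1_len > 0L)
    paste(sample(c("A", "C", "G", "T"), event$l1_len, replace = TRUE,
                 prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "") else ""
  insert <- paste0(body, strrep("A", event$polyA_len), l1)
  chrom_seq <- as.character(genome[[event$insertion_chrom]])
  p <- event$insertion_pos
  t <- event$tsd_len
  alt <- paste0(substr(chrom_seq, 1L, p), insert,
                substr(chrom_seq, p - t + 1L, nchar(chrom_seq)))
  truth <- data.frame(gene_id = event$parent_gene,
                      chrom = event$insertion_chrom,
                      pos = p, orientation = event$orientation,
                      insert_len = nchar(insert),
                      transcript_len = nchar(tx),
                      polyA_len = event$polyA_len,
                      tsd_len = event$tsd_len,
                      l1_len = event$l1_len,
                      l1_subfamily = if (event$l1_len > 0L) event$l1_subfamily
                                     else NA_character_,
                      stringsAsFactors = FALSE)
  list(insert_seq = insert, alt_seq = alt, transcript_len = nchar(tx),
       truth = truth)
}

#' Simulate exome reads of one individual's retrocopy alleles
#'
#' Reads are drawn uniformly along each carried retrocopy's transcript
#' (plus poly-A tail) at the given coverage, with uniform substitution
#' errors and random sequencing strand. Reads that span an exon-exon
#' boundary (or run into the tail) cannot map to the reference genome and
#' are returned as the individual's unmapped read set; reads fully inside
#' one exon would map and are not emitted.
#'
#' @param genome,genes Toy genome and annotation.
#' @param events List of [retrocopy_event()]s carried by the individual.
#' @param coverage Mean exome depth (default 65.7).
#' @param read_len Read length (default 76).
#' @param error_rate Per-base substitution rate (default 0.005).
#' @param sample_id Read-name prefix.
#' @param seed Optional RNG seed.
#' @return List with `unmapped` (named character vector of read sequences),
#'   `truth` (`data.frame`: per read, its gene, junction id or `"polyA"`,
#'   transcript position, error count) and `boundary_support`
#'   (`data.frame`: reads spanning each exon-exon boundary).
#' @export
simulate_wes <- function(genome, genes, events, coverage = 65.7,
                         read_len = 76L, error_rate = 0.005,
                         sample_id = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reads <- character(0); truth <- list()
  for (ev in events) {
    ex <- genes[[ev$parent_gene]]
    k <- length(ex)
    inc <- ev$included_exons %||% seq_len(k)
    tx <- retro_transcript(genes, genome, ev$parent_gene, inc)
    full <- paste0(tx, strrep("A", ev$polyA_len))
    L <- nchar(full)
    if (L < read_len) next
    strand <- as.character(GenomicRanges::strand(ex))[1]
    ord <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
    widths <- GenomicRanges::width(ex)[ord][inc]
    cum <- cumsum(widths)                       # boundaries after each exon
    n_reads <- stats::rpois(1L, coverage * L / read_len)
    if (n_reads == 0L) next
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    for (s in starts) {
      e <- s + read_len - 1L
      # which boundary (between consecutive included exons) does it span?
      bidx <- which(s <= cum[-length(cum)] & e >= cum[-length(cum)] + 1L)
      in_tail <- e > nchar(tx)
      if (length(bidx) == 0L && !in_tail) next  # maps to the genome
      if (s > nchar(tx)) next                   # entirely poly-A
      raw <- substr(full, s, e)
      n_err <- stats::rbinom(1L, read_len, error_rate)
      seq <- raw
      if (n_err > 0L) {
        at <- sample.int(read_len, n_err)
        ch <- strsplit(seq, "")[[1]]
        for (a in at) ch[a] <- sample(setdiff(c("A", "C", "G", "T"), ch[a]), 1L)
        seq <- paste(ch, collapse = "")
      }
      if (stats::runif(1) < 0.5)
        seq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(seq)))
      jid <- if (length(bidx) > 0L)
        sprintf("%s:e%d-e%d", ev$parent_gene, inc[bidx[1]], inc[bidx[1] + 1L])
      else "polyA"
      reads <- c(reads, seq)
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = ev$parent_gene, junction = jid, tx_pos = s,
        n_errors = n_err, raw = raw, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), junction = character(),
               tx_pos = integer(), n_errors = integer(), raw = character())
  if (length(reads)) names(reads) <- sprintf("%s_u%05d", sample_id,
                                             seq_along(reads))
  bs <- truth[truth$junction != "polyA", , drop = FALSE]
  boundary_support <- if (nrow(bs)) {
    stats::aggregate(list(n_reads = bs$tx_pos),
                     by = list(gene_id = bs$gene_id, junction = bs$junction),
                     FUN = length)
  } else data.frame(gene_id = character(), junction = character(),
                    n_reads = integer())
  list(unmapped = reads, truth = truth, boundary_support = boundary_support)
}

#' Verify simulated reads against their truth records
#'
#' Each emitted read must equal the recorded transcript substring up to its
#' recorded number of substitution errors (on one of the two strands).
#'
#' @param sim A [simulate_wes()] result.
#' @return `TRUE` invisibly; errors out on the first inconsistent read.
#' @export
verify_wes_reads <- function(sim) {
  for (i in seq_along(sim$unmapped)) {
    seq <- sim$unmapped[i]
    raw <- sim$truth$raw[i]
    mm_fwd <- sum(charToRaw(seq) != charToRaw(raw))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    mm_rev <- sum(charToRaw(rc) != charToRaw(raw))
    if (min(mm_fwd, mm_rev) != sim$truth$n_errors[i])
      stop("read ", names(sim$unmapped)[i], " inconsistent with truth record")
  }
  invisible(TRUE)
}

#' Simulate pooled whole-genome read pairs around retrocopy insertions
#'
#' For each carrier haplotype, fragments are placed uniformly over a window
#' around the planted insertion on the alternate haplotype at the per-genome
#' coverage; insert sizes are truncated-normal (minimum twice the read
#' length). A pair becomes discordant when one read falls inside the insert
#' (it maps back to the parent gene's exons) and its mate falls in the
#' flanking genome (it maps at the insertion site). Reads landing in the
#' poly-A tail or a co-inserted L1 fragment are emitted with mapping quality
#' 0, which is how a long L1 co-insertion turns an event single-sided.
#'
#' @param genome,genes Toy genome and annotation.
#' @param events List of [retrocopy_event()]s (one per planted insertion).
#' @param n_carriers Carrier individuals contributing to the pool (one
#'   alternate haplotype each).
#' @param coverage Per-genome depth (default 7.4).
#' @param read_len Read length (default 100).
#' @param insert_mean,insert_sd Fragment-size distribution (default 300/50).
#' @param population Population label on the records.
#' @param seed Optional RNG seed.
#' @return `data.frame` of alignment records in the [read_sam()] layout
#'   plus a `population` column.
#' @export
simulate_wgs_pairs <- function(genome, genes, events, n_carriers = 10L,
                               coverage = 7.4, read_len = 100L,
                               insert_mean = 300, insert_sd = 50,
                               population = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recs <- list()
  rid <- 0L
  for (ev in events) {
    planted <- plant_retrocopy(genome, genes, ev)
    Li <- planted$truth$insert_len
    Lt <- planted$truth$transcript_len
    p <- ev$insertion_pos
    t <- ev$tsd_len
    ex <- genes[[ev$parent_gene]]
    strand <- as.character(GenomicRanges::strand(ex))[1]
    k <- length(ex)
    ord <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
    inc <- ev$included_exons %||% seq_len(k)
    widths <- GenomicRanges::width(ex)[ord][inc]
    cum <- cumsum(widths)
    gene_chrom <- as.character(GenomeInfoDb::seqnames(ex))[1]
    # map transcript offset -> genomic position of that base
    tx2genomic <- function(o) {
      if (ev$orientation == "-") o <- Lt - o + 1L
      i <- findInterval(o - 1L, c(0L, cum))      # included-exon index
      within <- o - c(0L, cum)[i] - 1L
      g <- ord[inc[i]]
      if (strand == "+") GenomicRanges::start(ex)[g] + within
      else GenomicRanges::end(ex)[g] - within
    }
    margin <- as.integer(insert_mean + 4 * insert_sd)
    win_lo <- p - margin
    win_len <- Li + 2L * margin
    cov_hap <- coverage / 2
    for (carrier in seq_len(n_carriers)) {
      n_frag <- stats::rpois(1L, win_len * cov_hap / (2 * read_len))
      if (n_frag == 0L) next
      is_len <- pmax(2L * read_len,
                     as.integer(round(stats::rnorm(n_frag, insert_mean,
                                                   insert_sd))))
      fs <- win_lo + as.integer(floor(stats::runif(n_frag) * (win_len - is_len)))
      for (f in seq_len(n_frag)) {
        a1 <- c(fs[f], fs[f] + is_len[f] - read_len)   # read starts (alt)
        a2 <- a1 + read_len - 1L                        # read ends
        region <- function(lo, hi) {
          if (hi <= p) "left" else if (lo > p + Li) "right"
          else if (lo > p && hi <= p + Li) "insert" else "straddle"
        }
        rg <- c(region(a1[1], a2[1]), region(a1[2], a2[2]))
        if (any(rg == "straddle")) next
        if (all(rg %in% c("left", "right")) && rg[1] == rg[2]) next
        rid <- rid + 1L
        qname <- sprintf("%s_p%06d", population, rid)
        for (m in 1:2) {
          strand_m <- if (m == 1L) "+" else "-"
          flag <- 1L + if (m == 1L) 64L else 128L
          if (strand_m == "-") flag <- flag + 16L else flag <- flag + 32L
          if (rg[m] == "left") {
            chrom <- ev$insertion_chrom; pos <- a1[m]; mapq <- 60L
          } else if (rg[m] == "right") {
            chrom <- ev$insertion_chrom; pos <- a1[m] - Li - t; mapq <- 60L
          } else {
            o <- a1[m] - p
            if (o + read_len - 1L <= Lt) {
              gpos <- tx2genomic(o)
              chrom <- gene_chrom
              pos <- max(1L, gpos - if (ev$orientation == "-" || strand == "-")
                read_len - 1L else 0L)
              mapq <- 60L
            } else {
              chrom <- ev$insertion_chrom; pos <- p; mapq <- 0L   # poly-A / L1
            }
          }
          recs[[length(recs) + 1L]] <- data.frame(
            read_id = qname, flag = flag, mapped = TRUE, chrom = chrom,
            pos = as.integer(pos), mapq = mapq,
            cigar = sprintf("%dM", read_len), strand = strand_m,
            mate_chrom = NA_character_, mate_pos = NA_integer_,
            is_read1 = m == 1L, n_mismatch = 0L,
            seq = strrep("N", read_len), population = population,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(read_id = character(), flag = integer(),
                      mapped = logical(), chrom = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      strand = character(), mate_chrom = character(),
                      mate_pos = integer(), is_read1 = logical(),
                      n_mismatch = integer(), seq = character(),
                      population = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  # fill mate coordinates
  m1 <- out[out$is_read1, ]; m2 <- out[!out$is_read1, ]
  i1 <- match(out$read_id, m1$read_id); i2 <- match(out$read_id, m2$read_id)
  out$mate_chrom <- ifelse(out$is_read1, m2$chrom[i2], m1$chrom[i1])
  out$mate_pos <- ifelse(out$is_read1, m2$pos[i2], m1$pos[i1])
  out
}

#' Cohort design for population-level simulations
#'
#' Carrier-frequency profiles per population for M parent genes. Structure
#' `"superpop"` gives each superpopulation a private block of genes at
#' `base_freq` (plus a small shared background), the planted signal used to
#' test population trees and differentiation; `"uniform"` gives every gene
#' the same frequency everywhere (a null for the fixation-index test);
#' `"spectrum"` draws gene frequencies from a low-frequency spectrum
#' mimicking rare retrocopy alleles.
#'
#' @param n_genes Number of parent genes M.
#' @param n_per_pop Individuals per population (default 10).
#' @param structure `"superpop"`, `"uniform"` or `"spectrum"`.
#' @param base_freq Carrier frequency of the structured/private block
#'   (default 0.4).
#' @param background_freq Shared background frequency (default 0.05).
#' @param populations Population table (default [default_populations()]).
#' @param seed RNG seed.
#' @return A `cohort_design` list with `populations`, `freqs` (genes x
#'   populations), `n_per_pop`, `seed`.
#' @export
make_cohort_design <- function(n_genes = 100L, n_per_pop = 10L,
                               structure = c("superpop", "uniform", "spectrum"),
                               base_freq = 0.4, background_freq = 0.05,
                               populations = default_populations(),
                               seed = 1L) {
  structure <- match.arg(structure)
  set.seed(seed)
  pops <- populations$population
  sps <- unique(populations$superpop)
  genes <- sprintf("G%03d", seq_len(n_genes))
  freqs <- matrix(0, n_genes, length(pops), dimnames = list(genes, pops))
  if (structure == "uniform") {
    freqs[] <- base_freq
  } else if (structure == "spectrum") {
    base <- stats::rbeta(n_genes, 0.3, 3)      # rare-allele spectrum
    for (g in seq_len(n_genes))
      freqs[g, ] <- pmin(1, pmax(0, base[g] *
        stats::rgamma(length(pops), shape = 4, rate = 4)))
  } else {
    block <- split(seq_len(n_genes),
                   rep(seq_along(sps), length.out = n_genes))
    for (si in seq_along(sps)) {
      cols <- populations$superpop == sps[si]
      freqs[block[[si]], cols] <- base_freq
    }
    shared <- sample.int(n_genes, max(1L, n_genes %/% 10L))
    freqs[shared, ] <- background_freq
  }
  base::structure(list(populations = populations, freqs = freqs,
                       n_per_pop = n_per_pop, seed = seed),
                  class = "cohort_design")
}

#' Simulate a cohort: carriers, call table and expression
#'
#' Draws each individual's carrier status per parent gene from the design's
#' population frequencies, tabulates the per-individual call table, and
#' generates a normalized expression matrix in which carriers of a parent
#' gene are shifted by `carrier_effect` standard deviations.
#'
#' @param design A [make_cohort_design()].
#' @param n_expression_genes Total measured genes in the expression table
#'   (parent genes are its first rows; default 1000).
#' @param carrier_effect Expression shift of carriers in SD units
#'   (default 0).
#' @param parent_expression_shift Mean shift of parent genes relative to
#'   all measured genes in SD units (default 0).
#' @param seed Optional RNG seed (defaults to the design's).
#' @return List with `manifest`, `carriers` (individuals x genes), `calls`,
#'   `expression` (genes x individuals), `design`.
#' @export
simulate_cohort <- function(design, n_expression_genes = 1000L,
                            carrier_effect = 0, parent_expression_shift = 0,
                            seed = NULL) {
  set.seed(seed %||% design$seed)
  pops <- design$populations$population
  manifest <- data.frame(
    sample_id = sprintf("I%04d", seq_len(length(pops) * design$n_per_pop)),
    population = rep(pops, each = design$n_per_pop),
    superpop = rep(design$populations$superpop, each = design$n_per_pop),
    stringsAsFactors = FALSE)
  n <- nrow(manifest)
  genes <- rownames(design$freqs)
  pf <- design$freqs[, manifest$population, drop = FALSE]
  carriers <- matrix(stats::runif(length(genes) * n) < pf,
                     nrow = length(genes), ncol = n,
                     dimnames = list(genes, manifest$sample_id))
  carriers <- t(carriers)                     # individuals x genes
  idx <- which(carriers, arr.ind = TRUE)
  calls <- data.frame(sample_id = manifest$sample_id[idx[, 1]],
                      gene_id = genes[idx[, 2]],
                      population = manifest$population[idx[, 1]],
                      stringsAsFactors = FALSE)
  all_genes <- c(genes, sprintf("E%04d", seq_len(max(0L, n_expression_genes -
                                                       length(genes)))))
  expression <- matrix(stats::rnorm(length(all_genes) * n), length(all_genes),
                       n, dimnames = list(all_genes, manifest$sample_id))
  if (parent_expression_shift != 0)
    expression[genes, ] <- expression[genes, ] + parent_expression_shift
  if (carrier_effect != 0)
    expression[genes, ] <- expression[genes, ] +
      carrier_effect * t(carriers) * 1
  list(manifest = manifest, carriers = carriers, calls = calls,
       expression = expression, design = design)
}

#' Simulate a full exome cohort with planted retrocopies
#'
#' End-to-end driver for the junction-calling stage: builds a toy genome and
#' annotation, plants retrocopy events in genes with at least four exons
#' (optionally 5'-truncated, always keeping four or more exons so that two
#' genomically disjoint junctions exist and the event is detectable in
#' principle), assigns carriers per population at the given frequencies, and
#' simulates each carrier's unmapped junction-spanning reads.
#'
#' @param seed RNG seed for the whole simulation.
#' @param n_events Number of planted parent genes (default 8).
#' @param n_per_pop Individuals per population (default 10).
#' @param freq_range Carrier-frequency range sampled per gene
#'   (default c(0.05, 0.3)).
#' @param coverage,read_len,error_rate Exome read parameters
#'   (defaults 65.7x, 76 bp, 0.005).
#' @param truncation_prob Chance that an event is 5'-truncated
#'   (default 0.3).
#' @param populations Population table (default [default_populations()]).
#' @param n_genes,exons_per_gene Annotation scale (defaults 30 genes, 4-8
#'   exons).
#' @return List with `genome`, `gaps`, `genes`, `events` (by gene id),
#'   `manifest`, `carriers` (individuals x event genes), `reads` (named
#'   list per sample of unmapped read sets; empty for non-carriers) and
#'   `truth_support` (per sample and gene, junction-spanning read counts).
#' @export
simulate_retro_wes_cohort <- function(seed = 1L, n_events = 8L,
                                      n_per_pop = 10L,
                                      freq_range = c(0.05, 0.3),
                                      coverage = 65.7, read_len = 76L,
                                      error_rate = 0.005,
                                      truncation_prob = 0.3,
                                      populations = default_populations(),
                                      n_genes = 30L, exons_per_gene = 4:8) {
  set.seed(seed)
  gen <- make_genome(seed = seed)
  ann <- make_annotation(gen$genome, gen$gaps, n_genes = n_genes,
                         exons_per_gene = exons_per_gene, seed = seed)
  genes <- ann$genes
  eligible <- names(genes)[lengths(genes) >= 4L]
  target <- sample(eligible, min(n_events, length(eligible)))
  chroms <- names(gen$genome)
  events <- lapply(target, function(g) {
    k <- length(genes[[g]])
    inc <- if (k >= 5L && stats::runif(1) < truncation_prob)
      (k - 3L):k else NULL                      # 5' truncation, keep >= 4
    retrocopy_event(g,
                    insertion_chrom = sample(chroms, 1L),
                    insertion_pos = sample(2e5:8e5, 1L),
                    included_exons = inc,
                    orientation = sample(c("+", "-"), 1L))
  })
  names(events) <- target
  freqs <- stats::runif(length(target), freq_range[1], freq_range[2])
  names(freqs) <- target
  manifest <- data.frame(
    sample_id = sprintf("I%04d", seq_len(nrow(populations) * n_per_pop)),
    population = rep(populations$population, each = n_per_pop),
    superpop = rep(populations$superpop, each = n_per_pop),
    stringsAsFactors = FALSE)
  n <- nrow(manifest)
  carriers <- matrix(stats::runif(n * length(target)) <
                       rep(freqs, each = n),
                     nrow = n, dimnames = list(manifest$sample_id, target))
  reads <- vector("list", n); names(reads) <- manifest$sample_id
  support <- list()
  for (i in seq_len(n)) {
    ev <- events[carriers[i, ]]
    if (length(ev) == 0L) { reads[[i]] <- character(0); next }
    sim <- simulate_wes(gen$genome, genes, ev, coverage = coverage,
                        read_len = read_len, error_rate = error_rate,
                        sample_id = manifest$sample_id[i])
    reads[[i]] <- sim$unmapped
    if (nrow(sim$boundary_support)) {
      sim$boundary_support$sample_id <- manifest$sample_id[i]
      support[[length(support) + 1L]] <- sim$boundary_support
    }
  }
  truth_support <- if (length(support)) do.call(rbind, support) else
    data.frame(gene_id = character(), junction = character(),
               n_reads = integer(), sample_id = character())
  list(genome = gen$genome, gaps = gen$gaps, genes = genes, events = events,
       manifest = manifest, carriers = carriers, reads = reads,
       truth_support = truth_support)
}

#' Recovery rate of planted retrocopies
#'
#' Fraction of planted (sample, parent gene) events recovered by the
#' caller, restricted to events with at least `min_reads` junction-spanning
#' reads in the simulation truth (events with fewer reads carry too little
#' evidence to be callable and are not counted against the caller).
#'
#' @param calls [call_sample()]-style calls with `sample_id`, `gene_id`.
#' @param truth_support `truth_support` of
#'   [simulate_retro_wes_cohort()].
#' @param min_reads Minimum truth-level junction reads (default 3).
#' @return List with `rate`, `n_eligible`, `n_recovered`.
#' @export
recovery_rate <- function(calls, truth_support, min_reads = 3L) {
  tot <- stats::aggregate(list(n_reads = truth_support$n_reads),
                          by = list(sample_id = truth_support$sample_id,
                                    gene_id = truth_support$gene_id),
                          FUN = sum)
  eligible <- tot[tot$n_reads >= min_reads, , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$gene_id)
  hit <- key(eligible) %in% key(calls)
  list(rate = if (nrow(eligible)) mean(hit) else NA_real_,
       n_eligible = nrow(eligible), n_recovered = sum(hit))
}
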