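#' Build the true exon-junction library
#'
#' A retrocopy is an intron-less gene copy, so exome reads from it span
#' exon-exon junctions that do not exist in the reference genome. The true
#' junction library contains, for every gene with at least two protein-coding
#' exons, all ordered exon pairs (i, j), i < j in transcription order — not
#' only adjacent pairs, because retrocopies are frequently 5'-truncated and
#' may omit internal exons. Each junction joins the terminal `flank` bases of
#' the upstream exon to the leading `flank` bases of the downstream exon, in
#' transcript orientation (minus-strand genes are reverse-complemented).
#' Exons shorter than `flank` contribute their full length. Junctions whose
#' sequences are identical within a gene (duplicate exon structures) are kept
#' once, under the first junction id.
#'
#' @param genes Named `GRangesList` of exons per gene, as returned by
#'   [read_annotation()].
#' @param genome Named `DNAStringSet` with the chromosome sequences.
#' @param flank Maximum exon-segment length in bases (default 100).
#' @return A `junction_library` object: list with `kind` (`"true"`), `e`
#'   (`NA` for the true library), and `junctions`, a `data.frame` with one
#'   row per junction (`junction_id`, `gene_id`, `up_idx`, `down_idx`,
#'   chromosome/coordinates of both segments, `strand`, `offset` = bases
#'   contributed by the upstream segment, `seq`).
#' @export
build_true_library <- function(genes, genome, flank = 100L) {
  build_library(genes, genome, flank = flank, kind = "true", e = NA_integer_)
}

#' Build a shifted decoy exon-junction library
#'
#' Decoy libraries contain fake junctions built from exon annotations shifted
#' inward by `e` bases on both sides (start + e, end − e). No real read
#' should map across a decoy junction, so any decoy call is a false positive;
#' the calling parameters are tuned until every decoy library is silent.
#' Shifted exons with non-positive length are dropped.
#'
#' @inheritParams build_true_library
#' @param e Shift in bases; the standard set is 1, 2, 3, 6 and 12.
#' @return A `junction_library` with `kind = "decoy"`.
#' @export
build_decoy_library <- function(genes, genome, e, flank = 100L) {
  e <- as.integer(e)
  stopifnot(length(e) == 1L, e >= 1L)
  shifted <- S4Vectors::endoapply(genes, function(g) {
    g <- GenomicRanges::narrow(g[GenomicRanges::width(g) > 2L * e],
                               start = e + 1L, end = -(e + 1L))
    g
  })
  build_library(shifted, genome, flank = flank, kind = "decoy", e = e)
}

#' The standard set of five decoy libraries
#'
#' @inheritParams build_true_library
#' @param shifts Integer vector of shifts (default `c(1, 2, 3, 6, 12)`).
#' @return Named list of `junction_library` objects, one per shift.
#' @export
build_decoy_libraries <- function(genes, genome, shifts = c(1L, 2L, 3L, 6L, 12L),
                                  flank = 100L) {
  out <- lapply(shifts, function(e) build_decoy_library(genes, genome, e, flank))
  names(out) <- paste0("decoy_e", shifts)
  out
}

build_library <- function(genes, genome, flank, kind, e) {
  rows <- vector("list", length(genes))
  gids <- names(genes)
  for (gi in seq_along(genes)) {
    ex <- genes[[gi]]
    k <- length(ex)
    if (k < 2L) next
    strand <- as.character(GenomicRanges::strand(ex))[1]
    chrom <- as.character(GenomeInfoDb::seqnames(ex))[1]
    # transcription order: genomic order for +, reversed for -
    ord <- if (strand == "-") rev(seq_len(k)) else seq_len(k)
    st <- GenomicRanges::start(ex)[ord]
    en <- GenomicRanges::end(ex)[ord]
    fl <- pmin(flank, en - st + 1L)
    chrom_seq <- genome[[chrom]]
    # per-exon flank sequences in transcript orientation
    don <- acc <- character(k)   # donor = exon 3' end, acceptor = exon 5' start
    for (i in seq_len(k)) {
      if (strand == "+") {
        don[i] <- as.character(Biostrings::subseq(chrom_seq, en[i] - fl[i] + 1L, en[i]))
        acc[i] <- as.character(Biostrings::subseq(chrom_seq, st[i], st[i] + fl[i] - 1L))
      } else {
        don[i] <- as.character(Biostrings::reverseComplement(
          Biostrings::subseq(chrom_seq, st[i], st[i] + fl[i] - 1L)))
        acc[i] <- as.character(Biostrings::reverseComplement(
          Biostrings::subseq(chrom_seq, en[i] - fl[i] + 1L, en[i])))
      }
    }
    pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    i <- pairs[, 1L]; j <- pairs[, 2L]
    seqs <- paste0(don[i], acc[j])
    keep <- !duplicated(seqs)      # dedup identical junction sequences
    i <- i[keep]; j <- j[keep]; seqs <- seqs[keep]
    rows[[gi]] <- data.frame(
      junction_id = sprintf("%s:e%d-e%d", gids[gi], i, j),
      gene_id = gids[gi],
      up_idx = i, down_idx = j,
      chrom = chrom,
      up_start = st[i], up_end = en[i],
      down_start = st[j], down_end = en[j],
      strand = strand,
      offset = fl[i],
      seq = seqs,
      stringsAsFactors = FALSE)
  }
  junc <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(junc)) {
    junc <- data.frame(junction_id = character(), gene_id = character(),
                       up_idx = integer(), down_idx = integer(),
                       chrom = character(), up_start = integer(),
                       up_end = integer(), down_start = integer(),
                       down_end = integer(), strand = character(),
                       offset = integer(), seq = character(),
                       stringsAsFactors = FALSE)
  }
  rownames(junc) <- NULL
  structure(list(kind = kind, e = e, junctions = junc),
            class = "junction_library")
}

#' @export
print.junction_library <- function(x, ...) {
  lab <- if (x$kind == "true") "true" else sprintf("decoy (e = %d)", x$e)
  cat(sprintf("Exon-junction library [%s]: %d junctions from %d gene(s)\n",
              lab, nrow(x$junctions), length(unique(x$junctions$gene_id))))
  invisible(x)
}

#' Write a junction library to FASTA
#'
#' One record per junction; the header encodes junction id, gene id and
#' junction offset as `junction_id gene_id offset`, so the library can be
#' used as an alignment target and parsed back with
#' [read_library_fasta()].
#'
#' @param lib A `junction_library`.
#' @param path Output FASTA path.
#' @export
write_library_fasta <- function(lib, path) {
  seqs <- Biostrings::DNAStringSet(lib$junctions$seq)
  names(seqs) <- sprintf("%s %s %d", lib$junctions$junction_id,
                         lib$junctions$gene_id, lib$junctions$offset)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_library_fasta
#' @param kind Library kind recorded on the parsed object.
#' @param e Decoy shift recorded on the parsed object.
#' @return `read_library_fasta`: a `junction_library` (segment coordinates,
#'   not encoded in FASTA headers, are `NA`).
#' @export
read_library_fasta <- function(path, kind = "true", e = NA_integer_) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    return(structure(list(kind = kind, e = e,
                          junctions = build_library(GenomicRanges::GRangesList(),
                                                    NULL, 100L, kind, e)$junctions),
                     class = "junction_library"))
  }
  parts <- strsplit(names(seqs), " ", fixed = TRUE)
  jid <- vapply(parts, `[`, character(1), 1L)
  gid <- vapply(parts, `[`, character(1), 2L)
  off <- as.integer(vapply(parts, `[`, character(1), 3L))
  idx <- t(vapply(strsplit(sub("^.*:e", "", jid), "-e"), function(p)
    as.integer(p), integer(2)))
  junc <- data.frame(junction_id = jid, gene_id = gid,
                     up_idx = idx[, 1L], down_idx = idx[, 2L],
                     chrom = NA_character_, up_start = NA_integer_,
                     up_end = NA_integer_, down_start = NA_integer_,
                     down_end = NA_integer_, strand = NA_character_,
                     offset = off, seq = as.character(seqs),
                     stringsAsFactors = FALSE)
  structure(list(kind = kind, e = e, junctions = junc),
            class = "junction_library")
}

#' Write a junction-library manifest table
#'
#' TSV with junction id, gene, the coordinates of both exon segments and the
#' junction offset.
#'
#' @param lib A `junction_library`.
#' @param path Output TSV path.
#' @export
write_library_manifest <- function(lib, path) {
  write_table(lib$junctions[, setdiff(names(lib$junctions), "seq")], path)
}
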