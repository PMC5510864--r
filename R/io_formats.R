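#' Read gene annotation (GFF3/GTF) as per-gene exon sets
#'
#' Parses a GFF3 or GTF file and returns, for every protein-coding gene, its
#' distinct protein-coding exons sorted by genomic coordinate. Exons shared by
#' several transcripts of the same gene appear once. All intervals are
#' represented as `GRanges` (1-based, closed), the package-wide convention;
#' the 1-based inclusive GFF/GTF coordinates are converted on read by
#' `rtracklayer`.
#'
#' @param path Path to a GFF3 or GTF file (gzip accepted).
#' @param coding_only Keep only features annotated as protein coding when the
#'   file carries a `gene_type`/`gene_biotype` attribute. Default `TRUE`.
#' @return A named `GRangesList`, one element per gene, exons sorted by
#'   start coordinate. Strand is taken from the exon features.
#' @export
read_annotation <- function(path, coding_only = TRUE) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) stop(annotation_parse_error(path, conditionMessage(e)))
  )
  if (!"type" %in% names(S4Vectors::mcols(gr)))
    stop("annotation file has no feature type column: ", path)
  ex <- gr[as.character(gr$type) == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  biotype_col <- intersect(c("gene_type", "gene_biotype"),
                           names(S4Vectors::mcols(ex)))
  if (coding_only && length(biotype_col)) {
    bt <- as.character(S4Vectors::mcols(ex)[[biotype_col[1]]])
    ex <- ex[is.na(bt) | bt == "protein_coding"]
  }
  if (!"gene_id" %in% names(S4Vectors::mcols(ex)))
    stop("exon features carry no gene_id attribute: ", path)
  gid <- as.character(ex$gene_id)
  S4Vectors::mcols(ex) <- NULL
  grl <- GenomicRanges::split(ex, gid)
  grl <- S4Vectors::endoapply(grl, function(g) {
    g <- unique(g)           # transcripts sharing an exon contribute it once
    sort(g, ignore.strand = TRUE)
  })
  grl
}

# Locate the first structurally bad line so parse failures are actionable.
annotation_parse_error <- function(path, msg) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 9)
      return(sprintf("malformed annotation line %d in %s: %s", i, path, msg))
  }
  sprintf("failed to parse annotation %s: %s", path, msg)
}

#' Read a FASTA file
#'
#' @param path FASTA file path (gzip accepted).
#' @return A named `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#'
#' @param seqs Named `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED input is 0-based half-open; `rtracklayer` converts to the internal
#' 1-based closed `GRanges` convention. Intervals on chromosomes absent from
#' `genome` are dropped with a warning.
#'
#' @param path BED file path (gzip accepted).
#' @param genome Optional `DNAStringSet` (or character vector of chromosome
#'   names) used to validate chromosome names.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) {
    chroms <- if (is.character(genome)) genome else names(genome)
    bad <- !(as.character(GenomeInfoDb::seqnames(gr)) %in% chroms)
    if (any(bad)) {
      warning(sprintf("dropping %d BED interval(s) on unknown chromosome(s): %s",
                      sum(bad),
                      paste(unique(as.character(GenomeInfoDb::seqnames(gr))[bad]),
                            collapse = ", ")))
      gr <- gr[!bad]
    }
  }
  gr
}

#' Write intervals to BED
#'
#' @param gr A `GRanges`; converted back to 0-based half-open on write.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' The SAM is converted to BAM with `Rsamtools::asBam()` and scanned; flags
#' are decoded into `mapped`, `is_read1` and strand, and the `NM` tag (edit
#' distance) is surfaced as `n_mismatch` where present.
#'
#' @param path SAM file path. The file must carry `@SQ` header lines for its
#'   reference sequences.
#' @return A `data.frame` with one row per alignment record: `read_id`,
#'   `flag`, `mapped`, `chrom`, `pos`, `mapq`, `cigar`, `strand`,
#'   `mate_chrom`, `mate_pos`, `is_read1`, `n_mismatch`, `seq`.
#' @export
read_sam <- function(path) {
  dest <- tempfile(fileext = ".bam")
  on.exit(unlink(c(dest, paste0(dest, ".bai")), force = TRUE), add = TRUE)
  bam <- suppressMessages(Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                                           overwrite = TRUE, indexDestination = FALSE))
  par <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "mrnm", "mpos", "seq"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = par)[[1]]
  flag <- x$flag
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  data.frame(
    read_id = x$qname,
    flag = flag,
    mapped = bitwAnd(flag, 4L) == 0L,
    chrom = as.character(x$rname),
    pos = x$pos,
    mapq = x$mapq,
    cigar = x$cigar,
    strand = as.character(x$strand),
    mate_chrom = as.character(x$mrnm),
    mate_pos = x$mpos,
    is_read1 = bitwAnd(flag, 64L) > 0L | bitwAnd(flag, 1L) == 0L,
    n_mismatch = nm,
    seq = as.character(x$seq),
    stringsAsFactors = FALSE)
}

#' Write alignment records to a SAM file
#'
#' Companion writer for the simulators; emits a minimal valid SAM with `@SQ`
#' lines for every reference sequence.
#'
#' @param records `data.frame` in the layout produced by [read_sam()].
#'   Missing optional columns are filled with SAM defaults.
#' @param path Output path.
#' @param seq_lengths Named integer vector of reference lengths for the
#'   `@SQ` header.
#' @export
write_sam <- function(records, path, seq_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                     as.integer(seq_lengths)), con)
  n <- nrow(records)
  if (n == 0L) return(invisible(path))
  get <- function(col, default) {
    if (col %in% names(records)) records[[col]] else rep(default, n)
  }
  flag <- get("flag", 0L)
  rname <- get("chrom", "*"); rname[is.na(rname)] <- "*"
  pos <- get("pos", 0L); pos[is.na(pos)] <- 0L
  mapq <- get("mapq", 0L); mapq[is.na(mapq)] <- 0L
  cigar <- get("cigar", "*"); cigar[is.na(cigar)] <- "*"
  mrnm <- get("mate_chrom", "*"); mrnm[is.na(mrnm)] <- "*"
  mpos <- get("mate_pos", 0L); mpos[is.na(mpos)] <- 0L
  seqs <- get("seq", "*"); seqs[is.na(seqs)] <- "*"
  qual <- vapply(nchar(seqs), function(k) {
    if (k <= 1L) "*" else strrep("I", k)
  }, character(1))
  nm <- get("n_mismatch", NA_integer_)
  opt <- ifelse(is.na(nm), "", sprintf("\tNM:i:%d", nm))
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s%s",
                     records$read_id, as.integer(flag), rname, as.integer(pos),
                     as.integer(mapq), cigar, mrnm, as.integer(mpos),
                     seqs, qual, opt), con)
  invisible(path)
}

#' Read/write plain tab-separated tables
#'
#' Thin wrappers with gzip transparency; `write_table` then `read_table`
#' round-trips content.
#'
#' @param path File path (`.gz` accepted).
#' @return `read_table`: a `data.frame`.
#' @export
read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_table
#' @param records A `data.frame` to write.
#' @export
write_table <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
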