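# In-memory alignment container and SAM/BAM I/O.
#
# The pipeline's working currency is a `read_alignment`: a data.frame of
# records (one per read) plus the reference sequence lengths. SAM semantics
# are kept as-is: `flag` bit 0x4 marks unmapped reads (chrom/pos NA), `seq`
# is stored in reference-plus orientation for mapped reverse-strand reads,
# and coordinates are 1-based.

ALN_COLS <- c("qname", "flag", "chrom", "pos", "mapq", "cigar",
              "mchrom", "mpos", "seq", "qual")

#' Construct an alignment container
#'
#' @param reads data.frame with columns `qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `mchrom`, `mpos`, `seq`, `qual`. Unmapped reads have
#'   flag bit 0x4 set and NA `chrom`/`pos`/`cigar`.
#' @param seqinfo named integer vector of reference sequence lengths.
#' @param validate check per-record invariants (soft clips only at the ends,
#'   query width equal to sequence length). Costs one pass over the records.
#' @return object of class `read_alignment`.
#' @export
read_alignment <- function(reads, seqinfo, validate = TRUE) {
  stopifnot(is.data.frame(reads), all(ALN_COLS %in% names(reads)),
            is.numeric(seqinfo), !is.null(names(seqinfo)))
  reads <- reads[ALN_COLS]
  rownames(reads) <- NULL
  if (validate && nrow(reads)) {
    mapped <- !bitwAnd(reads$flag, 4L)
    if (any(mapped & (is.na(reads$chrom) | is.na(reads$pos)))) {
      stop("mapped records must have chrom and pos")
    }
    if (any(mapped & !(reads$chrom %in% names(seqinfo)))) {
      stop("record on a chromosome absent from the header")
    }
    cs <- cigar_stats(reads$cigar[mapped])  # also validates clip placement
    bad <- which(cs$qwidth != nchar(reads$seq[mapped]))
    if (length(bad)) {
      stop("CIGAR query width disagrees with sequence length for record(s): ",
           paste(head(reads$qname[mapped][bad], 3), collapse = ", "))
    }
  }
  structure(list(reads = reads, seqinfo = seqinfo), class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  n <- nrow(x$reads)
  nun <- sum(bitwAnd(x$reads$flag, 4L) != 0)
  cat("read_alignment:", n, "records (", nun, "unmapped ) on",
      length(x$seqinfo), "sequence(s)\n")
  invisible(x)
}

#' Extract the unmapped records of an alignment
#' @param aln a `read_alignment`.
#' @return data.frame of unmapped records.
#' @export
unmapped_reads <- function(aln) {
  aln$reads[bitwAnd(aln$reads$flag, 4L) != 0L, , drop = FALSE]
}

#' Sort alignment records by coordinate
#' @param aln a `read_alignment`.
#' @return the alignment, records ordered by chromosome then position,
#'   unmapped records last.
#' @export
sort_alignment <- function(aln) {
  r <- aln$reads
  chrom <- factor(r$chrom, levels = names(aln$seqinfo))
  o <- order(is.na(r$pos), as.integer(chrom), r$pos, r$qname, r$flag)
  aln$reads <- r[o, , drop = FALSE]
  rownames(aln$reads) <- NULL
  aln
}

#' Read a SAM or BAM file into an alignment container
#'
#' SAM input is converted through [Rsamtools::asBam()] (which also
#' coordinate-sorts and indexes), so malformed records or a missing header
#' fail loudly rather than truncating silently.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param region optional `list(chrom =, start =, end =)` filter; records not
#'   overlapping the region (and all unmapped records) are excluded.
#' @param include_unmapped keep unmapped records (ignored when `region` is
#'   given).
#' @return a `read_alignment`.
#' @export
read_alignment_file <- function(path, region = NULL, include_unmapped = TRUE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tmp <- tempfile()
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, destination = tmp, overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- Rsamtools::sortBam(path, destination = tmp)
    Rsamtools::indexBam(bam)
  }
  on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE), add = TRUE)

  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(hdr) || !length(hdr)) stop("alignment header has no @SQ lines: ", path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos",
            "seq", "qual")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what)
  } else {
    gr <- GenomicRanges::GRanges(region$chrom,
                                 IRanges::IRanges(region$start, region$end))
    param <- Rsamtools::ScanBamParam(what = what, which = gr)
  }
  chunks <- Rsamtools::scanBam(bam, param = param)
  fields <- names(chunks[[1]])
  res <- lapply(setNames(fields, fields), function(f) {
    unlist(lapply(chunks, function(ch) as.character(ch[[f]])),
           use.names = FALSE)
  })
  reads <- data.frame(
    qname = as.character(res$qname),
    flag = as.integer(res$flag),
    chrom = as.character(res$rname),
    pos = as.integer(res$pos),
    mapq = as.integer(res$mapq),
    cigar = as.character(res$cigar),
    mchrom = as.character(res$mrnm),
    mpos = as.integer(res$mpos),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    stringsAsFactors = FALSE)
  if (!include_unmapped && is.null(region)) {
    reads <- reads[bitwAnd(reads$flag, 4L) == 0L, , drop = FALSE]
  }
  seqinfo <- setNames(as.integer(hdr), names(hdr))
  read_alignment(reads, seqinfo)
}

#' Write an alignment container as SAM
#'
#' Records are coordinate-sorted and a minimal `@HD`/`@SQ` header is
#' emitted, so the output round-trips through [read_alignment_file()].
#'
#' @param aln a `read_alignment`.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_alignment_sam <- function(aln, path) {
  aln <- sort_alignment(aln)
  r <- aln$reads
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(aln$seqinfo),
                   as.integer(aln$seqinfo)),
           "@PG\tID:clipsv\tPN:clipsv")
  mapped <- bitwAnd(r$flag, 4L) == 0L
  rnext <- ifelse(is.na(r$mchrom), "*",
                  ifelse(!is.na(r$chrom) & r$mchrom == r$chrom, "=", r$mchrom))
  body <- paste(r$qname, r$flag,
                ifelse(mapped, r$chrom, "*"),
                ifelse(mapped, r$pos, 0L),
                ifelse(mapped, r$mapq, 0L),
                ifelse(mapped, r$cigar, "*"),
                rnext,
                ifelse(is.na(r$mpos), 0L, r$mpos),
                0L, r$seq, r$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
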