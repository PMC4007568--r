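# CIGAR bookkeeping. Decomposition is delegated to GenomicAlignments; the
# helpers here cache per-unique-cigar results because simulated libraries
# contain huge numbers of identical strings ("75M" etc).

VALID_CIGAR_RE <- "^(\\d+H)?(\\d+S)?(\\d+[MIDN=X])+(\\d+S)?(\\d+H)?$"

#' Summarise CIGAR strings
#'
#' Per-record clip lengths and reference/query widths. Hard clips are
#' reported separately: they mark a clip boundary (and so count toward
#' clusters) but carry no sequence.
#'
#' @param cigar character vector of CIGAR strings; `"*"` and `NA` give NA rows.
#' @return data.frame with columns `lsoft`, `rsoft`, `lhard`, `rhard`,
#'   `ref_width`, `qwidth` (query width including soft clips).
#' @export
cigar_stats <- function(cigar) {
  n <- length(cigar)
  out <- data.frame(lsoft = rep(NA_integer_, n), rsoft = NA_integer_,
                    lhard = NA_integer_, rhard = NA_integer_,
                    ref_width = NA_integer_, qwidth = NA_integer_)
  ok <- !is.na(cigar) & cigar != "*"
  if (!any(ok)) return(out)
  u <- unique(cigar[ok])
  bad <- !grepl(VALID_CIGAR_RE, u)
  if (any(bad)) stop("malformed CIGAR string(s): ", paste(head(u[bad], 3), collapse = ", "))
  ops <- GenomicAlignments::explodeCigarOps(u)
  lens <- GenomicAlignments::explodeCigarOpLengths(u)
  one <- function(o, l) {
    lh <- if (o[1] == "H") l[1] else 0L
    rh <- if (o[length(o)] == "H") l[length(o)] else 0L
    if (lh > 0) { o <- o[-1]; l <- l[-1] }
    if (rh > 0) { o <- o[-length(o)]; l <- l[-length(l)] }
    ls <- if (o[1] == "S") l[1] else 0L
    rs <- if (length(o) > 1 && o[length(o)] == "S") l[length(o)] else 0L
    c(ls, rs, lh, rh)
  }
  clips <- t(mapply(one, ops, lens))
  idx <- match(cigar[ok], u)
  out$lsoft[ok] <- clips[idx, 1]
  out$rsoft[ok] <- clips[idx, 2]
  out$lhard[ok] <- clips[idx, 3]
  out$rhard[ok] <- clips[idx, 4]
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(u)
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(u, after.soft.clipping = FALSE)
  out$ref_width[ok] <- rw[idx]
  out$qwidth[ok] <- qw[idx]
  out
}

# reference-space intervals of the M/=/X runs of each cigar, as a list of
# two-column matrices (start, end); used by the breakpoint classifier
match_run_ranges <- function(cigar, pos) {
  rg <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
  lapply(seq_along(rg), function(i) {
    r <- rg[[i]]
    cbind(start = IRanges::start(r), end = IRanges::end(r))
  })
}
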