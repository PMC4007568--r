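# Local alignment with soft-clipping, and breakpoint read classification.
#
# The Smith-Waterman-Gotoh kernel lives in src/local_align.cpp; it stands in
# for the external local aligner used to fix soft-clipping near candidate
# breakpoints, so tie-breaking must be fully deterministic (leftmost window
# placement, diagonal-preferring traceback).

#' Local (Smith-Waterman) alignment of a read against a reference window
#'
#' Optimal local alignment under affine-gap scoring; read ends that do not
#' take part in the optimal alignment become soft clips. A gap of length k
#' costs `gap_open + k * gap_extend` (both negative).
#'
#' @param read read sequence (character scalar).
#' @param window reference window sequence (character scalar).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`,
#'   `min_score`; see [run_config()] for defaults.
#' @return list with `score`, `ref_start`/`ref_end` (1-based inclusive
#'   window coordinates), `read_start`/`read_end`, `nmatch` (exact base
#'   matches on the path), `lclip`/`rclip` (implied soft-clip lengths),
#'   `cigar` (full CIGAR including clips), and `mapped` (FALSE when the best
#'   score is below `min_score`).
#' @export
local_align <- function(read, window, scoring = scoring_of(run_config())) {
  if (!is.character(read) || length(read) != 1 || !nzchar(read)) {
    stop("read must be a non-empty character scalar")
  }
  if (!is.character(window) || length(window) != 1 || !nzchar(window)) {
    stop("window must be a non-empty character scalar")
  }
  r <- .sw_align_cpp(read, window, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  finish_sw_result(r, nchar(read), scoring$min_score)
}

finish_sw_result <- function(r, read_len, min_score) {
  mapped <- r$score >= min_score
  if (!mapped || is.na(r$ref_start)) {
    return(list(score = r$score, ref_start = NA_integer_, ref_end = NA_integer_,
                read_start = NA_integer_, read_end = NA_integer_,
                nmatch = 0L, lclip = NA_integer_, rclip = NA_integer_,
                cigar = NA_character_, mapped = FALSE))
  }
  lclip <- r$read_start - 1L
  rclip <- read_len - r$read_end
  cigar <- paste0(if (lclip > 0) paste0(lclip, "S"), r$cigar,
                  if (rclip > 0) paste0(rclip, "S"))
  list(score = r$score, ref_start = r$ref_start, ref_end = r$ref_end,
       read_start = r$read_start, read_end = r$read_end, nmatch = r$nmatch,
       lclip = lclip, rclip = rclip, cigar = cigar, mapped = TRUE)
}

# batch interface used by the refinement loop: reads and windows are
# parallel character vectors
local_align_batch <- function(reads, windows, scoring) {
  if (!length(reads)) {
    return(data.frame(score = numeric(0), ref_start = integer(0),
                      ref_end = integer(0), read_start = integer(0),
                      read_end = integer(0), nmatch = integer(0),
                      cigar = character(0)))
  }
  .sw_align_batch_cpp(reads, windows, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
}

#' Classify reads relative to an SV breakpoint
#'
#' A breakpoint is `(chrom, pos, side)` where `pos` is the last reference
#' base before the junction on its side and `side` says on which side of an
#' aligned read the variant signal clips (`"right_clip"`: reads match up to
#' `pos` and clip after it; `"left_clip"`: reads start matching at `pos + 1`
#' and clip before it).
#'
#' A read is `soft_clipped` when it has a clip boundary within
#' `clip_tolerance` of the junction on the breakpoint's clipped side;
#' `spanning` when a single contiguous match run covers
#' `[pos - anchor + 1, pos + anchor]` and no clip boundary falls within
#' `clip_tolerance` of the junction; otherwise `neither`. Unmapped reads and
#' reads on other chromosomes are always `neither`.
#'
#' @param reads data.frame of alignment records (see [read_alignment()]) or
#'   a `read_alignment`.
#' @param breakpoint list with `chrom`, `pos`, `side`.
#' @param anchor bp of contiguous match required on both sides of the
#'   junction for a spanning call.
#' @param clip_tolerance bp slack when matching a clip boundary to the
#'   junction, absorbing one-off junction ambiguity.
#' @return character vector (one of `"spanning"`, `"soft_clipped"`,
#'   `"neither"`) parallel to the rows of `reads`.
#' @export
classify_read_at_breakpoint <- function(reads, breakpoint,
                                        anchor = 5L, clip_tolerance = 2L) {
  if (inherits(reads, "read_alignment")) reads <- reads$reads
  stopifnot(all(c("chrom", "pos", "side") %in% names(breakpoint)))
  side <- match.arg(breakpoint$side, c("right_clip", "left_clip"))
  bp <- as.integer(breakpoint$pos)
  n <- nrow(reads)
  out <- rep("neither", n)
  if (!n) return(out)

  mapped <- bitwAnd(reads$flag, 4L) == 0L & !is.na(reads$chrom) &
    reads$chrom == breakpoint$chrom
  if (!any(mapped)) return(out)
  idx <- which(mapped)
  cs <- cigar_stats(reads$cigar[idx])
  pos <- reads$pos[idx]
  end <- pos + cs$ref_width - 1L

  has_l <- (cs$lsoft + cs$lhard) > 0L
  has_r <- (cs$rsoft + cs$rhard) > 0L
  # clip boundary positions: first aligned base (left clips), last aligned
  # base (right clips); junction-adjacent bases are bp (right side) and
  # bp + 1 (left side)
  near_l <- has_l & (abs(pos - (bp + 1L)) <= clip_tolerance | abs(pos - bp) <= clip_tolerance)
  near_r <- has_r & (abs(end - bp) <= clip_tolerance | abs(end - (bp + 1L)) <= clip_tolerance)
  clipped_here <- if (side == "right_clip") {
    has_r & abs(end - bp) <= clip_tolerance
  } else {
    has_l & abs(pos - (bp + 1L)) <= clip_tolerance
  }

  # spanning: some single match run covers the anchored window, and no clip
  # boundary sits within tolerance of the junction
  lo <- bp - anchor + 1L
  hi <- bp + anchor
  maybe_span <- pos <= lo & end >= hi & !near_l & !near_r & !clipped_here
  span <- logical(length(idx))
  if (any(maybe_span)) {
    simple <- grepl("^\\d+M$", reads$cigar[idx])
    span[maybe_span & simple] <- TRUE
    hard <- which(maybe_span & !simple)
    if (length(hard)) {
      runs <- match_run_ranges(reads$cigar[idx][hard], pos[hard])
      span[hard] <- vapply(runs, function(m) {
        any(m[, "start"] <= lo & m[, "end"] >= hi)
      }, logical(1))
    }
  }
  out[idx[clipped_here]] <- "soft_clipped"
  out[idx[span & !clipped_here]] <- "spanning"
  out
}
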