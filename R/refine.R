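# Iterative refinement: detect SVs, extract breakpoint-neighbourhood and
# unmapped reads from the original alignment, realign them locally with
# soft-clipping, re-detect, and repeat until the SV set is stable.
# Concordant reads far from any candidate breakpoint are never touched,
# which is what makes the loop cheap relative to realigning the library.

#' Detect candidate SVs in an alignment
#'
#' One detection pass: soft-clip clustering ([build_clusters()]) followed by
#' partner matching ([match_partners()]).
#'
#' @param aln a `read_alignment` (coordinate-sorted).
#' @param reference named character vector of reference sequences.
#' @param config a [run_config()].
#' @return candidate SV data.frame.
#' @export
detect_svs <- function(aln, reference, config = run_config()) {
  cl <- build_clusters(aln, min_clip_len = config$min_clip_len,
                       merge_window = config$merge_window,
                       min_cluster_support = config$min_cluster_support)
  match_partners(cl, reference, config)
}

#' Extract breakpoint-neighbourhood and unmapped reads
#'
#' Returns the indices of every record whose alignment overlaps
#' `[bp - neighborhood, bp + neighborhood]` for any breakpoint of any SV,
#' grouped by SV, plus the indices of all unmapped records. Everything else
#' is left alone.
#'
#' @param aln a `read_alignment`.
#' @param svs SV data.frame (may be empty).
#' @param neighborhood half-width in bp of the window around each
#'   breakpoint.
#' @return list with `bp_reads` (data.frame `row`, `sv_id`) and
#'   `unmapped_rows` (integer vector).
#' @export
extract_candidates <- function(aln, svs, neighborhood = 650L) {
  r <- aln$reads
  unmapped_rows <- which(bitwAnd(r$flag, 4L) != 0L)
  bp_reads <- data.frame(row = integer(0), sv_id = character(0),
                         stringsAsFactors = FALSE)
  if (!is.null(svs) && nrow(svs)) {
    cs <- cigar_stats(r$cigar)
    end <- r$pos + cs$ref_width - 1L
    hits <- list()
    for (i in seq_len(nrow(svs))) {
      bps <- data.frame(chrom = c(svs$chrom1[i], svs$chrom2[i]),
                        pos = c(svs$bp1[i], svs$bp2[i]))
      rows <- integer(0)
      for (k in 1:2) {
        lo <- bps$pos[k] - neighborhood
        hi <- bps$pos[k] + neighborhood
        rows <- c(rows, which(!is.na(r$chrom) & r$chrom == bps$chrom[k] &
                                r$pos <= hi & end >= lo))
      }
      rows <- sort(unique(rows))
      if (length(rows)) {
        hits[[length(hits) + 1L]] <- data.frame(row = rows,
                                                sv_id = svs$sv_id[i],
                                                stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) bp_reads <- do.call(rbind, hits)
  }
  list(bp_reads = bp_reads, unmapped_rows = unmapped_rows)
}

# exact-match seed index over all reference sequences
build_seed_index <- function(reference, seed_length) {
  kmers <- character(0)
  chroms <- character(0)
  starts <- integer(0)
  for (chr in names(reference)) {
    s <- reference[[chr]]
    L <- nchar(s)
    if (L < seed_length) next
    st <- seq_len(L - seed_length + 1L)
    kmers <- c(kmers, substring(s, st, st + seed_length - 1L))
    chroms <- c(chroms, rep(chr, length(st)))
    starts <- c(starts, st)
  }
  list(kmers = kmers, chroms = chroms, starts = starts)
}

# realign one set of read sequences against per-read windows; returns the
# batch result plus derived record fields
window_positions <- function(res, win_lo, read_len) {
  lclip <- res$read_start - 1L
  rclip <- read_len - res$read_end
  data.frame(pos = win_lo + res$ref_start - 1L,
             cigar = paste0(ifelse(lclip > 0, paste0(lclip, "S"), ""),
                            res$cigar,
                            ifelse(rclip > 0, paste0(rclip, "S"), "")),
             score = res$score, stringsAsFactors = FALSE)
}

#' Realign extracted reads
#'
#' Breakpoint-neighbourhood reads are realigned individually (pairing
#' removed) against both breakpoint windows of their SV, keeping the
#' highest-scoring placement; unmapped reads are realigned against the
#' whole reference by exact-seed lookup (`seed_length`-mers from both read
#' ends, both orientations) followed by local alignment in the seeded
#' window. Reads that reach `min_score` nowhere remain (or become)
#' unmapped.
#'
#' @param aln a `read_alignment`.
#' @param extraction output of [extract_candidates()].
#' @param reference named character vector.
#' @param svs SV data.frame the extraction was made against.
#' @param config a [run_config()].
#' @return a new coordinate-sorted `read_alignment` in which only the
#'   extracted records have been replaced.
#' @export
realign_candidates <- function(aln, extraction, reference, svs,
                               config = run_config()) {
  r <- aln$reads
  sc <- scoring_of(config)
  neighborhood <- config$neighborhood
  touched <- integer(0)

  # --- breakpoint reads: window realignment -------------------------------
  # a read extracted for several SVs keeps its best placement across all of
  # their breakpoint windows
  bp <- extraction$bp_reads
  bp <- bp[!(bp$row %in% extraction$unmapped_rows), , drop = FALSE]
  if (nrow(bp)) {
    all_rows <- sort(unique(bp$row))
    best <- data.frame(row = all_rows, score = -Inf, chrom = NA_character_,
                       pos = NA_integer_, cigar = NA_character_,
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(svs))) {
      rows <- sort(unique(bp$row[bp$sv_id == svs$sv_id[i]]))
      if (!length(rows)) next
      seqs <- r$seq[rows]
      lens <- nchar(seqs)
      at <- match(rows, best$row)
      pad <- max(lens) + 10L  # reads overlapping the window edge align fully
      for (k in 1:2) {
        chrom <- if (k == 1) svs$chrom1[i] else svs$chrom2[i]
        bpos <- if (k == 1) svs$bp1[i] else svs$bp2[i]
        refseq <- reference[[chrom]]
        lo <- max(1L, bpos - neighborhood - pad)
        hi <- min(nchar(refseq), bpos + neighborhood + pad)
        res <- local_align_batch(seqs, rep(substring(refseq, lo, hi),
                                           length(seqs)), sc)
        cand <- window_positions(res, lo, lens)
        better <- which(!is.na(cand$score) & cand$score > best$score[at] + 1e-9)
        bat <- at[better]
        best$score[bat] <- cand$score[better]
        best$chrom[bat] <- chrom
        best$pos[bat] <- cand$pos[better]
        best$cigar[bat] <- cand$cigar[better]
      }
    }
    # reads that reach min_score nowhere keep their original placement
    ok <- is.finite(best$score) & best$score >= sc$min_score
    mrows <- best$row[ok]
    r$chrom[mrows] <- best$chrom[ok]
    r$pos[mrows] <- best$pos[ok]
    r$cigar[mrows] <- best$cigar[ok]
    r$mapq[mrows] <- 60L
    r$flag[mrows] <- bitwAnd(r$flag[mrows], bitwNot(4L))
    touched <- c(touched, mrows)
  }

  # --- unmapped reads: seed-and-extend over the whole reference -----------
  un <- extraction$unmapped_rows
  if (length(un)) {
    idx <- build_seed_index(reference, config$seed_length)
    sl <- config$seed_length
    for (row in un) {
      seq <- r$seq[row]
      len <- nchar(seq)
      if (len < sl) next
      best <- NULL
      for (orient in c("+", "-")) {
        s <- if (orient == "+") seq else revcomp(seq)
        for (seed in unique(c(substr(s, 1L, sl), substr(s, len - sl + 1L, len)))) {
          hit <- match(seed, idx$kmers)
          if (is.na(hit)) next
          chrom <- idx$chroms[hit]
          refseq <- reference[[chrom]]
          lo <- max(1L, idx$starts[hit] - len)
          hi <- min(nchar(refseq), idx$starts[hit] + 2L * len)
          res <- .sw_align_cpp(s, substring(refseq, lo, hi), sc$match,
                               sc$mismatch, sc$gap_open, sc$gap_extend)
          if (is.na(res$ref_start)) next
          cand <- list(score = res$score, chrom = chrom,
                       pos = lo + res$ref_start - 1L,
                       cigar = paste0(
                         if (res$read_start > 1L) paste0(res$read_start - 1L, "S"),
                         res$cigar,
                         if (res$read_end < len) paste0(len - res$read_end, "S")),
                       orient = orient, seq = s)
          if (is.null(best) || cand$score > best$score + 1e-9) best <- cand
        }
      }
      if (!is.null(best) && best$score >= sc$min_score) {
        r$chrom[row] <- best$chrom
        r$pos[row] <- best$pos
        r$cigar[row] <- best$cigar
        r$mapq[row] <- 60L
        r$seq[row] <- best$seq
        fl <- bitwAnd(r$flag[row], bitwNot(bitwOr(4L, 16L)))
        if (best$orient == "-") fl <- bitwOr(fl, 16L)
        r$flag[row] <- fl
        touched <- c(touched, row)
      }
    }
  }

  r <- refresh_mate_info(r)
  sort_alignment(read_alignment(r, aln$seqinfo, validate = FALSE))
}

# recompute mate coordinates and mate-status flag bits after realignment;
# assumes at most one mate pair per qname (first/second distinguished by
# flag bits 0x40/0x80)
refresh_mate_info <- function(r) {
  mate_no <- ifelse(bitwAnd(r$flag, 64L) != 0L, 1L, 2L)
  key <- paste0(r$qname, ":", mate_no)
  midx <- match(paste0(r$qname, ":", 3L - mate_no), key)
  has <- !is.na(midx)
  m_unmapped <- bitwAnd(r$flag[midx[has]], 4L) != 0L
  m_rev <- bitwAnd(r$flag[midx[has]], 16L) != 0L
  fl <- bitwAnd(r$flag[has], bitwNot(bitwOr(8L, 32L)))
  fl <- bitwOr(fl, ifelse(m_unmapped, 8L, 0L))
  fl <- bitwOr(fl, ifelse(m_rev & !m_unmapped, 32L, 0L))
  r$flag[has] <- fl
  r$mchrom[has] <- ifelse(m_unmapped, NA_character_, r$chrom[midx[has]])
  r$mpos[has] <- ifelse(m_unmapped, NA_integer_, r$pos[midx[has]])
  r
}

sv_key <- function(svs) {
  if (is.null(svs) || !nrow(svs)) return(character(0))
  sort(paste(svs$sv_type, svs$chrom1, svs$bp1, svs$chrom2, svs$bp2, sep = ":"))
}

#' Run the iterative refinement loop
#'
#' Detect, extract, realign, re-detect until the SV set (type and both
#' breakpoints; support counts excluded) is identical between consecutive
#' iterations or `max_iterations` is reached. Extraction always starts from
#' the *original* alignment, so records are realigned at most once per
#' iteration and untouched records are byte-identical between input and
#' output. After convergence the derivative-SV filter is applied and
#' surviving calls are marked `confirmed`.
#'
#' @param aln initial `read_alignment` (coordinate-sorted).
#' @param reference named character vector.
#' @param config a [run_config()].
#' @param max_iterations hard cap on realignment passes; non-convergence
#'   returns the last state with `converged = FALSE` and a warning.
#' @return list with `svs` (final, statuses `confirmed`/`filtered`),
#'   `alignment` (final), `history` (per-iteration SV data.frames),
#'   `iterations`, `converged`.
#' @export
run_refinement <- function(aln, reference, config = run_config(),
                           max_iterations = config$max_iterations) {
  original <- aln
  svs <- detect_svs(aln, reference, config)
  history <- list()
  iter <- 0L
  converged <- FALSE
  while (iter < max_iterations) {
    ext <- extract_candidates(original, svs, config$neighborhood)
    if (!nrow(ext$bp_reads) && !length(ext$unmapped_rows)) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    aln <- realign_candidates(original, ext, reference, svs, config)
    svs_new <- detect_svs(aln, reference, config)
    history[[iter]] <- svs_new
    if (identical(sv_key(svs_new), sv_key(svs))) {
      svs <- svs_new
      converged <- TRUE
      break
    }
    svs <- svs_new
  }
  if (!converged) {
    warning("SV predictions did not stabilise within ", max_iterations,
            " iterations; returning the last state")
  }
  svs <- filter_derivative_svs(svs, main_window = config$main_window,
                               support_ratio = config$support_ratio,
                               clip_tolerance = config$clip_tolerance)
  svs$status[svs$status == "candidate"] <- "confirmed"
  list(svs = svs, alignment = aln, history = history,
       iterations = iter, converged = converged)
}
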