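# Base-pair-resolution split-read SV calling: cluster soft-clip boundaries,
# then pair clusters whose clipped sequences explain each other across the
# reference ("pairs of soft-clip clusters that match each other"), typing
# the event from the relative position and orientation of the match.

#' Cluster soft-clip boundaries
#'
#' Every clip boundary with clip length >= `min_clip_len` is assigned to
#' exactly one cluster per (chromosome, side); boundaries within
#' `merge_window` of each other merge, the modal boundary position becomes
#' the cluster position (ties to the smaller position), and clusters with
#' fewer than `min_cluster_support` members are dropped. The consensus
#' clipped sequence is the per-column majority over member clips anchored at
#' the boundary (ties to the lexicographically smallest base). Hard-clipped
#' records mark boundaries and count toward support but contribute no
#' sequence.
#'
#' @param aln a `read_alignment` (coordinate-sorted; unsorted input is an
#'   error).
#' @param min_clip_len minimum clip length (bp) for a boundary to be
#'   informative.
#' @param merge_window bp window within which boundaries merge.
#' @param min_cluster_support minimum member reads per cluster.
#' @return data.frame with columns `chrom`, `pos` (boundary: last aligned
#'   base for right clips, first aligned base for left clips), `side`
#'   (`right_clip`/`left_clip`), `support`, `consensus`.
#' @export
build_clusters <- function(aln, min_clip_len = 8L, merge_window = 2L,
                           min_cluster_support = 3L) {
  r <- aln$reads
  mapped <- bitwAnd(r$flag, 4L) == 0L
  r <- r[mapped, , drop = FALSE]
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      side = character(0), support = integer(0),
                      consensus = character(0), stringsAsFactors = FALSE)
  if (!nrow(r)) return(empty)
  # coordinate-sortedness: each chromosome appears as one block of
  # non-decreasing positions
  rle_c <- rle(r$chrom)
  if (anyDuplicated(rle_c$values) ||
      any(unlist(tapply(r$pos, factor(r$chrom, levels = rle_c$values),
                        is.unsorted, simplify = FALSE)))) {
    stop("alignment is not coordinate-sorted; sort it first (sort_alignment)")
  }
  cs <- cigar_stats(r$cigar)
  end <- r$pos + cs$ref_width - 1L

  boundary_tbl <- function(side) {
    if (side == "left_clip") {
      keep <- (cs$lsoft >= min_clip_len) | (cs$lhard >= min_clip_len)
      data.frame(chrom = r$chrom[keep], bnd = r$pos[keep],
                 clip = ifelse(cs$lsoft[keep] > 0,
                               substr(r$seq[keep], 1L, cs$lsoft[keep]), ""),
                 stringsAsFactors = FALSE)
    } else {
      keep <- (cs$rsoft >= min_clip_len) | (cs$rhard >= min_clip_len)
      nc <- nchar(r$seq[keep])
      data.frame(chrom = r$chrom[keep], bnd = end[keep],
                 clip = ifelse(cs$rsoft[keep] > 0,
                               substr(r$seq[keep], nc - cs$rsoft[keep] + 1L, nc), ""),
                 stringsAsFactors = FALSE)
    }
  }

  out <- list()
  for (side in c("right_clip", "left_clip")) {
    tb <- boundary_tbl(side)
    if (!nrow(tb)) next
    for (chr in unique(tb$chrom)) {
      x <- tb[tb$chrom == chr, , drop = FALSE]
      x <- x[order(x$bnd), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(diff(x$bnd) > merge_window)))
      for (g in split(seq_len(nrow(x)), grp)) {
        if (length(g) < min_cluster_support) next
        tab <- table(x$bnd[g])
        modal <- as.integer(names(tab)[which.max(tab)])  # ties: smallest pos
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, pos = modal, side = side, support = length(g),
          consensus = clip_consensus(x$clip[g], side),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos, res$side), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-column majority over member clips, anchored at the boundary: right
# clips align at their left end, left clips at their right end
clip_consensus <- function(clips, side) {
  clips <- clips[nzchar(clips)]
  if (!length(clips)) return("")
  n <- nchar(clips)
  width <- max(n)
  if (side == "left_clip") clips <- strrep(" ", width - n) |> paste0(clips)
  chars <- matrix("", nrow = length(clips), ncol = width)
  sp <- strsplit(clips, "")
  for (i in seq_along(sp)) chars[i, seq_along(sp[[i]])] <- sp[[i]]
  cons <- apply(chars, 2L, function(col) {
    col <- col[col != "" & col != " "]
    if (!length(col)) return("")
    tab <- sort(table(col), decreasing = TRUE)
    best <- tab[tab == tab[1]]
    sort(names(best))[1]
  })
  paste(cons, collapse = "")
}

# does a clipped consensus locally align to the reference at an expected
# junction position?  identity is exact matches over the clip length
clip_matches <- function(clip, refseq, at_start = NULL, at_end = NULL,
                         rc = FALSE, scoring, min_identity, tol, pad) {
  if (!nzchar(clip)) return(FALSE)
  if (rc) clip <- revcomp(clip)
  len <- nchar(clip)
  L <- nchar(refseq)
  if (!is.null(at_start)) {
    lo <- max(1L, at_start - pad)
    hi <- min(L, at_start + len + pad)
  } else {
    lo <- max(1L, at_end - len - pad)
    hi <- min(L, at_end + pad)
  }
  if (hi - lo + 1L < 4L) return(FALSE)
  res <- .sw_align_cpp(clip, substring(refseq, lo, hi), scoring$match,
                       scoring$mismatch, scoring$gap_open, scoring$gap_extend)
  if (is.na(res$ref_start)) return(FALSE)
  if (res$nmatch / len < min_identity) return(FALSE)
  if (!is.null(at_start)) {
    abs((lo + res$ref_start - 1L) - res$read_start + 1L - at_start) <= tol
  } else {
    abs((lo + res$ref_end - 1L) + (len - res$read_end) - at_end) <= tol
  }
}

#' Match partner clusters and type candidate SVs
#'
#' For each (right-clip, left-clip) cluster pair, the consensus clipped
#' sequences are locally aligned against the partner's neighbourhood, in
#' both orientations, and a candidate SV is emitted when both directions
#' reach `min_identity` at positions consistent with the pair (a reciprocal
#' match). With right cluster at `p` and left cluster at `q`:
#' forward-strand matches give a deletion when `q > p + 1` (breakpoints
#' `p`, `q - 1`) and a tandem duplication when `q <= p` (breakpoints
#' `q - 1`, `p`); reverse-complement matches with `q > p + 1` give an
#' inversion (breakpoints `p`, `q - 1`); reciprocal forward matches across
#' chromosomes are reported as translocations.
#'
#' @param clusters data.frame from [build_clusters()].
#' @param reference named character vector of reference sequences.
#' @param config a [run_config()] (uses the scoring block, `search_radius`,
#'   `min_identity`, `clip_tolerance`, `match_pad`).
#' @return data.frame of candidate SVs: `sv_id`, `sv_type`, `chrom1`,
#'   `bp1`, `chrom2`, `bp2`, `support_bp1`, `support_bp2`, `status`.
#' @export
match_partners <- function(clusters, reference, config = run_config()) {
  empty <- data.frame(sv_id = character(0), sv_type = character(0),
                      chrom1 = character(0), bp1 = integer(0),
                      chrom2 = character(0), bp2 = integer(0),
                      support_bp1 = integer(0), support_bp2 = integer(0),
                      status = character(0), stringsAsFactors = FALSE)
  if (is.null(clusters) || !nrow(clusters)) return(empty)
  sc <- scoring_of(config)
  tol <- config$clip_tolerance
  pad <- config$match_pad
  mid <- config$min_identity
  rights <- clusters[clusters$side == "right_clip", , drop = FALSE]
  lefts <- clusters[clusters$side == "left_clip", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rights))) for (j in seq_len(nrow(lefts))) {
    cr <- rights[i, ]
    cl <- lefts[j, ]
    p <- cr$pos
    q <- cl$pos
    if (cr$chrom == cl$chrom) {
      if (abs(q - p) > config$search_radius) next
      refseq <- reference[[cr$chrom]]
      if (q > p + 1L) {
        # deletion: right clip continues at q, left clip ends at p
        if (clip_matches(cr$consensus, refseq, at_start = q, scoring = sc,
                         min_identity = mid, tol = tol, pad = pad) &&
            clip_matches(cl$consensus, refseq, at_end = p, scoring = sc,
                         min_identity = mid, tol = tol, pad = pad)) {
          out[[length(out) + 1L]] <- data.frame(
            sv_type = "DEL", chrom1 = cr$chrom, bp1 = p,
            chrom2 = cl$chrom, bp2 = q - 1L,
            support_bp1 = cr$support, support_bp2 = cl$support,
            stringsAsFactors = FALSE)
          next
        }
        # inversion: clips match the reverse complement across the pair
        if (clip_matches(cr$consensus, refseq, at_end = q - 1L, rc = TRUE,
                         scoring = sc, min_identity = mid, tol = tol, pad = pad) &&
            clip_matches(cl$consensus, refseq, at_start = p + 1L, rc = TRUE,
                         scoring = sc, min_identity = mid, tol = tol, pad = pad)) {
          out[[length(out) + 1L]] <- data.frame(
            sv_type = "INV", chrom1 = cr$chrom, bp1 = p,
            chrom2 = cl$chrom, bp2 = q - 1L,
            support_bp1 = cr$support, support_bp2 = cl$support,
            stringsAsFactors = FALSE)
        }
      } else if (q <= p) {
        # tandem duplication: right clip at the segment end continues at
        # the segment start q
        if (clip_matches(cr$consensus, refseq, at_start = q, scoring = sc,
                         min_identity = mid, tol = tol, pad = pad) &&
            clip_matches(cl$consensus, refseq, at_end = p, scoring = sc,
                         min_identity = mid, tol = tol, pad = pad)) {
          out[[length(out) + 1L]] <- data.frame(
            sv_type = "DUP", chrom1 = cr$chrom, bp1 = q - 1L,
            chrom2 = cl$chrom, bp2 = p,
            support_bp1 = cl$support, support_bp2 = cr$support,
            stringsAsFactors = FALSE)
        }
      }
    } else {
      # translocation (reported only): reciprocal forward match across
      # chromosomes
      if (clip_matches(cr$consensus, reference[[cl$chrom]], at_start = q,
                       scoring = sc, min_identity = mid, tol = tol, pad = pad) &&
          clip_matches(cl$consensus, reference[[cr$chrom]], at_end = p,
                       scoring = sc, min_identity = mid, tol = tol, pad = pad)) {
        out[[length(out) + 1L]] <- data.frame(
          sv_type = "TRA", chrom1 = cr$chrom, bp1 = p,
          chrom2 = cl$chrom, bp2 = q - 1L,
          support_bp1 = cr$support, support_bp2 = cl$support,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$chrom1, res$bp1, res$chrom2, res$bp2), , drop = FALSE]
  res$sv_id <- sprintf("sv%d", seq_len(nrow(res)))
  res$status <- "candidate"
  rownames(res) <- NULL
  res[c("sv_id", "sv_type", "chrom1", "bp1", "chrom2", "bp2",
        "support_bp1", "support_bp2", "status")]
}

#' Filter derivative SV calls
#'
#' An SV is marked `filtered` when another SV of the same type shares one
#' breakpoint (within `clip_tolerance`), has its other breakpoint within
#' `main_window`, and the candidate's total support is below
#' `support_ratio` times the main SV's: such slight derivations of a strong
#' call are sequencing-error artifacts. Equal-support pairs are left alone.
#'
#' @param svs data.frame from [match_partners()].
#' @param main_window bp window for the non-shared breakpoint.
#' @param support_ratio fraction of the main SV's support below which the
#'   derivative is discarded.
#' @param clip_tolerance bp tolerance for the shared breakpoint.
#' @return `svs` with `status` updated (`filtered` for discarded calls).
#' @export
filter_derivative_svs <- function(svs, main_window = 20L,
                                  support_ratio = 0.1,
                                  clip_tolerance = 2L) {
  if (!nrow(svs)) return(svs)
  tot <- svs$support_bp1 + svs$support_bp2
  for (i in seq_len(nrow(svs))) {
    for (j in seq_len(nrow(svs))) {
      if (i == j || svs$sv_type[i] != svs$sv_type[j]) next
      if (svs$chrom1[i] != svs$chrom1[j] || svs$chrom2[i] != svs$chrom2[j]) next
      d1 <- abs(svs$bp1[i] - svs$bp1[j])
      d2 <- abs(svs$bp2[i] - svs$bp2[j])
      shares <- (d1 <= clip_tolerance && d2 <= main_window) ||
        (d2 <= clip_tolerance && d1 <= main_window)
      if (shares && tot[i] < support_ratio * tot[j]) {
        svs$status[i] <- "filtered"
      }
    }
  }
  svs
}

#' Write an SV report TSV
#'
#' Fixed column order: sv_id, type, chrom1, bp1, chrom2, bp2, support_bp1,
#' support_bp2, status, then any heterogeneity columns present.
#'
#' @param svs SV data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_report <- function(svs, path) {
  lead <- c("sv_id", "sv_type", "chrom1", "bp1", "chrom2", "bp2",
            "support_bp1", "support_bp2", "status")
  cols <- c(lead, setdiff(names(svs), lead))
  write.table(svs[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
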