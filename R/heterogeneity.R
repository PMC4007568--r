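# Heterogeneity estimation: the fraction of the sample carrying an SV,
# inferred from read counts at its breakpoints. A = total reads spanning
# either breakpoint, B = total reads soft-clipped at either breakpoint.
# B estimates the variant depth V; the reference depth R depends on the SV
# type (a deletion has two reference breakpoints collapsing onto one
# variant junction, so R averages the spanning reads, R = A/2; a tandem
# duplication's outer edges carry spanning reads from both populations, so
# R = A/2 - B; an inversion changes no copy number, so H compares B with A
# directly). H = V / (V + R) in all cases.

#' Breakpoints of an SV with their clipped sides
#'
#' The clipped side is the read side on which the variant allele soft-clips
#' at that breakpoint: deletions clip rightwards at bp1 and leftwards at
#' bp2; a tandem duplication's novel junction (middle of the repeat) clips
#' leftwards at bp1 (reads resuming at the segment start) and rightwards at
#' bp2; inversions clip rightwards at bp1 and leftwards at bp2.
#' Translocations are treated like deletions' side convention.
#'
#' @param sv one-row SV data.frame.
#' @return data.frame with `chrom`, `pos`, `side` (two rows).
#' @export
sv_breakpoints <- function(sv) {
  sides <- switch(sv$sv_type,
                  DEL = c("right_clip", "left_clip"),
                  DUP = c("left_clip", "right_clip"),
                  INV = c("right_clip", "left_clip"),
                  TRA = c("right_clip", "left_clip"),
                  stop("unknown SV type: ", sv$sv_type))
  data.frame(chrom = c(sv$chrom1, sv$chrom2), pos = c(sv$bp1, sv$bp2),
             side = sides, stringsAsFactors = FALSE)
}

#' Count spanning (A) and soft-clipped (B) reads at an SV's breakpoints
#'
#' A sums the `spanning` classifications over both breakpoints; B counts
#' reads classified `soft_clipped` at either breakpoint, once per read even
#' if a short-fragment read clips at both junction-adjacent positions.
#'
#' @param aln a `read_alignment` (post-refinement).
#' @param sv one-row SV data.frame.
#' @param anchor,clip_tolerance see [classify_read_at_breakpoint()].
#' @return list with `A`, `B`, and per-breakpoint spanning counts
#'   `A_per_bp`.
#' @export
count_breakpoint_reads <- function(aln, sv, anchor = 5L, clip_tolerance = 2L) {
  bps <- sv_breakpoints(sv)
  for (k in 1:2) {
    if (!(bps$chrom[k] %in% names(aln$seqinfo)) ||
        bps$pos[k] < 1L || bps$pos[k] > aln$seqinfo[[bps$chrom[k]]]) {
      stop("breakpoint ", bps$chrom[k], ":", bps$pos[k],
           " outside reference bounds")
    }
  }
  r <- aln$reads
  cs <- NULL
  A_per_bp <- integer(2)
  clipped_rows <- integer(0)
  for (k in 1:2) {
    # candidate window: anything whose aligned span could span or clip here
    lo <- bps$pos[k] - anchor - clip_tolerance - 1L
    hi <- bps$pos[k] + anchor + clip_tolerance + 1L
    mapped <- bitwAnd(r$flag, 4L) == 0L & !is.na(r$chrom) & r$chrom == bps$chrom[k]
    sub <- which(mapped & r$pos <= hi)
    if (length(sub)) {
      if (is.null(cs)) cs <- cigar_stats(r$cigar)
      ends <- r$pos[sub] + cs$ref_width[sub] - 1L
      sub <- sub[ends >= lo]
    }
    if (!length(sub)) next
    cls <- classify_read_at_breakpoint(r[sub, , drop = FALSE],
                                       as.list(bps[k, ]),
                                       anchor = anchor,
                                       clip_tolerance = clip_tolerance)
    A_per_bp[k] <- sum(cls == "spanning")
    clipped_rows <- c(clipped_rows, sub[cls == "soft_clipped"])
  }
  list(A = sum(A_per_bp), B = length(unique(clipped_rows)),
       A_per_bp = A_per_bp)
}

#' Estimate SV heterogeneity from breakpoint read counts
#'
#' Type-specific estimators (all clamped into `[0, 1]`):
#' deletion `H = B / (B + A/2)`; tandem duplication `H = B / (A/2)` (i.e.
#' `V = B`, `R = A/2 - B`; when sampling noise drives `B > A/2` the result
#' is clamped to `H = 1`, `R = 0` and flagged); inversion
#' `H = B / (A + B)`. Translocations use the inversion formula, flagged as
#' an assumption since no copy-number correction is derivable for them.
#'
#' @param sv_type one of DEL, DUP, INV, TRA.
#' @param A spanning read count (both breakpoints summed).
#' @param B soft-clipped read count (both breakpoints, once per read).
#' @return list with `sv_type`, `A`, `B`, `V` (variant depth), `R`
#'   (reference depth), `H` (fraction), `het_percent` (two decimals),
#'   `formula`, `clamped`.
#' @export
estimate_het <- function(sv_type, A, B) {
  stopifnot(length(A) == 1, length(B) == 1, A >= 0, B >= 0)
  sv_type <- match.arg(toupper(sv_type), c("DEL", "DUP", "INV", "TRA"))
  clamped <- FALSE
  if (A == 0 && B == 0) {
    warning("no spanning or soft-clipped reads at either breakpoint; ",
            "heterogeneity undefined")
    V <- R <- H <- NA_real_
  } else if (sv_type == "DEL") {
    V <- B
    R <- A / 2
    H <- V / (V + R)
  } else if (sv_type == "DUP") {
    V <- B
    R <- A / 2 - B
    if (R < 0) {
      clamped <- TRUE
      R <- 0
    }
    H <- if (V + R > 0) V / (V + R) else 1
    if (H > 1) H <- 1
  } else {
    V <- B
    R <- A
    H <- B / (A + B)
  }
  formula <- switch(sv_type, DEL = "deletion", DUP = "duplication",
                    INV = "inversion", TRA = "inversion")
  list(sv_type = sv_type, A = A, B = B, V = V, R = R, H = H,
       het_percent = round(100 * H, 2), formula = formula,
       clamped = clamped)
}

#' Estimate heterogeneity for every SV in a report
#'
#' Extends the SV report with columns `A`, `B`, `V`, `R`, `H`,
#' `het_percent`, `formula` (same row order, so reports stay joinable).
#' SVs with no reads at either breakpoint get NA estimates.
#'
#' @param aln final `read_alignment`.
#' @param svs SV data.frame.
#' @param config a [run_config()] (uses `anchor`, `clip_tolerance`).
#' @return `svs` with estimation columns appended.
#' @export
estimate_sv_heterogeneity <- function(aln, svs, config = run_config()) {
  n <- nrow(svs)
  svs$A <- svs$B <- NA_integer_
  svs$V <- svs$R <- svs$H <- svs$het_percent <- NA_real_
  svs$formula <- NA_character_
  for (i in seq_len(n)) {
    cnt <- count_breakpoint_reads(aln, svs[i, , drop = FALSE],
                                  anchor = config$anchor,
                                  clip_tolerance = config$clip_tolerance)
    est <- if (cnt$A == 0 && cnt$B == 0) {
      warning("SV ", svs$sv_id[i], ": no reads at either breakpoint; ",
              "heterogeneity undefined")
      list(V = NA_real_, R = NA_real_, H = NA_real_,
           het_percent = NA_real_,
           formula = switch(svs$sv_type[i], DEL = "deletion",
                            DUP = "duplication", "inversion"))
    } else {
      estimate_het(svs$sv_type[i], cnt$A, cnt$B)
    }
    svs$A[i] <- cnt$A
    svs$B[i] <- cnt$B
    svs$V[i] <- est$V
    svs$R[i] <- est$R
    svs$H[i] <- est$H
    svs$het_percent[i] <- est$het_percent
    svs$formula[i] <- est$formula
  }
  svs
}
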