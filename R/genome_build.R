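# Personal genome construction: apply a selected, mutually non-overlapping
# set of intra-chromosomal SVs to the reference. With breakpoints as "last
# base before the junction", a deletion removes reference positions
# bp1+1 .. bp2, a tandem duplication inserts a second copy of bp1+1 .. bp2
# immediately after bp2, and an inversion reverse-complements bp1+1 .. bp2
# in place. Edits are applied right to left so earlier coordinates stay
# valid.

normalize_sv_table <- function(svs) {
  if (!"chrom1" %in% names(svs) && "chrom" %in% names(svs)) {
    svs$chrom1 <- svs$chrom2 <- svs$chrom
  }
  if (!"sv_id" %in% names(svs)) svs$sv_id <- sprintf("sv%d", seq_len(nrow(svs)))
  if (!"status" %in% names(svs)) svs$status <- "confirmed"
  svs
}

#' Select SVs for application to the reference
#'
#' Threshold mode keeps confirmed SVs whose heterogeneity fraction `H` is at
#' least `h_min` (the most common set of predicted variants); explicit mode
#' keeps exactly the listed ids (the set chosen by the user). Selected SVs
#' must be intra-chromosomal and mutually non-overlapping; violations are
#' rejected with the offending pair named.
#'
#' @param svs SV data.frame (heterogeneity columns required for threshold
#'   mode).
#' @param mode `"threshold"` or `"explicit"`.
#' @param h_min heterogeneity threshold in `[0, 1]` for threshold mode.
#' @param ids character vector of `sv_id`s for explicit mode.
#' @return an `edit_plan`: the selected SVs sorted by `bp1` descending.
#' @export
select_svs <- function(svs, mode = c("threshold", "explicit"), h_min = 0.5,
                       ids = NULL) {
  mode <- match.arg(mode)
  svs <- normalize_sv_table(svs)
  if (mode == "threshold") {
    if (!"H" %in% names(svs)) {
      stop("threshold mode needs heterogeneity estimates (column H)")
    }
    sel <- svs[svs$status %in% c("confirmed", "candidate") &
                 !is.na(svs$H) & svs$H >= h_min, , drop = FALSE]
  } else {
    if (is.null(ids)) stop("explicit mode needs ids")
    unknown <- setdiff(ids, svs$sv_id)
    if (length(unknown)) stop("unknown sv_id(s): ", paste(unknown, collapse = ", "))
    sel <- svs[match(ids, svs$sv_id), , drop = FALSE]
  }
  if (nrow(sel)) {
    if (any(sel$sv_type == "TRA" | sel$chrom1 != sel$chrom2)) {
      stop("inter-chromosomal SVs cannot be applied to the reference")
    }
    if (any(sel$bp1 >= sel$bp2)) stop("SV with bp1 >= bp2 cannot be applied")
    o <- order(sel$chrom1, sel$bp1)
    s <- sel[o, , drop = FALSE]
    if (nrow(s) > 1) {
      for (i in seq_len(nrow(s) - 1L)) {
        if (s$chrom1[i + 1L] == s$chrom1[i] && s$bp1[i + 1L] + 1L <= s$bp2[i]) {
          stop("selected SVs overlap: ", s$sv_id[i], " (", s$bp1[i] + 1L, "..",
               s$bp2[i], ") and ", s$sv_id[i + 1L], " (", s$bp1[i + 1L] + 1L,
               "..", s$bp2[i + 1L], ")")
        }
      }
    }
    sel <- sel[order(sel$chrom1, -sel$bp1), , drop = FALSE]
    rownames(sel) <- NULL
  }
  structure(list(svs = sel, mode = mode,
                 h_min = if (mode == "threshold") h_min else NA_real_),
            class = "edit_plan")
}

#' @export
print.edit_plan <- function(x, ...) {
  cat("edit_plan:", nrow(x$svs), "SV(s), mode", x$mode, "\n")
  invisible(x)
}

#' Apply an edit plan to the reference
#'
#' Emits the personal sequence and a reference-to-personal coordinate map.
#' Deleted positions map to NA; positions inside a duplicated segment map
#' to the first copy; inverted segments are mapped block-wise (each
#' reference position keeps its offset within the segment), which keeps the
#' map monotone over non-deleted positions.
#'
#' @param reference named character vector of reference sequences.
#' @param plan an `edit_plan` from [select_svs()].
#' @return list with `sequence` (named character vector), `coord_map`
#'   (named list of integer vectors, `NA` = deleted), `applied` (the SVs
#'   applied).
#' @export
apply_edits <- function(reference, plan) {
  stopifnot(inherits(plan, "edit_plan"))
  svs <- plan$svs
  out <- reference
  coord_map <- lapply(reference, function(s) seq_len(nchar(s)))
  names(coord_map) <- names(reference)
  if (nrow(svs)) {
    if (!all(svs$chrom1 %in% names(reference))) {
      stop("SV on a chromosome absent from the reference")
    }
    for (chr in unique(svs$chrom1)) {
      s <- unname(out[[chr]])
      L <- nchar(s)
      sub <- svs[svs$chrom1 == chr, , drop = FALSE]  # bp1 descending
      if (any(sub$bp2 > L) || any(sub$bp1 < 0L)) {
        stop("edit beyond sequence bounds on ", chr)
      }
      for (i in seq_len(nrow(sub))) {
        a <- sub$bp1[i] + 1L
        b <- sub$bp2[i]
        seg <- substring(s, a, b)
        pre <- substring(s, 1L, a - 1L)
        post <- if (b < nchar(s)) substring(s, b + 1L, nchar(s)) else ""
        s <- switch(sub$sv_type[i],
                    DEL = paste0(pre, post),
                    DUP = paste0(pre, seg, seg, post),
                    INV = paste0(pre, revcomp(seg), post),
                    stop("cannot apply SV type ", sub$sv_type[i]))
      }
      out[[chr]] <- s
      # coordinate map, walking edits in ascending order
      map <- seq_len(L)
      shift <- rep(0L, L)
      deleted <- rep(FALSE, L)
      asc <- sub[order(sub$bp1), , drop = FALSE]
      for (i in seq_len(nrow(asc))) {
        a <- asc$bp1[i] + 1L
        b <- asc$bp2[i]
        len <- b - a + 1L
        if (asc$sv_type[i] == "DEL") {
          deleted[a:b] <- TRUE
          if (b < L) shift[(b + 1L):L] <- shift[(b + 1L):L] - len
        } else if (asc$sv_type[i] == "DUP") {
          if (b < L) shift[(b + 1L):L] <- shift[(b + 1L):L] + len
        }
        # INV: block-wise identity
      }
      map <- map + shift
      map[deleted] <- NA_integer_
      coord_map[[chr]] <- map
    }
  }
  list(sequence = out, coord_map = coord_map, applied = svs)
}

#' Build and write a personal genomic sequence
#'
#' Convenience wrapper: select, apply, and write FASTA (70-column wrap;
#' headers record the applied SV ids and package version) plus a
#' reference-to-personal coordinate map TSV (`ref_pos`, `personal_pos`,
#' `-` for deleted positions).
#'
#' @param reference named character vector.
#' @param svs SV data.frame.
#' @param out_fasta output FASTA path.
#' @param out_map optional coordinate map TSV path.
#' @param ... passed to [select_svs()].
#' @return the [apply_edits()] result, invisibly.
#' @export
build_personal_genome <- function(reference, svs, out_fasta, out_map = NULL,
                                  ...) {
  plan <- select_svs(svs, ...)
  res <- apply_edits(reference, plan)
  ver <- as.character(utils::packageVersion("clipsv"))
  ids <- if (nrow(res$applied)) paste(res$applied$sv_id, collapse = ",") else "none"
  seqs <- res$sequence
  names(seqs) <- paste0(names(seqs), " clipsv:", ver, " svs=", ids)
  write_reference(seqs, out_fasta)
  if (!is.null(out_map)) {
    tabs <- lapply(names(res$coord_map), function(chr) {
      m <- res$coord_map[[chr]]
      data.frame(chrom = chr, ref_pos = seq_along(m),
                 personal_pos = ifelse(is.na(m), "-", as.character(m)),
                 stringsAsFactors = FALSE)
    })
    write.table(do.call(rbind, tabs), out_map, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(res)
}
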