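# Heterogeneous paired-end read simulator.
#
# Emulates the evaluation protocol the pipeline is designed for: a ~70 kb
# non-repetitive reference, a variant haplotype carrying non-overlapping
# deletions / tandem duplications / inversions, error-free 75 bp paired-end
# reads with truncated-normal fragment sizes (mean 250, sd 20, bounds
# [175, 325]), and a configured fraction of fragments drawn from the variant
# haplotype. Truth alignments come in two dialects: "oracle" (each read at
# its true position with correct soft-clipping at SV junctions) and "naive"
# (junction reads forced end-to-end with mismatches when the overhang is
# small, unmapped otherwise - the two failure modes targeted realignment is
# meant to repair).

SV_TYPES <- c("DEL", "DUP", "INV")

#' Simulation configuration
#'
#' @param reference_length reference length in bp.
#' @param sv_spec data.frame with columns `type` (DEL/DUP/INV), `length`
#'   (bp), `anchor` (1-based first affected reference base). The affected
#'   segment is `anchor .. anchor + length - 1`; breakpoints are
#'   `bp1 = anchor - 1`, `bp2 = anchor + length - 1`.
#' @param variant_fraction proportion in `[0, 1]` of fragments drawn from
#'   the variant haplotype.
#' @param coverage mean fold-coverage over the reference; the fragment count
#'   is `floor(coverage * reference_length / (2 * read_length))`.
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max truncated
#'   normal fragment-size model (inclusive bounds, sampled by rejection).
#' @param seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(reference_length, sv_spec = NULL,
                              variant_fraction = 0, coverage = 20,
                              read_length = 75L, fragment_mean = 250,
                              fragment_sd = 20, fragment_min = 175,
                              fragment_max = 325, seed = 1L) {
  stopifnot(reference_length >= 1, coverage > 0, read_length >= 20)
  if (!(fragment_min <= fragment_mean && fragment_mean <= fragment_max)) {
    stop("fragment bounds must satisfy fragment_min <= fragment_mean <= fragment_max")
  }
  if (is.na(variant_fraction) || variant_fraction < 0 || variant_fraction > 1) {
    stop("variant_fraction must be in [0, 1]")
  }
  if (reference_length < fragment_max) {
    stop("reference shorter than fragment_max (", fragment_max, " bp)")
  }
  if (!is.null(sv_spec)) sv_spec <- validate_sv_spec(sv_spec, reference_length)
  structure(list(reference_length = as.integer(reference_length),
                 sv_spec = sv_spec,
                 variant_fraction = variant_fraction,
                 coverage = coverage, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 fragment_min = fragment_min, fragment_max = fragment_max,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

validate_sv_spec <- function(sv_spec, reference_length) {
  stopifnot(is.data.frame(sv_spec),
            all(c("type", "length", "anchor") %in% names(sv_spec)))
  sv_spec$type <- toupper(as.character(sv_spec$type))
  sv_spec$length <- as.integer(sv_spec$length)
  sv_spec$anchor <- as.integer(sv_spec$anchor)
  for (i in seq_len(nrow(sv_spec))) {
    s <- sv_spec$anchor[i]
    e <- s + sv_spec$length[i] - 1L
    lab <- sprintf("SV %d (%s %d..%d)", i, sv_spec$type[i], s, e)
    if (!sv_spec$type[i] %in% SV_TYPES) stop(lab, ": unsupported type")
    if (sv_spec$length[i] < 1L) stop(lab, ": non-positive length")
    if (s < 2L || e > reference_length - 1L) {
      stop(lab, ": outside the reference interior (need anchor >= 2 and end <= length - 1)")
    }
  }
  o <- order(sv_spec$anchor)
  sv_spec <- sv_spec[o, , drop = FALSE]
  rownames(sv_spec) <- NULL
  if (nrow(sv_spec) > 1) {
    s <- sv_spec$anchor
    e <- s + sv_spec$length - 1L
    bad <- which(s[-1] <= e[-length(e)])
    if (length(bad)) {
      stop(sprintf("SV %d (%s %d..%d) overlaps SV %d (%s %d..%d)",
                   bad[1] + 1L, sv_spec$type[bad[1] + 1L], s[bad[1] + 1L], e[bad[1] + 1L],
                   bad[1], sv_spec$type[bad[1]], s[bad[1]], e[bad[1]]))
    }
  }
  sv_spec
}

#' Build the variant haplotype from a reference and an SV specification
#'
#' Deletions are excised, tandem duplications doubled in place, inversions
#' reverse-complemented. Also returns the block structure mapping variant
#' coordinates back to the reference and, per SV, the variant-coordinate
#' junction position(s) (last variant base before each novel adjacency),
#' which downstream truth computations need.
#'
#' @param reference named character vector of length 1.
#' @param sv_spec see [simulation_config()].
#' @return list with `sequence` (named character), `svs` (data.frame:
#'   `sv_id`, `sv_type`, `chrom`, `bp1`, `bp2`, `length`, `vjunc1`,
#'   `vjunc2`), and `blocks` (data.frame: `ref_start`, `ref_end`, `strand`,
#'   `var_start`, `var_end`).
#' @export
build_variant_genome <- function(reference, sv_spec) {
  stopifnot(is.character(reference), length(reference) == 1,
            !is.null(names(reference)))
  chrom <- names(reference)
  L <- nchar(reference)
  sv_spec <- validate_sv_spec(sv_spec, L)
  n <- nrow(sv_spec)

  blocks <- list()  # (ref_start, ref_end, strand)
  svs <- data.frame(sv_id = sprintf("sv%d", seq_len(n)),
                    sv_type = sv_spec$type, chrom = chrom,
                    bp1 = sv_spec$anchor - 1L,
                    bp2 = sv_spec$anchor + sv_spec$length - 1L,
                    length = sv_spec$length,
                    vjunc1 = NA_integer_, vjunc2 = NA_integer_,
                    stringsAsFactors = FALSE)
  varlen <- 0L
  cursor <- 1L
  add <- function(s, e, strand) {
    blocks[[length(blocks) + 1L]] <<- c(s, e, strand)
    varlen <<- varlen + (e - s + 1L)
  }
  for (i in seq_len(n)) {
    s <- sv_spec$anchor[i]
    e <- s + sv_spec$length[i] - 1L
    if (cursor <= s - 1L) add(cursor, s - 1L, 1L)
    if (sv_spec$type[i] == "DEL") {
      svs$vjunc1[i] <- varlen
    } else if (sv_spec$type[i] == "DUP") {
      add(s, e, 1L)
      svs$vjunc1[i] <- varlen
      add(s, e, 1L)
    } else {  # INV
      svs$vjunc1[i] <- varlen
      add(s, e, -1L)
      svs$vjunc2[i] <- varlen
    }
    cursor <- e + 1L
  }
  if (cursor <= L) add(cursor, L, 1L)

  bl <- do.call(rbind, blocks)
  bl <- data.frame(ref_start = bl[, 1], ref_end = bl[, 2],
                   strand = ifelse(bl[, 3] > 0, "+", "-"))
  # merge reference-contiguous plus-strand neighbours: SV junctions are
  # never reference-contiguous on the plus strand, so these are just
  # construction seams (e.g. a flank meeting the first copy of a tandem
  # duplication)
  keep <- rep(TRUE, nrow(bl))
  for (i in seq_len(nrow(bl))[-1]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    if (bl$strand[i] == "+" && bl$strand[j] == "+" &&
        bl$ref_start[i] == bl$ref_end[j] + 1L) {
      bl$ref_end[j] <- bl$ref_end[i]
      keep[i] <- FALSE
    }
  }
  bl <- bl[keep, , drop = FALSE]
  w <- bl$ref_end - bl$ref_start + 1L
  bl$var_end <- cumsum(w)
  bl$var_start <- bl$var_end - w + 1L
  rownames(bl) <- NULL

  pieces <- ifelse(bl$strand == "+",
                   substring(reference, bl$ref_start, bl$ref_end),
                   revcomp(substring(reference, bl$ref_start, bl$ref_end)))
  seq <- paste(pieces, collapse = "")
  list(sequence = setNames(seq, chrom), svs = svs, blocks = bl)
}

#' Sample heterogeneous paired-end fragments
#'
#' Fragment haplotypes are Bernoulli(`variant_fraction`), lengths are drawn
#' from the truncated normal by rejection, positions are uniform over the
#' source haplotype, and bases are copied without error (the truth
#' alignments report phred-40 qualities throughout). Deterministic under the
#' configured seed.
#'
#' @param config a [simulation_config()].
#' @param reference named character vector of length 1.
#' @param variant variant haplotype sequence (character scalar), e.g. from
#'   [build_variant_genome()]; may be NULL when `variant_fraction` is 0.
#' @return list with `fragments` (data.frame: `fragment_id`, `haplotype`,
#'   `origin_start`, `frag_len`) and `reads` (data.frame: `qname`,
#'   `fragment_id`, `mate`, `haplotype`, `a`, `b`, `dir` with `a`/`b` the
#'   1-based source-haplotype interval and `dir` the source strand).
#' @export
sample_reads <- function(config, reference, variant = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  L <- nchar(reference)
  if (L != config$reference_length) {
    stop("reference length does not match the configuration")
  }
  Lv <- if (is.null(variant)) NA_integer_ else nchar(variant)
  if (config$variant_fraction > 0 && is.na(Lv)) {
    stop("variant sequence required when variant_fraction > 0")
  }
  rl <- config$read_length
  set.seed(config$seed)
  n <- as.integer(floor(config$coverage * L / (2 * rl)))
  hap <- ifelse(rbinom(n, 1L, config$variant_fraction) == 1L,
                "variant", "reference")

  rtnorm <- function(k, lo, hi) {
    out <- integer(0)
    while (length(out) < k) {
      x <- as.integer(round(rnorm(k - length(out), config$fragment_mean,
                                  config$fragment_sd)))
      out <- c(out, x[x >= lo & x <= hi])
    }
    out
  }
  flen <- rtnorm(n, config$fragment_min, config$fragment_max)
  src_len <- ifelse(hap == "variant", Lv, L)
  # fragments longer than their source haplotype are resampled within bounds
  over <- which(flen > src_len)
  if (length(over)) {
    if (any(src_len[over] < config$fragment_min)) {
      stop("variant haplotype shorter than fragment_min; cannot sample fragments")
    }
    for (i in over) flen[i] <- rtnorm(1L, config$fragment_min, src_len[i])
  }
  start <- 1L + as.integer(floor(runif(n) * (src_len - flen + 1)))

  fragments <- data.frame(fragment_id = sprintf("frag%07d", seq_len(n)),
                          haplotype = hap, origin_start = start,
                          frag_len = flen, stringsAsFactors = FALSE)
  reads <- data.frame(
    qname = rep(paste0(fragments$fragment_id, ":",
                       substr(hap, 1L, 1L)), 2L),
    fragment_id = rep(fragments$fragment_id, 2L),
    mate = rep(c(1L, 2L), each = n),
    haplotype = rep(hap, 2L),
    a = c(start, start + flen - rl),
    b = c(start + rl - 1L, start + flen - 1L),
    dir = rep(c("+", "-"), each = n),
    stringsAsFactors = FALSE)
  list(fragments = fragments, reads = reads)
}

# piecewise map of one variant-haplotype read interval onto the reference,
# split at block boundaries; returns a data.frame of pieces in haplotype
# order with the reference interval and strand of each
read_pieces <- function(a, b, blocks) {
  ia <- findInterval(a, blocks$var_start)
  ib <- findInterval(b, blocks$var_start)
  ks <- ia:ib
  vs <- pmax(a, blocks$var_start[ks])
  ve <- pmin(b, blocks$var_end[ks])
  len <- ve - vs + 1L
  plus <- blocks$strand[ks] == "+"
  rs <- ifelse(plus,
               blocks$ref_start[ks] + (vs - blocks$var_start[ks]),
               blocks$ref_end[ks] - (ve - blocks$var_start[ks]))
  data.frame(k = ks, vs = vs, ve = ve, len = len,
             rs = as.integer(rs), re = as.integer(rs + len - 1L),
             strand = blocks$strand[ks], stringsAsFactors = FALSE)
}

#' Emit truth alignments for simulated reads
#'
#' Two dialects. `"oracle"`: every read is placed at its true reference
#' position; reads crossing an SV junction are soft-clipped exactly at the
#' junction, anchored on their longer plus-strand portion (or, if the
#' outside portion is shorter than `min_plus_anchor`, on the longer portion
#' whatever its strand). `"naive"`: reads crossing a junction by at most
#' `margin` bases are forced into an end-to-end placement with mismatches
#' (no clipping), and reads crossing by more than `margin` are left
#' unmapped - reproducing the two ways a global aligner hides SV signal.
#' Reads fully inside one block are identical in both dialects.
#'
#' @param sim output of [sample_reads()].
#' @param reference named character vector of length 1.
#' @param variant_info output of [build_variant_genome()] (or NULL when all
#'   fragments are reference-haplotype).
#' @param mode `"oracle"` or `"naive"`.
#' @param margin naive-mode overhang (bp) up to which a junction read is
#'   forced end-to-end rather than unmapped.
#' @param min_plus_anchor oracle-mode minimum length (bp) for anchoring a
#'   junction read on its outside-of-inversion portion.
#' @return a `read_alignment`.
#' @export
emit_truth_alignment <- function(sim, reference, variant_info = NULL,
                                 mode = c("oracle", "naive"), margin = 5L,
                                 min_plus_anchor = 20L) {
  mode <- match.arg(mode)
  chrom <- names(reference)
  L <- nchar(reference)
  rd <- sim$reads
  n <- nrow(rd)
  refseq <- unname(reference)
  varseq <- if (!is.null(variant_info)) unname(variant_info$sequence) else NULL
  blocks <- if (!is.null(variant_info)) variant_info$blocks else NULL

  pos <- rep(NA_integer_, n)
  cig <- rep(NA_character_, n)
  seqs <- rep(NA_character_, n)
  rev <- rep(FALSE, n)     # alignment on reference minus strand
  unmapped <- rep(FALSE, n)

  is_ref <- rd$haplotype == "reference"
  if (any(is_ref)) {
    i <- which(is_ref)
    pos[i] <- rd$a[i]
    cig[i] <- paste0(rd$b[i] - rd$a[i] + 1L, "M")
    seqs[i] <- substring(refseq, rd$a[i], rd$b[i])
    rev[i] <- rd$dir[i] == "-"
  }
  if (any(!is_ref)) {
    if (is.null(blocks)) stop("variant_info required for variant-haplotype reads")
    i <- which(!is_ref)
    ia <- findInterval(rd$a[i], blocks$var_start)
    ib <- findInterval(rd$b[i], blocks$var_start)
    same <- ia == ib
    # fully within one block: direct placement
    j <- i[same]
    if (length(j)) {
      k <- ia[same]
      plus <- blocks$strand[k] == "+"
      off_a <- rd$a[j] - blocks$var_start[k]
      off_b <- rd$b[j] - blocks$var_start[k]
      pos[j] <- ifelse(plus, blocks$ref_start[k] + off_a,
                       blocks$ref_end[k] - off_b)
      cig[j] <- paste0(rd$b[j] - rd$a[j] + 1L, "M")
      hapseq <- substring(varseq, rd$a[j], rd$b[j])
      if (any(!plus)) hapseq[!plus] <- revcomp(hapseq[!plus])
      seqs[j] <- hapseq
      rev[j] <- ifelse(plus, rd$dir[j] == "-", rd$dir[j] == "+")
    }
    # junction-crossing reads: per-read handling
    for (j in i[!same]) {
      p <- read_pieces(rd$a[j], rd$b[j], blocks)
      hapseq <- substring(varseq, rd$a[j], rd$b[j])
      rl <- rd$b[j] - rd$a[j] + 1L
      if (mode == "oracle") {
        cand <- which(p$strand == "+" & p$len >= min_plus_anchor)
        ai <- if (length(cand)) cand[which.max(p$len[cand])] else which.max(p$len)
        sigma <- p$strand[ai]
        lead <- sum(p$len[seq_len(ai - 1L)])
        trail <- rl - lead - p$len[ai]
        if (sigma == "+") {
          pos[j] <- p$rs[ai]
          cig[j] <- paste0(if (lead > 0) paste0(lead, "S"), p$len[ai], "M",
                           if (trail > 0) paste0(trail, "S"))
          seqs[j] <- hapseq
          rev[j] <- rd$dir[j] == "-"
        } else {
          # anchored inside an inverted segment: stored orientation reverses
          pos[j] <- p$rs[ai]
          cig[j] <- paste0(if (trail > 0) paste0(trail, "S"), p$len[ai], "M",
                           if (lead > 0) paste0(lead, "S"))
          seqs[j] <- revcomp(hapseq)
          rev[j] <- rd$dir[j] == "+"
        }
      } else {  # naive
        ai <- which.max(p$len)
        overhang <- rl - p$len[ai]
        lead <- sum(p$len[seq_len(ai - 1L)])
        gpos <- p$rs[ai] - lead
        if (overhang <= margin && all(p$strand == "+") &&
            gpos >= 1L && gpos + rl - 1L <= L) {
          pos[j] <- gpos
          cig[j] <- paste0(rl, "M")
          seqs[j] <- hapseq
          rev[j] <- rd$dir[j] == "-"
        } else {
          unmapped[j] <- TRUE
          seqs[j] <- if (rd$dir[j] == "+") hapseq else revcomp(hapseq)
        }
      }
    }
  }

  flag <- 1L + ifelse(rd$mate == 1L, 64L, 128L) +
    ifelse(unmapped, 4L, 0L) + ifelse(rev & !unmapped, 16L, 0L)
  # mate flags/coordinates: join mates through (fragment_id, other mate)
  key <- paste0(rd$fragment_id, ":", 3L - rd$mate)
  midx <- match(key, paste0(rd$fragment_id, ":", rd$mate))
  flag <- flag + ifelse(unmapped[midx], 8L, 0L) +
    ifelse(rev[midx] & !unmapped[midx], 32L, 0L)
  mchrom <- ifelse(unmapped[midx], NA_character_, chrom)
  mpos <- ifelse(unmapped[midx], NA_integer_, pos[midx])

  reads <- data.frame(
    qname = rd$qname, flag = flag,
    chrom = ifelse(unmapped, NA_character_, chrom),
    pos = ifelse(unmapped, NA_integer_, pos),
    mapq = ifelse(unmapped, 0L, 60L),
    cigar = ifelse(unmapped, NA_character_, cig),
    mchrom = mchrom, mpos = mpos,
    seq = seqs, qual = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE)
  sort_alignment(read_alignment(reads, setNames(L, chrom)))
}

#' Choose SV anchor positions on a reference
#'
#' Spreads non-overlapping segments of the requested sizes evenly across the
#' reference interior, then nudges each anchor forward until the junction
#' bases carry no microhomology (the first base on either side of every
#' novel adjacency differs), so that split alignments place the junction
#' unambiguously. Deterministic for a given reference.
#'
#' @param reference named character vector of length 1.
#' @param types character vector of SV types (`DEL`/`DUP`/`INV`).
#' @param lengths integer vector of segment lengths, parallel to `types`.
#' @param edge_margin bp kept free at each end of the reference.
#' @return an `sv_spec` data.frame (`type`, `length`, `anchor`).
#' @export
pick_sv_anchors <- function(reference, types, lengths, edge_margin = 2000L) {
  stopifnot(length(types) == length(lengths))
  L <- nchar(reference)
  k <- length(types)
  free <- L - 2L * edge_margin - sum(lengths)
  if (free < 10L * k) stop("reference too short for the requested SVs")
  gap <- free %/% (k + 1L)
  base <- function(x) substring(reference, x, x)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  anchors <- integer(k)
  cursor <- edge_margin + gap
  for (i in seq_len(k)) {
    s <- cursor + 1L
    repeat {
      e <- s + lengths[i] - 1L
      ok <- if (types[i] == "INV") {
        base(s) != comp[[base(e)]] && base(e + 1L) != comp[[base(s - 1L)]]
      } else {
        # deletions and tandem duplications share the same two junction
        # adjacency checks
        base(s) != base(e + 1L) && base(e) != base(s - 1L)
      }
      if (ok) break
      s <- s + 1L
      if (s > L) stop("could not place SV ", i, " without junction microhomology")
    }
    anchors[i] <- s
    cursor <- s + lengths[i] - 1L + gap
  }
  spec <- data.frame(type = toupper(types), length = as.integer(lengths),
                     anchor = anchors, stringsAsFactors = FALSE)
  validate_sv_spec(spec, L)
}

#' Run one simulation end to end
#'
#' Convenience wrapper: builds the variant haplotype, samples fragments and
#' emits the truth alignment in the requested dialect.
#'
#' @inheritParams emit_truth_alignment
#' @param reference named character vector of length 1.
#' @param sv_spec SV specification (see [simulation_config()]); NULL for a
#'   pure reference sample.
#' @param coverage,variant_fraction,seed forwarded to [simulation_config()].
#' @param ... further arguments to [simulation_config()].
#' @return list with `config`, `variant` ([build_variant_genome()] output or
#'   NULL), `fragments`, `reads`, `alignment`.
#' @export
simulate_dataset <- function(reference, sv_spec = NULL, coverage = 20,
                             variant_fraction = 0, seed = 1L,
                             mode = c("oracle", "naive"), margin = 5L, ...) {
  mode <- match.arg(mode)
  config <- simulation_config(reference_length = nchar(reference),
                              sv_spec = sv_spec, coverage = coverage,
                              variant_fraction = variant_fraction,
                              seed = seed, ...)
  variant <- if (!is.null(sv_spec)) build_variant_genome(reference, sv_spec) else NULL
  sim <- sample_reads(config, reference,
                      variant = if (!is.null(variant)) variant$sequence else NULL)
  aln <- emit_truth_alignment(sim, reference, variant, mode = mode,
                              margin = margin)
  list(config = config, variant = variant, fragments = sim$fragments,
       reads = sim$reads, alignment = aln)
}

#' Write simulator outputs to disk
#'
#' Emits paired FASTQ (`<prefix>_1.fq` / `<prefix>_2.fq`, read names with
#' `/1` and `/2` suffixes), the truth alignment as SAM
#' (`<prefix>.truth.sam`), a fragment truth table
#' (`<prefix>.fragments.tsv`: fragment_id, haplotype, origin_start,
#' frag_len) and, when SVs were simulated, a truth SV table
#' (`<prefix>.svs.tsv`: sv_type, chrom, bp1, bp2, variant_fraction).
#'
#' @param dataset output of [simulate_dataset()].
#' @param reference named character vector of length 1.
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_simulation <- function(dataset, reference, prefix) {
  refseq <- unname(reference)
  varseq <- if (!is.null(dataset$variant)) unname(dataset$variant$sequence)
  rd <- dataset$reads
  hapseq <- ifelse(rd$haplotype == "reference",
                   substring(refseq, rd$a, rd$b),
                   substring(varseq, rd$a, rd$b))
  readseq <- hapseq
  neg <- rd$dir == "-"
  readseq[neg] <- revcomp(hapseq[neg])
  qual <- strrep("I", nchar(readseq))
  files <- c(r1 = paste0(prefix, "_1.fq"), r2 = paste0(prefix, "_2.fq"),
             sam = paste0(prefix, ".truth.sam"),
             fragments = paste0(prefix, ".fragments.tsv"))
  for (m in 1:2) {
    i <- which(rd$mate == m)
    i <- i[order(rd$fragment_id[i])]
    writeLines(paste0("@", rd$qname[i], "/", m, "\n", readseq[i], "\n+\n",
                      qual[i]), files[[m]])
  }
  write_alignment_sam(dataset$alignment, files[["sam"]])
  write.table(dataset$fragments, files[["fragments"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$variant)) {
    files[["svs"]] <- paste0(prefix, ".svs.tsv")
    tt <- dataset$variant$svs[c("sv_id", "sv_type", "chrom", "bp1", "bp2", "length")]
    tt$variant_fraction <- dataset$config$variant_fraction
    write.table(tt, files[["svs"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(files)
}
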