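# Shared fixtures and independent oracles.

DEFAULT_SCORING <- list(match = 1, mismatch = -3, gap_open = -5,
                        gap_extend = -2, min_score = 25)

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent brute-force Smith-Waterman-Gotoh score (three explicit DP
# matrices, plain R); the oracle for the C++ local aligner
bf_local_score <- function(read, window, scoring = DEFAULT_SCORING) {
  n <- nchar(read)
  m <- nchar(window)
  r <- strsplit(read, "")[[1]]
  w <- strsplit(window, "")[[1]]
  NEG <- -1e18
  M <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(E[i, j - 1], M[i, j - 1] + scoring$gap_open) + scoring$gap_extend
    F[i, j] <- max(F[i - 1, j], M[i - 1, j] + scoring$gap_open) + scoring$gap_extend
    s <- if (r[i - 1] == w[j - 1]) scoring$match else scoring$mismatch
    M[i, j] <- max(0, M[i - 1, j - 1] + s, E[i, j], F[i, j])
    if (M[i, j] > best) best <- M[i, j]
  }
  best
}

# build one alignment record; seq defaults to the right length of 'A's
toy_read <- function(qname, chrom, pos, cigar, seq = NULL, flag = 0L,
                     mchrom = NA_character_, mpos = NA_integer_) {
  if (is.null(seq) && !is.na(cigar)) {
    qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
    seq <- strrep("A", qw)
  }
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = 60L, cigar = cigar, mchrom = mchrom, mpos = mpos,
             seq = seq, qual = strrep("I", nchar(seq)),
             stringsAsFactors = FALSE)
}

toy_alignment <- function(..., seqinfo) {
  sort_alignment(read_alignment(do.call(rbind, list(...)), seqinfo))
}

# one-SV simulation fixture used by several files (built once per session)
.fixture_env <- new.env()
del_fixture <- function() {
  if (is.null(.fixture_env$del)) {
    reference <- random_reference(12000, seed = 42)
    spec <- pick_sv_anchors(reference, "DEL", 800)
    .fixture_env$del <- list(
      reference = reference, spec = spec,
      naive = simulate_dataset(reference, spec, coverage = 80,
                               variant_fraction = 0.6, seed = 3,
                               mode = "naive"),
      oracle = simulate_dataset(reference, spec, coverage = 80,
                                variant_fraction = 0.6, seed = 3,
                                mode = "oracle"))
  }
  .fixture_env$del
}

# normalise a truth SV table to the caller's report shape
truth_as_calls <- function(truth) {
  data.frame(sv_id = truth$sv_id, sv_type = truth$sv_type,
             chrom1 = truth$chrom, bp1 = truth$bp1,
             chrom2 = truth$chrom, bp2 = truth$bp2,
             support_bp1 = NA_integer_, support_bp2 = NA_integer_,
             status = "confirmed", stringsAsFactors = FALSE)
}
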