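# Soft-clip clustering, partner matching and the derivative-SV filter.

test_that("clip boundaries cluster with modal position and support threshold", {
  mk <- function(n, pos, cigar, seq) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      toy_read(sprintf("r%d_%d", pos, i), "chr1", pos, cigar, seq = seq)
    }))
  }
  clipseq <- paste0(strrep("A", 60), strrep("C", 15))
  aln <- sort_alignment(read_alignment(rbind(
    mk(10, 4941L, "60M15S", clipseq),         # right boundary at 5000
    mk(8, 4941L, "60M15S", clipseq),          # same boundary (total 18)
    mk(2, 4942L, "60M15S", clipseq),          # boundary 5001, merges
    mk(1, 7000L, "60M15S", clipseq)),         # lone clip: below support
    c(chr1 = 10000L)))
  cl <- build_clusters(aln, min_clip_len = 8L, merge_window = 2L,
                       min_cluster_support = 3L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$pos, 5000L)
  expect_equal(cl$side, "right_clip")
  expect_equal(cl$support, 20L)
  expect_equal(cl$consensus, strrep("C", 15))
})

test_that("short clips and sub-threshold clusters are ignored", {
  aln <- toy_alignment(
    toy_read("a", "chr1", 100L, "70M5S"),   # clip below min_clip_len
    toy_read("b", "chr1", 200L, "60M15S"),  # support 1 < 3
    seqinfo = c(chr1 = 1000L))
  cl <- build_clusters(aln)
  expect_equal(nrow(cl), 0L)
})

test_that("unsorted input is rejected with advice to sort", {
  unsorted <- read_alignment(rbind(
    toy_read("a", "chr1", 500L, "75M"),
    toy_read("b", "chr1", 100L, "75M")), c(chr1 = 1000L))
  expect_error(build_clusters(unsorted), "sort")
})

test_that("partner matching recovers each SV type at exact truth breakpoints", {
  ref <- random_reference(12000, seed = 42)
  for (ty in c("DEL", "DUP", "INV")) {
    spec <- pick_sv_anchors(ref, ty, 800)
    ds <- simulate_dataset(ref, spec, coverage = 60, variant_fraction = 1,
                           seed = 7, mode = "oracle")
    svs <- detect_svs(ds$alignment, ref, run_config())
    truth <- ds$variant$svs
    expect_equal(nrow(svs), 1L, info = ty)
    expect_equal(svs$sv_type, ty)
    expect_equal(svs$bp1, truth$bp1, info = ty)
    expect_equal(svs$bp2, truth$bp2, info = ty)
    expect_gte(min(svs$support_bp1, svs$support_bp2), 3L)
  }
})

test_that("clusters whose clips do not explain each other emit no SV", {
  ref <- random_reference(5000, seed = 17)
  clusters <- data.frame(
    chrom = "chrSim", pos = c(1000L, 3000L),
    side = c("right_clip", "left_clip"),
    support = c(5L, 5L),
    consensus = c(strrep("A", 20), strrep("C", 20)),
    stringsAsFactors = FALSE)
  svs <- match_partners(clusters, ref, run_config())
  expect_equal(nrow(svs), 0L)
})

test_that("reciprocal cross-chromosome matches are reported as translocations", {
  set.seed(31)
  ref <- c(chrA = rand_dna(3000), chrB = rand_dna(3000))
  # clip of the right cluster on chrA continues at chrB:1001; clip of the
  # left cluster on chrB ends at chrA:1500
  clusters <- data.frame(
    chrom = c("chrA", "chrB"), pos = c(1500L, 1001L),
    side = c("right_clip", "left_clip"),
    support = c(6L, 7L),
    consensus = c(substring(ref[["chrB"]], 1001, 1020),
                  substring(ref[["chrA"]], 1481, 1500)),
    stringsAsFactors = FALSE)
  svs <- match_partners(clusters, ref, run_config())
  expect_equal(svs$sv_type, "TRA")
  expect_equal(svs$chrom1, "chrA")
  expect_equal(svs$bp1, 1500L)
  expect_equal(svs$chrom2, "chrB")
  expect_equal(svs$bp2, 1000L)
})

test_that("derivative filter discards only the weak near-duplicate call", {
  svs <- data.frame(
    sv_id = c("sv1", "sv2"), sv_type = "DEL",
    chrom1 = "chrX", bp1 = c(10000L, 10000L),
    chrom2 = "chrX", bp2 = c(20000L, 20004L),  # 4 bp off on one breakpoint
    support_bp1 = c(400L, 3L), support_bp2 = c(373L, 3L),  # 773 vs 6
    status = "candidate", stringsAsFactors = FALSE)
  out <- filter_derivative_svs(svs, main_window = 20L, support_ratio = 0.1,
                               clip_tolerance = 2L)
  expect_equal(out$status, c("candidate", "filtered"))

  # equal support: neither call is filtered
  eq <- svs
  eq$support_bp1 <- c(400L, 400L)
  eq$support_bp2 <- c(373L, 373L)
  expect_equal(filter_derivative_svs(eq)$status, c("candidate", "candidate"))

  # a single SV is left unchanged
  one <- svs[1, ]
  expect_equal(filter_derivative_svs(one)$status, "candidate")
})
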