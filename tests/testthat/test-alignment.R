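# Alignment container, SAM I/O, CIGAR bookkeeping, the local aligner and
# the breakpoint read classifier.

test_that("cigar_stats decomposes clips and widths", {
  cs <- cigar_stats(c("75M", "10S65M", "65M10S", "5H10S60M", "*", NA))
  expect_equal(cs$lsoft, c(0L, 10L, 0L, 10L, NA, NA))
  expect_equal(cs$rsoft, c(0L, 0L, 10L, 0L, NA, NA))
  expect_equal(cs$lhard, c(0L, 0L, 0L, 5L, NA, NA))
  expect_equal(cs$ref_width, c(75L, 65L, 65L, 60L, NA, NA))
  expect_equal(cs$qwidth, c(75L, 75L, 75L, 70L, NA, NA))
  expect_error(cigar_stats("10M5S10M"), "malformed")
})

test_that("read_alignment validates record invariants", {
  good <- toy_read("r1", "chr1", 100L, "10S65M")
  expect_silent(read_alignment(good, c(chr1 = 1000L)))
  bad <- good
  bad$seq <- "ACGT"  # query width disagrees
  bad$qual <- "IIII"
  expect_error(read_alignment(bad, c(chr1 = 1000L)), "width")
  expect_error(read_alignment(good, c(chr2 = 1000L)), "absent")
})

test_that("SAM round trip preserves records semantically", {
  aln <- toy_alignment(
    toy_read("p1", "chr1", 100L, "75M", flag = 1L + 64L,
             mchrom = "chr1", mpos = 300L),
    toy_read("p1", "chr1", 300L, "75M", flag = 1L + 128L + 16L,
             mchrom = "chr1", mpos = 100L),
    toy_read("c1", "chr1", 500L, "10S65M", seq = paste0(strrep("C", 10),
                                                        strrep("A", 65))),
    data.frame(qname = "u1", flag = 4L, chrom = NA_character_,
               pos = NA_integer_, mapq = 0L, cigar = NA_character_,
               mchrom = NA_character_, mpos = NA_integer_,
               seq = strrep("G", 75), qual = strrep("I", 75),
               stringsAsFactors = FALSE),
    seqinfo = c(chr1 = 2000L))
  path <- tempfile(fileext = ".sam")
  write_alignment_sam(aln, path)
  back <- read_alignment_file(path)
  keep <- c("qname", "flag", "chrom", "pos", "cigar", "seq")
  o1 <- aln$reads[order(aln$reads$qname, aln$reads$flag), keep]
  o2 <- back$reads[order(back$reads$qname, back$reads$flag), keep]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(back$seqinfo, c(chr1 = 2000L))
  expect_equal(nrow(unmapped_reads(back)), 1L)

  # region filter excludes non-overlapping and unmapped records
  reg <- read_alignment_file(path, region = list(chrom = "chr1",
                                                 start = 90, end = 120))
  expect_equal(reg$reads$qname, "p1")
})

test_that("malformed or headerless SAM fails loudly", {
  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "r1\t0\tchr1"), bad)  # truncated record, no @SQ
  expect_error(read_alignment_file(bad))
  missing <- tempfile(fileext = ".sam")
  expect_error(read_alignment_file(missing), "not found")
})

test_that("local_align handles exact, clipped and hopeless reads", {
  sc <- DEFAULT_SCORING
  set.seed(11)
  win <- rand_dna(200)
  # read identical to a window substring: full-length match, no clipping
  rd <- substring(win, 50, 89)
  r <- local_align(rd, win, scoring = sc)
  expect_equal(r$score, 40)
  expect_equal(r$ref_start, 50L)
  expect_equal(r$cigar, "40M")
  expect_equal(c(r$lclip, r$rclip), c(0L, 0L))

  # read whose first 30 bases match and last 10 come from elsewhere:
  # suffix becomes a soft clip
  distal <- rand_dna(10)
  rd2 <- paste0(substring(win, 20, 49), distal)
  r2 <- local_align(rd2, win, scoring = sc)
  expect_equal(r2$ref_start, 20L)
  expect_gte(r2$rclip, 9L)  # microhomology can extend the match by one
  expect_equal(r2$read_start, 1L)

  # no adequate local hit: reported unmapped in the window
  r3 <- local_align(strrep("A", 30), strrep("C", 100), scoring = sc)
  expect_false(r3$mapped)

  expect_error(local_align("", win, sc), "non-empty")
})

test_that("local aligner agrees with the brute-force DP oracle", {
  set.seed(7)
  sc <- DEFAULT_SCORING
  for (t in 1:300) {
    n <- sample(5:40, 1)
    m <- sample(10:120, 1)
    rd <- rand_dna(n)
    wn <- rand_dna(m)
    if (runif(1) < 0.6 && m > n) {
      # embed a mutated copy of the read so non-trivial alignments occur
      pos <- sample(1:(m - n + 1), 1)
      sub <- strsplit(rd, "")[[1]]
      flip <- runif(n) < 0.15
      sub[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      wn <- paste0(substr(wn, 1, pos - 1), paste(sub, collapse = ""),
                   substr(wn, pos + n, m))
    }
    got <- clipsv:::.sw_align_cpp(rd, wn, sc$match, sc$mismatch,
                                  sc$gap_open, sc$gap_extend)
    expect_equal(got$score, bf_local_score(rd, wn, sc))
  }
})

test_that("classifier spec cases: spanning, clipped, neither", {
  bp <- list(chrom = "chr1", pos = 200L, side = "right_clip")
  reads <- rbind(
    toy_read("span", "chr1", 150L, "75M"),
    toy_read("clip", "chr1", 136L, "65M10S"),      # match ends exactly at 200
    toy_read("near", "chr1", 128L, "75M"),         # ends unclipped at 202
    toy_read("far", "chr1", 1000L, "75M"),
    data.frame(qname = "un", flag = 4L, chrom = NA_character_,
               pos = NA_integer_, mapq = 0L, cigar = NA_character_,
               mchrom = NA_character_, mpos = NA_integer_,
               seq = strrep("A", 75), qual = strrep("I", 75),
               stringsAsFactors = FALSE))
  cls <- classify_read_at_breakpoint(reads, bp, anchor = 5L,
                                     clip_tolerance = 2L)
  expect_equal(cls, c("spanning", "soft_clipped", "neither", "neither",
                      "neither"))
})

test_that("classifier matches a brute-force rule over all 75-mer placements", {
  # independent restatement of the rule for simple 75M and one-clip reads
  bf_rule <- function(pos, end, lclip, rclip, bp, side, anchor, tol) {
    near_l <- lclip > 0 && min(abs(pos - bp), abs(pos - (bp + 1))) <= tol
    near_r <- rclip > 0 && min(abs(end - bp), abs(end - (bp + 1))) <= tol
    clipped <- if (side == "right_clip") rclip > 0 && abs(end - bp) <= tol
               else lclip > 0 && abs(pos - (bp + 1)) <= tol
    if (clipped) return("soft_clipped")
    if (pos <= bp - anchor + 1 && end >= bp + anchor && !near_l && !near_r) {
      return("spanning")
    }
    "neither"
  }
  bp <- 500L
  for (side in c("right_clip", "left_clip")) {
    for (off in -80:80) {
      for (cig in c("75M", "65M10S", "10S65M")) {
        cs <- cigar_stats(cig)
        pos <- bp + off
        rd <- toy_read("x", "chr1", pos, cig)
        got <- classify_read_at_breakpoint(
          rd, list(chrom = "chr1", pos = bp, side = side))
        want <- bf_rule(pos, pos + cs$ref_width - 1L, cs$lsoft, cs$rsoft,
                        bp, side, 5L, 2L)
        expect_equal(got, want, info = paste(side, off, cig))
      }
    }
  }
})

test_that("classifier partitions reads overlapping the breakpoint window", {
  fx <- del_fixture()
  aln <- fx$oracle$alignment
  sv <- fx$oracle$variant$svs
  bp <- list(chrom = sv$chrom, pos = sv$bp1, side = "right_clip")
  cls <- classify_read_at_breakpoint(aln$reads, bp)
  expect_true(all(cls %in% c("spanning", "soft_clipped", "neither")))
  expect_gt(sum(cls == "spanning"), 0)
  expect_gt(sum(cls == "soft_clipped"), 0)
  expect_equal(sum(cls %in% c("spanning", "soft_clipped", "neither")),
               nrow(aln$reads))
})
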