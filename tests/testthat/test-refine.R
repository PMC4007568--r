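# Extraction, targeted realignment and the iterative refinement loop.

test_that("extraction returns breakpoint-window and unmapped reads only", {
  fx <- del_fixture()
  aln <- fx$naive$alignment
  svs <- truth_as_calls(fx$naive$variant$svs)

  # no SVs, no unmapped reads: nothing extracted
  clean <- fx$oracle$alignment
  e0 <- extract_candidates(clean, svs[0, ], neighborhood = 650L)
  expect_equal(nrow(e0$bp_reads), 0L)
  expect_equal(length(e0$unmapped_rows), 0L)

  ext <- extract_candidates(aln, svs, neighborhood = 650L)
  expect_equal(sort(ext$unmapped_rows),
               which(bitwAnd(aln$reads$flag, 4L) != 0L))
  # every extracted mapped read overlaps a breakpoint window
  r <- aln$reads[ext$bp_reads$row, ]
  cs <- cigar_stats(r$cigar)
  ends <- r$pos + cs$ref_width - 1L
  near <- outer(r$pos, c(svs$bp1, svs$bp2) + 650L, "<=") &
    outer(ends, c(svs$bp1, svs$bp2) - 650L, ">=")
  expect_true(all(rowSums(near) > 0))
  # and no read 10 kb away is touched
  far <- which(!is.na(aln$reads$pos) &
                 pmin(abs(aln$reads$pos - svs$bp1),
                      abs(aln$reads$pos - svs$bp2)) > 10000)
  expect_false(any(far %in% ext$bp_reads$row))

  # every mapped read whose fragment truly crosses the junction is extracted
  rd <- fx$naive$reads
  vj <- fx$naive$variant$svs$vjunc1
  cross_q <- unique(rd$qname[rd$haplotype == "variant" &
                               rd$a <= vj & rd$b > vj])
  mapped_cross <- which(aln$reads$qname %in% cross_q &
                          bitwAnd(aln$reads$flag, 4L) == 0L)
  expect_true(all(mapped_cross %in% ext$bp_reads$row))
})

test_that("realignment is idempotent on an already-correct alignment", {
  fx <- del_fixture()
  aln <- fx$oracle$alignment
  svs <- truth_as_calls(fx$oracle$variant$svs)
  ext <- extract_candidates(aln, svs, neighborhood = 650L)
  out <- realign_candidates(aln, ext, fx$reference, svs, run_config())
  key <- function(x) paste0(x$qname, "/", bitwAnd(x$flag, 192L))
  m <- match(key(aln$reads), key(out$reads))
  expect_equal(out$reads$pos[m], aln$reads$pos)
  expect_equal(out$reads$cigar[m], aln$reads$cigar)
})

test_that("refinement fixes forced-global and unmapped junction reads", {
  fx <- del_fixture()
  sv <- fx$naive$variant$svs
  rd <- fx$naive$reads
  vj <- sv$vjunc1
  rf <- run_refinement(fx$naive$alignment, fx$reference, run_config())
  expect_true(rf$converged)
  expect_lte(rf$iterations, 3L)
  expect_equal(rf$svs$sv_type, "DEL")
  expect_equal(rf$svs$bp1, sv$bp1)
  expect_equal(rf$svs$bp2, sv$bp2)

  # every junction-crossing read (forced-global with a small overhang, or
  # unmapped with a large one) ends up soft-clipped exactly at a junction
  crosses <- rd$haplotype == "variant" & rd$a <= vj & rd$b > vj &
    pmin(rd$b - vj, vj - rd$a + 1L) >= 8L
  ckey <- paste0(rd$qname, "/", c(64L, 128L)[rd$mate])[crosses]
  fin <- rf$alignment$reads
  fkey <- paste0(fin$qname, "/", bitwAnd(fin$flag, 192L))
  rows <- match(ckey, fkey)
  cs <- cigar_stats(fin$cigar[rows])
  ends <- fin$pos[rows] + cs$ref_width - 1L
  clipped_at_junction <-
    (cs$rsoft > 0 & ends == sv$bp1) | (cs$lsoft > 0 & fin$pos[rows] == sv$bp2 + 1L)
  expect_true(all(clipped_at_junction))
  expect_equal(nrow(unmapped_reads(rf$alignment)), 0L)

  # reads never extracted are untouched
  ext <- extract_candidates(fx$naive$alignment,
                            truth_as_calls(sv), neighborhood = 650L)
  touched <- union(ext$bp_reads$row, ext$unmapped_rows)
  nkey <- paste0(fx$naive$alignment$reads$qname, "/",
                 bitwAnd(fx$naive$alignment$reads$flag, 192L))
  keep <- setdiff(seq_len(nrow(fx$naive$alignment$reads)), touched)
  m <- match(nkey[keep], fkey)
  expect_equal(fin$pos[m], fx$naive$alignment$reads$pos[keep])
  expect_equal(fin$cigar[m], fx$naive$alignment$reads$cigar[keep])

  # soft-clip support never decreases between consecutive iterations
  if (length(rf$history) >= 2) {
    for (i in 2:length(rf$history)) {
      prev <- rf$history[[i - 1]]
      cur <- rf$history[[i]]
      key <- function(s) paste(s$sv_type, s$bp1, s$bp2)
      shared <- intersect(key(prev), key(cur))
      p <- prev[match(shared, key(prev)), ]
      q <- cur[match(shared, key(cur)), ]
      expect_true(all(q$support_bp1 + q$support_bp2 >=
                        p$support_bp1 + p$support_bp2))
    }
  }
})

test_that("refinement on an oracle alignment converges in one pass", {
  fx <- del_fixture()
  rf <- run_refinement(fx$oracle$alignment, fx$reference, run_config())
  expect_true(rf$converged)
  expect_equal(rf$iterations, 1L)
  expect_equal(rf$svs$bp1, fx$oracle$variant$svs$bp1)
})

test_that("an empty alignment converges immediately with no SVs", {
  empty <- read_alignment(
    data.frame(qname = character(0), flag = integer(0),
               chrom = character(0), pos = integer(0), mapq = integer(0),
               cigar = character(0), mchrom = character(0),
               mpos = integer(0), seq = character(0), qual = character(0),
               stringsAsFactors = FALSE),
    c(chr1 = 1000L))
  rf <- run_refinement(empty, setNames(strrep("A", 1000), "chr1"),
                       run_config())
  expect_true(rf$converged)
  expect_equal(nrow(rf$svs), 0L)
  expect_equal(rf$iterations, 0L)
})
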