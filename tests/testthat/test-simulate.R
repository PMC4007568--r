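# Variant genome construction and the heterogeneous read simulator.

test_that("build_variant_genome applies DEL, DUP and INV as specified", {
  ref <- setNames("AAACCCGGGTTT", "chr1")
  del <- build_variant_genome(ref, data.frame(type = "DEL", length = 3, anchor = 4))
  expect_equal(unname(del$sequence), "AAAGGGTTT")
  expect_equal(del$svs$bp1, 3L)
  expect_equal(del$svs$bp2, 6L)
  dup <- build_variant_genome(ref, data.frame(type = "DUP", length = 3, anchor = 4))
  expect_equal(unname(dup$sequence), "AAACCCCCCGGGTTT")
  inv <- build_variant_genome(ref, data.frame(type = "INV", length = 3, anchor = 7))
  expect_equal(unname(nchar(inv$sequence)), 12L)
  expect_equal(unname(substr(inv$sequence, 7, 9)), "CCC")  # reverse complement of GGG
})

test_that("length change equals dup minus del lengths", {
  set.seed(5)
  ref <- random_reference(20000, seed = 5)
  spec <- pick_sv_anchors(ref, c("DEL", "DUP", "INV"), c(500, 800, 300),
                          edge_margin = 1000)
  v <- build_variant_genome(ref, spec)
  expect_equal(unname(nchar(v$sequence)), 20000L + 800L - 500L)
})

test_that("invalid SV specifications are rejected with the offending SV named", {
  ref <- setNames(strrep("ACGT", 1000), "chr1")
  expect_error(
    build_variant_genome(ref, data.frame(type = c("DEL", "DUP"),
                                         length = c(100, 100),
                                         anchor = c(50, 100))),
    "overlaps")
  expect_error(
    build_variant_genome(ref, data.frame(type = "DEL", length = 100,
                                         anchor = 3950)),
    "SV 1.*outside")
  expect_error(
    build_variant_genome(ref, data.frame(type = "XXX", length = 10,
                                         anchor = 50)),
    "unsupported type")
})

test_that("fragment count follows the coverage definition", {
  ref <- random_reference(70000, seed = 1)
  cfg <- simulation_config(70000, coverage = 20, seed = 1)
  sim <- sample_reads(cfg, ref)
  expect_equal(nrow(sim$fragments), 9333L)  # floor(20 * 70000 / 150)
  expect_equal(nrow(sim$reads), 2L * 9333L)
})

test_that("simulation is deterministic under a fixed seed", {
  ref <- random_reference(6000, seed = 2)
  spec <- pick_sv_anchors(ref, "DEL", 400, edge_margin = 600)
  a <- simulate_dataset(ref, spec, coverage = 15, variant_fraction = 0.5,
                        seed = 9, mode = "oracle")
  b <- simulate_dataset(ref, spec, coverage = 15, variant_fraction = 0.5,
                        seed = 9, mode = "oracle")
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$alignment$reads, b$alignment$reads)
  c <- simulate_dataset(ref, spec, coverage = 15, variant_fraction = 0.5,
                        seed = 10, mode = "oracle")
  expect_false(identical(a$fragments, c$fragments))
})

test_that("haplotype sampling is Bernoulli(variant_fraction)", {
  ref <- random_reference(5000, seed = 3)
  spec <- pick_sv_anchors(ref, "DEL", 300, edge_margin = 500)
  v <- build_variant_genome(ref, spec)
  # variant_fraction 0: every fragment is reference
  cfg0 <- simulation_config(5000, sv_spec = spec, variant_fraction = 0,
                            coverage = 30, seed = 4)
  sim0 <- sample_reads(cfg0, ref, v$sequence)
  expect_true(all(sim0$fragments$haplotype == "reference"))
  # 10,000 fragments at fraction 0.2: count within 3 binomial sd of 2,000
  cfg <- simulation_config(5000, sv_spec = spec, variant_fraction = 0.2,
                           coverage = 300, seed = 4)
  sim <- sample_reads(cfg, ref, v$sequence)
  expect_equal(nrow(sim$fragments), 10000L)
  nv <- sum(sim$fragments$haplotype == "variant")
  expect_lt(abs(nv - 2000), 3 * sqrt(10000 * 0.2 * 0.8))
})

test_that("fragment lengths respect the truncated normal model", {
  ref <- random_reference(20000, seed = 6)
  cfg <- simulation_config(20000, coverage = 50, seed = 11)
  sim <- sample_reads(cfg, ref)
  fl <- sim$fragments$frag_len
  expect_true(all(fl >= 175 & fl <= 325))
  expect_lt(abs(mean(fl) - 250), 3 * 20 / sqrt(length(fl)))
})

test_that("mean depth matches configured coverage within 5%", {
  ref <- random_reference(10000, seed = 8)
  ds <- simulate_dataset(ref, NULL, coverage = 20, variant_fraction = 0,
                         seed = 12, mode = "oracle")
  cs <- cigar_stats(ds$alignment$reads$cigar)
  mean_depth <- sum(cs$ref_width) / 10000
  expect_lt(abs(mean_depth - 20) / 20, 0.05)
})

test_that("oracle placements reproduce the reference base-for-base", {
  # strong self-consistency: the matched portion of every oracle-mode read
  # must equal the reference substring it claims to cover
  ref <- random_reference(15000, seed = 13)
  spec <- pick_sv_anchors(ref, c("DEL", "DUP", "INV"), c(400, 500, 300),
                          edge_margin = 1000)
  ds <- simulate_dataset(ref, spec, coverage = 25, variant_fraction = 0.6,
                         seed = 14, mode = "oracle")
  r <- ds$alignment$reads
  r <- r[bitwAnd(r$flag, 4L) == 0L, ]
  cs <- cigar_stats(r$cigar)
  matched <- substr(r$seq, cs$lsoft + 1L, cs$lsoft + cs$ref_width)
  wanted <- substring(unname(ref), r$pos, r$pos + cs$ref_width - 1L)
  expect_true(all(matched == wanted))
})

test_that("oracle mode clips junction reads exactly at the junction", {
  fx <- del_fixture()
  sv <- fx$oracle$variant$svs
  r <- fx$oracle$alignment$reads
  cs <- cigar_stats(r$cigar)
  rclips <- which(cs$rsoft > 0)
  lclips <- which(cs$lsoft > 0)
  expect_true(all(r$pos[rclips] + cs$ref_width[rclips] - 1L == sv$bp1))
  expect_true(all(r$pos[lclips] == sv$bp2 + 1L))
  # a junction read with 10 bases on the far side gets a 10-base clip
  expect_true(any(cs$rsoft[rclips] == 10L) || any(cs$lsoft[lclips] == 10L))
})

test_that("naive mode hides junction signal the way a global aligner does", {
  fx <- del_fixture()
  sv <- fx$naive$variant$svs
  rd <- fx$naive$reads
  rn <- fx$naive$alignment$reads
  ro <- fx$oracle$alignment$reads
  # identical placement for reads fully inside a block
  key <- function(x) paste0(x$qname, "/", bitwAnd(x$flag, 192L))
  vj <- sv$vjunc1
  crosses <- rd$haplotype == "variant" & rd$a <= vj & rd$b > vj
  plain <- setdiff(key(rn), paste0(rd$qname, "/", c(64L, 128L)[rd$mate])[crosses])
  m <- match(plain, key(ro))
  n <- match(plain, key(rn))
  expect_equal(rn$pos[n], ro$pos[m])
  expect_equal(rn$cigar[n], ro$cigar[m])
  # junction-crossing reads: forced 75M when overhang <= margin, unmapped
  # beyond
  ckey <- paste0(rd$qname, "/", c(64L, 128L)[rd$mate])[crosses]
  overhang <- pmin(rd$b[crosses] - vj, vj - rd$a[crosses] + 1L)
  cn <- match(ckey, key(rn))
  forced <- overhang <= 5L
  expect_true(all(rn$cigar[cn[forced]] == "75M"))
  expect_true(all(bitwAnd(rn$flag[cn[!forced]], 4L) == 4L))
  expect_equal(sum(!forced), nrow(unmapped_reads(fx$naive$alignment)))
})

test_that("simulator files are written in standard formats", {
  ref <- random_reference(4000, seed = 21)
  spec <- pick_sv_anchors(ref, "DEL", 200, edge_margin = 450)
  ds <- simulate_dataset(ref, spec, coverage = 10, variant_fraction = 0.5,
                         seed = 22, mode = "oracle")
  prefix <- tempfile()
  files <- write_simulation(ds, ref, prefix)
  expect_true(all(file.exists(files)))
  fq <- readLines(files[["r1"]])
  expect_equal(length(fq) %% 4, 0L)
  expect_true(all(grepl("/1$", fq[seq(1, length(fq), by = 4)])))
  expect_equal(unique(nchar(fq[seq(2, length(fq), by = 4)])), 75L)
  back <- read_alignment_file(files[["sam"]])
  expect_equal(nrow(back$reads), nrow(ds$alignment$reads))
  truth <- read.table(files[["fragments"]], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), nrow(ds$fragments))
  svtab <- read.table(files[["svs"]], header = TRUE, sep = "\t")
  expect_equal(svtab$bp1, ds$variant$svs$bp1)
})
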