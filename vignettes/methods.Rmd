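---
title: "Split-read SV detection and heterogeneity estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-read SV detection and heterogeneity estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clipsv)
```

# The problem

Sequencing samples from tumors and other mixed cell populations carry
structural variants (SVs) present in only a fraction of the cells. In an
alignment against the reference, a read sampled across an SV junction can
only align partially; a local aligner stores the overhanging bases as a
*soft clip*. Reads from the reference-like subpopulation span the same
positions without clipping. This package detects SVs from clusters of
soft-clip boundaries, repairs the soft-clipping errors a global aligner
introduces near those junctions, quantifies each SV's *heterogeneity
percentage* — the estimated fraction of the sample carrying it — from the
ratio of clipped to spanning reads, and applies a chosen set of SVs to the
reference to produce a personal genomic sequence for downstream analyses.

Coordinates are 1-based and inclusive throughout, as in SAM. A breakpoint's
position is defined as the **last reference base before the junction on its
side**; the segment affected by an SV with breakpoints `bp1 < bp2` is
`bp1+1 .. bp2`. A deletion removes that segment, a tandem duplication
inserts a second copy immediately after `bp2`, and an inversion
reverse-complements it in place. This convention is used identically by the
simulator, the caller and the genome builder, which is what makes the
round-trip test (simulator truth → `apply_edits` → variant genome,
byte-for-byte) possible.

# Detection model

**Clustering** (`build_clusters`). Every clip boundary with clip length at
least `min_clip_len` (default 8 bp — shorter clips are uninformative for
partner matching and arise freely from base errors in real data) is binned
by chromosome and side. Boundaries within `merge_window` (2 bp) merge; the
modal boundary becomes the cluster position (ties to the smaller
coordinate); clusters with fewer than `min_cluster_support` (3) members are
dropped. The consensus clipped sequence is a per-column majority anchored
at the boundary, ties resolved to the lexicographically smallest base —
an arbitrary but reproducible rule. Hard-clipped records mark boundaries
and add support but contribute no sequence.

**Partner matching** (`match_partners`). For each (right-clip `p`,
left-clip `q`) cluster pair within `search_radius` (100 kb, generous for
the 30 kb events the simulation protocol uses), both consensus clips are
locally aligned against the partner's neighbourhood (±`match_pad` = 10 bp)
and a candidate SV is emitted only when *both* directions reach
`min_identity` (0.9 over the clip length) at positions consistent with the
pair. The requirement that the two clusters explain each other is the
precision guard; "clusters that match" is read as bidirectional. Typing
falls out of geometry and orientation:

* forward match, `q > p + 1` → DEL with breakpoints `(p, q−1)`;
* forward match, `q ≤ p` → tandem DUP with breakpoints `(q−1, p)`;
* reverse-complement match, `q > p + 1` → INV with breakpoints `(p, q−1)`;
* reciprocal forward match across chromosomes → TRA (reported, never
  applied to a genome).

**Derivative filter** (`filter_derivative_svs`). A call that shares one
breakpoint (within `clip_tolerance` = 2 bp) with a same-type call, has its
other breakpoint within `main_window` (20 bp), and has total support below
`support_ratio` (0.1) times the stronger call's is marked `filtered`:
such slight derivations of a strong call are sequencing-error artifacts.
Equal-support pairs are never filtered.

# Targeted realignment

A global aligner hides junction reads in two ways: a read overhanging the
junction by a few bases is forced end-to-end with mismatches (the global
alignment is "good enough"), and a read with a large overhang may be left
unmapped entirely. The refinement loop (`run_refinement`) repairs exactly
these reads: every read whose alignment overlaps
`[bp − neighborhood, bp + neighborhood]` for any candidate breakpoint, plus
all unmapped reads, is extracted and realigned individually (pairing
constraints removed). Concordant reads elsewhere are never touched — that
is the efficiency argument for targeted refinement over whole-library
realignment. Extraction always re-starts from the *original* alignment, so
a record is replaced at most once per iteration and the loop's output is
independent of its path. Iteration stops when the SV set
(type + both breakpoints; support counts excluded, since support keeps
growing as clipping improves) is identical between consecutive passes;
`max_iterations` (5) is a hard cap and non-convergence is a warning, not an
error. On oracle-quality input the loop converges in a single pass; on
naive-mode simulations, in two.

`neighborhood` defaults to 650 bp = 2 × the maximum simulated fragment
length, so junction reads *and their mates* are captured. Unmapped reads
are realigned against the whole reference by exact `seed_length`-mer
lookup (20 bp, both read ends, both orientations) followed by local
alignment in the seeded window; exact seeds suffice for error-free reads
and the length can be lowered for real data. Breakpoint reads are
realigned against both breakpoint windows of their SV (windows padded by
one read length so edge-overlapping reads align fully) and keep the
best-scoring placement; a read that reaches `min_score` nowhere keeps its
original record.

**The local aligner** is a Smith–Waterman–Gotoh kernel (Rcpp) with
affine gaps: defaults `match = 1`, `mismatch = −3`, `gap_open = −5`,
`gap_extend = −2` (a gap of length *k* costs `gap_open + k·gap_extend`),
`min_score = 25`. These are conventional local-alignment settings in the
BWA-SW family; the exact values matter little for error-free data because
junction reads score as the length of their anchored side (≥ 38 for any
75 bp read split across a junction). Determinism is part of the contract:
among equal-score placements the leftmost window position wins, then the
shorter read prefix; traceback prefers a diagonal step, then the shortest
reference gap, then the shortest read gap. Scores are validated against an
independent brute-force three-matrix DP in the test suite.

# Heterogeneity estimation

At each breakpoint, reads are classified (`classify_read_at_breakpoint`)
as **spanning** (a single contiguous match run covers
`[pos − anchor + 1, pos + anchor]`, `anchor` = 5 bp, with no clip boundary
within `clip_tolerance` = 2 bp of the junction), **soft-clipped** (a clip
boundary within `clip_tolerance` of the junction on the breakpoint's
clipped side), or **neither**. The tolerance absorbs one-off junction
ambiguity from microhomology. `A` sums spanning calls over both
breakpoints; `B` counts reads clipped at either breakpoint — once per
read, so a short-fragment read clipped at both junction-adjacent positions
of one SV is not double-counted.

With `V = B` as the variant depth, the reference depth and `H = V/(V+R)`
by type:

* **Deletion**: the two reference breakpoints are one locus on the variant
  haplotype, so spanning reads are averaged: `R = A/2`,
  `H = B/(B + A/2)`.
* **Tandem duplication**: reads spanning the repeat's outer edges come
  from *both* populations, so the variant contribution is subtracted:
  `R = A/2 − B`, `H = B/(A/2)`. Sampling noise can drive `B > A/2`; the
  estimate is then clamped to `H = 1`, `R = 0` and flagged, rather than
  reporting a negative depth.
* **Inversion**: no copy-number change; `H = B/(A + B)`.
* **Translocation**: no copy-number correction is derivable from split
  reads alone, so the inversion formula is used and flagged as an
  assumption.

`A = B = 0` yields a missing estimate with a warning — never a silent 0 or
1. Worked examples: `(DEL, A=16, B=2)`, `(DUP, A=20, B=2)` and
`(INV, A=16, B=4)` all give exactly 20%; `(DEL, A=5400, B=1114)` gives
29.21%. `H` assumes intra-cellular homozygosity: 50% can mean all cells
heterozygous or half the cells homozygous. For a deletion, `R = A/2`
averages the spanning reads at the two junction positions; it does not
attempt to exclude reads that span *inside* the deleted interval, which is
exactly what the averaging form implies.

# The simulator and what passing tests show

`simulate_dataset` reproduces the evaluation protocol the method was
designed under: a uniform-random (hence non-repetitive) reference of
70 kb by default, SV segments of 150 bp / 1 kb / 30 kb, 75 bp error-free
paired-end reads at phred 40, fragment lengths drawn by rejection from
N(250, 20²) truncated to [175, 325] (inclusive), fragment positions
uniform over the source haplotype, and each fragment's haplotype drawn
Bernoulli(`variant_fraction`). Coverage is defined over the *reference*
length — the fragment count is `floor(coverage · L / (2 · read_length))` —
and counts both haplotypes jointly, matching the "overall average
coverage" convention; benchmark comparisons should state this, because a
30 kb deletion shortens the variant haplotype enough to shift local depth
visibly. `pick_sv_anchors` places segments so that no junction carries
one-base microhomology, making truth breakpoints unambiguous; real
junctions are frequently ambiguous by a few bases, which is what
`clip_tolerance` is for.

Truth alignments come in two dialects. *Oracle*: every read at its true
position, junction reads soft-clipped exactly at the junction, anchored on
the longer plus-strand portion (junction reads whose longer portion lies
*inside* an inverted segment anchor on the minus strand; their clip
boundaries land at scattered positions and are invisible to clustering —
the detectable inversion signal is carried by reads anchored outside the
segment, which is why `min_plus_anchor` = 20 bp prefers them). *Naive*:
junction reads with overhang ≤ `margin` (5 bp) are forced end-to-end with
mismatches, all others are left unmapped — the two failure modes the
refinement loop exists to repair, in their pure form.

What the simulator deliberately omits: sequencing errors and quality
variation, GC and positional bias, chimeric fragments, SNPs/small indels,
more than two haplotypes, and repetitive reference sequence. Passing
tests therefore demonstrate the *algorithmic* behaviour of clustering,
matching, refinement and estimation under clean conditions — not
robustness to noisy real libraries, where clip consensus quality,
`min_clip_len` and the seed length all start to matter.

In benchmark tables (`benchmark_grid`), heterogeneity error is measured
against the *realized* fraction of breakpoint-local reads from the variant
haplotype (`true_breakpoint_fraction`: variant reads crossing the SV's
variant-coordinate junction(s) versus reference reads crossing the
reference breakpoints, computed from the truth tables), not the configured
mixing fraction — with fragment counts fixed by reference-length coverage,
a large deletion or duplication changes local depth and the configured
fraction is simply not the quantity the estimator sees. Residual error at
high coverage (~2 points for deletions at a 60% mixture) reflects the
small asymmetry between the clipped-read window (any overhang ≥ 1 bp) and
the anchored spanning window (anchor = 5 bp); the duplication estimator is
noisier still because of its subtraction heuristic — both behaviours are
properties of the estimators, not of the implementation.

Problem sizes in the test suite are chosen to exercise the full study
conditions where it matters (70 kb reference, 100× naive-mode refinement
over three seeds; heterogeneity recovery at 20×/100×/500× over ten seeds)
and small references (4–15 kb) for module-level behaviour.

# Degenerate inputs and numerical choices

* Empty alignments converge immediately with an empty SV report.
* Unsorted alignments are rejected with instructions to sort.
* SV specifications that overlap or leave the reference interior are
  rejected naming the offending SV; so are overlapping selections in an
  edit plan.
* Fragments longer than their source haplotype are resampled within
  bounds; a reference shorter than `fragment_max` is a validation error.
* The coordinate map after `apply_edits` marks deleted positions `NA`,
  maps duplicated positions to the first copy, and maps inverted segments
  block-wise (each position keeps its offset within the segment), keeping
  the map monotone over non-deleted positions; a per-base mirror map would
  be non-monotone and no more useful for lifting annotations.
* All randomness flows through a single integer seed per simulation;
  identical configurations give byte-identical outputs.

# Limitations

Split-read evidence only: no read-pair, read-depth or assembly evidence,
so novel insertions are out of reach by construction. Inversion detection
relies on plus-strand-anchored junction reads; minus-strand-anchored
realignment is attempted only as a fallback for unmapped reads.
Translocations are reported with an assumed formula and never applied to a
personal genome. One personal sequence per run — no phasing of variants
into multiple haplotypes. No confidence intervals on `H`; its sampling
noise shrinks with coverage but is never zero, and on targeted
(bait-captured) data `H` is biased low because divergent fragments are
captured less efficiently. These match the method's own stated boundaries
and are the natural next steps.
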