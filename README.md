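# clipsv

Split-read structural variant (SV) detection with soft-clip refinement,
per-variant heterogeneity estimation, and personal genome construction —
aimed at heterogeneous samples such as tumor sequencing data, where an SV
may be carried by only a subpopulation of the cells and standard
assembly-based approaches miss it.

## What it does

Reads sampled across an SV junction align to the reference only partially;
a local aligner marks the overhanging bases as *soft clips*. `clipsv`
exploits this signal end to end:

1. **Detection** (`detect_svs`): soft-clip boundaries are clustered per
   reference position and side; each cluster's consensus clipped sequence
   is locally aligned against candidate partner clusters. A reciprocal
   match types the event — forward-strand match downstream = deletion
   (DEL), forward-strand match back to the segment start = tandem
   duplication (DUP), reverse-complement match = inversion (INV),
   cross-chromosome reciprocal match = translocation (TRA, reported
   only) — and fixes both breakpoints at base-pair resolution.
2. **Refinement** (`run_refinement`): global aligners hide junction reads
   in two ways — a read with a small overhang is forced end-to-end with
   mismatches, and a read with a large overhang may stay unmapped. The
   loop extracts breakpoint-neighborhood and unmapped reads from the
   original alignment, realigns them individually with a Smith–Waterman
   local aligner that soft-clips unaligned ends, and re-detects, until the
   SV set is stable (rarely more than 2–3 passes). Derivative calls — weak
   near-duplicates of a strong call a few bp off at one breakpoint — are
   then filtered.
3. **Heterogeneity** (`estimate_sv_heterogeneity`): with `A` the number of
   reads spanning either breakpoint and `B` the number soft-clipped at
   either breakpoint, the estimated variant depth is `V = B` and the
   reference depth `R` depends on the type:

   | type | estimator            | rationale |
   |------|----------------------|-----------|
   | DEL  | `H = B / (B + A/2)`  | two reference breakpoints collapse onto one variant junction, so spanning reads are averaged (`R = A/2`) |
   | DUP  | `H = B / (A/2)`      | the repeat's outer edges carry spanning reads from *both* populations, so `R = A/2 − B` |
   | INV  | `H = B / (A + B)`    | no copy-number change; clipped vs spanning totals compare directly |

   `H = V / (V + R)` in all cases, clamped to [0, 1]. Note `H` assumes
   intra-cellular homozygosity: `H = 50%` can equally mean 100% of cells
   heterozygous or 50% of cells homozygous for the variant.
4. **Personal genome** (`build_personal_genome`): a selected,
   non-overlapping set of intra-chromosomal SVs (threshold on `H`, or an
   explicit list) is applied to the reference — deletions excised,
   duplications doubled in tandem, inversions reverse-complemented — with
   a reference-to-personal coordinate map.

A bundled simulator (`simulate_dataset`) generates the study conditions
offline: error-free 75 bp paired-end reads (phred 40), truncated-normal
fragment sizes (mean 250 bp, sd 20, bounds [175, 325]), a configurable
fraction of fragments from the variant haplotype, and truth alignments in
an `oracle` dialect (perfect clipping) or a `naive` dialect that reproduces
both global-aligner failure modes.

## Worked example

```r
library(clipsv)

reference <- random_reference(20000, seed = 11)
spec <- pick_sv_anchors(reference, c("DEL", "DUP"), c(600, 400),
                        edge_margin = 2000)
ds <- simulate_dataset(reference, spec, coverage = 80,
                       variant_fraction = 0.4, seed = 11, mode = "naive")
res <- run_pipeline(ds$alignment, reference)
res$svs[c("sv_id", "sv_type", "bp1", "bp2", "A", "B", "het_percent")]
```

```
  sv_id sv_type   bp1   bp2   A  B het_percent
1   sv1     DEL  7003  7603  91 39       46.15
2   sv2     DUP 12605 13005 141 26       36.88
```

Both SVs are recovered at their exact simulated breakpoints (`bp1` is the
last reference base before each junction). At the deletion, 91 reads span
a breakpoint and 39 are soft-clipped there, giving an estimated 46.15%
of the sample carrying the deletion; the realized variant fractions at
these loci were 42.6% and 32.5% (the duplication estimator is the noisier
of the two — its `R = A/2 − B` subtraction amplifies sampling
fluctuations). The refinement loop converged in 2 iterations.

The same pipeline is scriptable from a shell via `exec/clipsv`
(subcommands `simulate`, `run`, `estimate`, `build-genome`, `benchmark`).

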