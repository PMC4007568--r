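# Benchmark harness: rerun the simulation grid (SV type x heterogeneity
# fraction x coverage x seed) and tabulate detection counts and
# heterogeneity-estimation error, at desk scale by default.

#' Realized variant fraction at an SV's breakpoints
#'
#' The truth an estimator should be compared against is the fraction of
#' breakpoint-local reads that actually came from the variant haplotype in
#' this sample, not the configured mixing fraction: fragment counts are
#' fixed by reference-length coverage, so haplotype length changes (a large
#' deletion or duplication) shift local depth away from the configured
#' fraction. Computed from the truth tables as
#' `v / (v + r)` where `v` is the (junction-averaged) count of
#' variant-haplotype reads crossing the SV's variant-coordinate junction(s)
#' and `r` the (breakpoint-averaged) count of reference-haplotype reads
#' crossing the reference breakpoints.
#'
#' @param dataset output of [simulate_dataset()].
#' @param sv_row row index into `dataset$variant$svs`.
#' @return fraction in `[0, 1]` (NaN when no reads touch the breakpoints).
#' @export
true_breakpoint_fraction <- function(dataset, sv_row) {
  sv <- dataset$variant$svs[sv_row, ]
  rd <- dataset$reads
  crossing <- function(hap, at) {
    sum(rd$haplotype == hap & rd$a <= at & rd$b >= at + 1L)
  }
  vj <- c(sv$vjunc1, sv$vjunc2)
  vj <- vj[!is.na(vj)]
  # DEL and DUP have a single variant junction (mean == count); INV has two
  v <- mean(vapply(vj, function(x) crossing("variant", x), numeric(1)))
  r <- mean(vapply(c(sv$bp1, sv$bp2), function(x) crossing("reference", x),
                   numeric(1)))
  v / (v + r)
}

#' Run one simulation grid cell
#'
#' Simulates three SVs of one type at the configured sizes, runs detection
#' (oracle-mode alignment) or the full refinement loop (naive mode), and
#' reports per-SV detection status and heterogeneity error against the
#' realized breakpoint fraction.
#'
#' @param sv_type `"DEL"`, `"DUP"` or `"INV"`.
#' @param sv_sizes segment sizes in bp.
#' @param coverage fold coverage.
#' @param fraction configured variant fraction.
#' @param seed simulation seed (also seeds the per-seed reference).
#' @param reference_length reference size in bp.
#' @param mode `"oracle"` (detection on truth clipping) or `"naive"` (full
#'   refinement from a global-aligner-style alignment).
#' @param config a [run_config()].
#' @param bp_tol bp tolerance when matching a call to truth.
#' @return data.frame, one row per simulated SV: `sv_type`, `size`,
#'   `coverage`, `fraction`, `seed`, `detected`, `het_percent`, `true_pct`,
#'   `abs_err`.
#' @export
benchmark_cell <- function(sv_type, sv_sizes = c(150L, 1000L, 30000L),
                           coverage = 100, fraction = 0.6, seed = 1L,
                           reference_length = 70000L,
                           mode = c("oracle", "naive"),
                           config = run_config(), bp_tol = 0L) {
  mode <- match.arg(mode)
  reference <- random_reference(reference_length, seed = seed)
  spec <- pick_sv_anchors(reference, rep(sv_type, length(sv_sizes)), sv_sizes)
  ds <- simulate_dataset(reference, spec, coverage = coverage,
                         variant_fraction = fraction, seed = seed,
                         mode = mode)
  if (mode == "oracle") {
    aln <- ds$alignment
    svs <- detect_svs(aln, reference, config)
  } else {
    rf <- run_refinement(ds$alignment, reference, config)
    aln <- rf$alignment
    svs <- rf$svs[rf$svs$status != "filtered", , drop = FALSE]
  }
  truth <- ds$variant$svs
  out <- truth[c("sv_type", "bp1", "bp2", "length")]
  names(out)[4] <- "size"
  out$coverage <- coverage
  out$fraction <- fraction
  out$seed <- seed
  out$detected <- FALSE
  out$het_percent <- NA_real_
  out$true_pct <- NA_real_
  for (i in seq_len(nrow(truth))) {
    hit <- which(svs$sv_type == truth$sv_type[i] &
                   abs(svs$bp1 - truth$bp1[i]) <= bp_tol &
                   abs(svs$bp2 - truth$bp2[i]) <= bp_tol)
    out$detected[i] <- length(hit) > 0
    est <- estimate_sv_heterogeneity(aln, truth[i, , drop = FALSE] |>
                                       normalize_sv_table(), config)
    out$het_percent[i] <- est$het_percent
    out$true_pct[i] <- 100 * true_breakpoint_fraction(ds, i)
  }
  out$abs_err <- abs(out$het_percent - out$true_pct)
  rownames(out) <- NULL
  out
}

#' Run a simulation benchmark grid
#'
#' Desk-scale by default. Returns the raw per-SV rows plus two aggregate
#' tables: detection counts per (type, fraction, coverage) and mean
#' absolute heterogeneity error per (type, size, coverage), the latter
#' averaged over detected SVs only.
#'
#' @param sv_types,fractions,coverages,seeds grid axes.
#' @param sv_sizes SV sizes simulated together in each cell.
#' @param ... forwarded to [benchmark_cell()].
#' @return list with `per_sv`, `detection`, `het_error`.
#' @export
benchmark_grid <- function(sv_types = c("DEL", "DUP"), fractions = 0.6,
                           coverages = c(20, 100), seeds = 1:3,
                           sv_sizes = c(150L, 1000L, 30000L), ...) {
  rows <- list()
  for (ty in sv_types) for (f in fractions) for (cv in coverages) for (sd in seeds) {
    rows[[length(rows) + 1L]] <- benchmark_cell(ty, sv_sizes = sv_sizes,
                                                coverage = cv, fraction = f,
                                                seed = sd, ...)
  }
  per_sv <- do.call(rbind, rows)
  detection <- aggregate(cbind(detected = per_sv$detected),
                         by = list(sv_type = per_sv$sv_type,
                                   fraction = per_sv$fraction,
                                   coverage = per_sv$coverage),
                         FUN = sum)
  detection$total <- aggregate(rep(1L, nrow(per_sv)),
                               by = list(per_sv$sv_type, per_sv$fraction,
                                         per_sv$coverage), FUN = sum)$x
  det_sv <- per_sv[per_sv$detected & !is.na(per_sv$abs_err), , drop = FALSE]
  het_error <- if (nrow(det_sv)) {
    aggregate(cbind(mean_abs_err = det_sv$abs_err),
              by = list(sv_type = det_sv$sv_type, size = det_sv$size,
                        coverage = det_sv$coverage), FUN = mean)
  } else {
    data.frame(sv_type = character(0), size = integer(0),
               coverage = numeric(0), mean_abs_err = numeric(0))
  }
  list(per_sv = per_sv, detection = detection, het_error = het_error)
}
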