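# Full pipeline composition: refinement -> heterogeneity -> optional
# personal genome, with on-disk outputs and a resolved-configuration file
# so a run can be reproduced exactly.

#' Run the full SV detection and heterogeneity pipeline
#'
#' Composes [run_refinement()], [estimate_sv_heterogeneity()] and
#' optionally [build_personal_genome()]. When `out_prefix` is given, writes
#' `<prefix>.svs.tsv` (SV report with heterogeneity columns),
#' `<prefix>.final.sam` (refined alignment), `<prefix>.config` (resolved
#' configuration) and, if requested, `<prefix>.personal.fa` plus
#' `<prefix>.coordmap.tsv`.
#'
#' @param alignment a `read_alignment` or a SAM/BAM path.
#' @param reference named character vector or a FASTA path.
#' @param config a [run_config()].
#' @param out_prefix optional output path prefix.
#' @param build_genome also emit the personal genome (threshold mode at
#'   `config$h_min`).
#' @return list with `svs`, `alignment`, `history`, `iterations`,
#'   `converged`, and `genome` (NULL unless built).
#' @export
run_pipeline <- function(alignment, reference, config = run_config(),
                         out_prefix = NULL, build_genome = FALSE) {
  if (is.character(reference) && length(reference) == 1 &&
      is.null(names(reference))) {
    reference <- read_reference(reference)
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  if (is.character(alignment)) alignment <- read_alignment_file(alignment)
  res <- run_refinement(alignment, reference, config)
  for (i in seq_along(res$history)) {
    message(sprintf("iteration %d: %d SV(s)", i, nrow(res$history[[i]])))
  }
  res$svs <- estimate_sv_heterogeneity(res$alignment, res$svs, config)
  genome <- NULL
  if (!is.null(out_prefix)) {
    write_sv_report(res$svs, paste0(out_prefix, ".svs.tsv"))
    write_alignment_sam(res$alignment, paste0(out_prefix, ".final.sam"))
    write_run_config(config, paste0(out_prefix, ".config"))
    if (length(res$history)) {
      for (i in seq_along(res$history)) {
        write_sv_report(res$history[[i]],
                        sprintf("%s.iter%d.svs.tsv", out_prefix, i))
      }
    }
  }
  if (build_genome) {
    confirmed <- res$svs[res$svs$status == "confirmed", , drop = FALSE]
    if (!is.null(out_prefix)) {
      genome <- build_personal_genome(reference, confirmed,
                                      out_fasta = paste0(out_prefix, ".personal.fa"),
                                      out_map = paste0(out_prefix, ".coordmap.tsv"),
                                      mode = "threshold", h_min = config$h_min)
    } else {
      plan <- select_svs(confirmed, mode = "threshold", h_min = config$h_min)
      genome <- apply_edits(reference, plan)
    }
  }
  c(res, list(genome = genome))
}
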