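# Pipeline configuration: every tunable across the modules, with one
# defaults table so a run can serialise its resolved settings next to its
# outputs and be reproduced from that file alone.

RUN_CONFIG_DEFAULTS <- list(
  # local alignment scoring (BWA-SW-like; a gap of length k costs
  # gap_open + k * gap_extend)
  match = 1,
  mismatch = -3,
  gap_open = -5,
  gap_extend = -2,
  min_score = 25,
  # breakpoint read classification
  anchor = 5L,
  clip_tolerance = 2L,
  # soft-clip clustering
  min_clip_len = 8L,
  merge_window = 2L,
  min_cluster_support = 3L,
  # partner matching
  search_radius = 100000L,
  min_identity = 0.9,
  match_pad = 10L,
  # derivative-SV filter
  main_window = 20L,
  support_ratio = 0.1,
  # refinement loop
  neighborhood = 650L,
  seed_length = 20L,
  max_iterations = 5L,
  # personal genome selection
  h_min = 0.5
)

#' Pipeline configuration
#'
#' Returns the full set of tunables with defaults, overridden by any named
#' arguments. `anchor` and `clip_tolerance` are in bp around a breakpoint;
#' `neighborhood` (bp) is the half-width of the window extracted around each
#' breakpoint, sized to two maximum fragment lengths under the default
#' simulation so junction reads and their mates are captured; `seed_length`
#' is the exact-match seed used when realigning unmapped reads against the
#' whole reference.
#'
#' @param ... named overrides of entries in the defaults table; unknown
#'   names are rejected.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(over), names(RUN_CONFIG_DEFAULTS))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
  }
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, over)
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("configuration values must be numeric")
  if (cfg$min_identity <= 0 || cfg$min_identity > 1) {
    stop("min_identity must be in (0, 1]")
  }
  structure(cfg, class = "run_config")
}

#' Write a configuration as a flat key=value file
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, format, character(1), digits = 15)), path)
  invisible(path)
}

#' Read a configuration written by [write_run_config()]
#'
#' Unknown keys are rejected so a stale or mistyped file cannot silently
#' change a run.
#'
#' @param path key=value file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed configuration line(s) in ", path)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2)))
  args <- as.list(vals)
  names(args) <- keys
  int_keys <- names(RUN_CONFIG_DEFAULTS)[vapply(RUN_CONFIG_DEFAULTS, is.integer, logical(1))]
  args[names(args) %in% int_keys] <- lapply(args[names(args) %in% int_keys], as.integer)
  do.call(run_config, args)
}

scoring_of <- function(config) {
  config[c("match", "mismatch", "gap_open", "gap_extend", "min_score")]
}
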