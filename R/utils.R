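#' Reverse-complement character sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors as the working currency of the pipeline.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random synthetic reference sequence
#'
#' Uniform i.i.d. bases, which makes the sequence non-repetitive with high
#' probability: 20-mers are unique and SV junctions have no long
#' microhomology, mirroring the non-repetitive region the simulation
#' protocol calls for.
#'
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @param chrom sequence name.
#' @return named character vector of length 1.
#' @export
random_reference <- function(length, seed = 1L, chrom = "chrSim") {
  stopifnot(length >= 1)
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  setNames(seq, chrom)
}

#' Read a reference FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_reference <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

# substring over one long string, vectorised over starts/ends
seq_extract <- function(seq, start, end) {
  substring(seq, start, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
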