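#' Generate a synthetic reference genome
#'
#' Draws an i.i.d. nucleotide sequence per chromosome at the configured GC
#' fraction (default 0.44, within the 43-48% read-based range observed for
#' the parental panel). Deterministic for a fixed configuration seed.
#'
#' @param config A [simulation_config()].
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lens <- config$chromosome_lengths
  if (any(lens <= 0)) {
    stop_kaspanel("zero-length chromosome requested", "kaspanel_config_error")
  }
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  seqs <- with_sub_seed(config$seed, "reference", {
    lapply(lens, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    })
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Write / read a reference genome as FASTA
#'
#' Thin wrappers over Biostrings kept for a uniform dataset interface.
#'
#' @param reference A `DNAStringSet`.
#' @param path FASTA path.
#' @return `read_reference()` returns a `DNAStringSet`; `write_reference()`
#'   returns `path` invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  Biostrings::readDNAStringSet(path)
}

reference_base <- function(reference, chromosome, position_bp) {
  as.character(Biostrings::subseq(reference[[chromosome]],
                                  start = position_bp, end = position_bp))
}
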