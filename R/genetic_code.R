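#' The standard genetic code
#'
#' Codon table 1 (standard nuclear code), built programmatically from the
#' classic degeneracy blocks rather than copied from a dependency so that
#' tests can use an external code table as an independent oracle.
#'
#' @return named character vector of length 64 mapping codon to one-letter
#'   amino acid, with `"*"` for stop codons.
#' @export
standard_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(
    rep(bases, each = 16L),
    rep(rep(bases, each = 4L), times = 4L),
    rep(bases, times = 16L)
  )
  # amino acids in TCAG-major codon order (TTT, TTC, TTA, TTG, TCT, ...)
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  setNames(aa, codons)
}

.codon_table <- NULL

codon_table <- function() {
  if (is.null(.codon_table)) {
    utils::assignInMyNamespace(".codon_table", standard_genetic_code())
  }
  .codon_table
}

#' Translate a single codon
#'
#' @param codon character vector of 3-base codons over `{A,C,G,T}`.
#' @return one-letter amino acid per codon (`"*"` for stop).
#' @examples
#' translate_codon(c("ACT", "CCT")) # T, P
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("not an unambiguous A/C/G/T codon: ", codon[which(bad)[1]])
  }
  unname(codon_table()[codon])
}

#' Translate a coding sequence
#'
#' @param cds in-frame coding sequence (length divisible by 3).
#' @return one-letter amino acid string, stops as `"*"`.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " not divisible by 3")
  }
  n <- nchar(cds) %/% 3L
  starts <- 3L * seq_len(n) - 2L
  paste(translate_codon(substring(cds, starts, starts + 2L)), collapse = "")
}
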