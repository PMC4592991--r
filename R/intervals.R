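#' Genomic interval helpers and coordinate-convention converters
#'
#' All internal coordinates follow the Bioconductor convention: 1-based,
#' closed intervals, carried in [GenomicRanges::GRanges] objects. The
#' functions below are the *only* places where other conventions appear:
#' VCF and GFF3 positions are already 1-based (identity mapping), BED is
#' 0-based half-open (start shifted by one on the way in, back on the way
#' out).
#'
#' @param chrom,start,end,strand interval components; `start`/`end` are
#'   1-based closed; `strand` one of `"+"`, `"-"`, `"*"`.
#' @return `genomic_interval()` returns a length-one `GRanges`.
#' @examples
#' genomic_interval("chr1", 117000001, 118200000)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (any(end < start)) {
    stop("invalid interval: end < start (", chrom, ":", start, "-", end, ")")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

#' Convert between BED (0-based half-open) and internal coordinates
#'
#' @param start0 0-based half-open start (BED).
#' @param pos1 1-based position (internal / VCF / GFF3).
#' @return the converted coordinate.
#' @export
bed_to_internal_start <- function(start0) start0 + 1L

#' @rdname bed_to_internal_start
#' @export
internal_to_bed_start <- function(pos1) pos1 - 1L

#' @rdname bed_to_internal_start
#' @export
vcf_to_internal_pos <- function(pos1) as.integer(pos1)

#' @rdname bed_to_internal_start
#' @export
internal_to_vcf_pos <- function(pos1) as.integer(pos1)

#' Fetch sequence for an interval from a reference
#'
#' Out-of-range lookups are an error, never a silent truncation.
#'
#' @param seqs a named [Biostrings::DNAStringSet] (one entry per chromosome).
#' @param gr a `GRanges` of intervals to extract.
#' @return character vector of sequences, one per interval, minus-strand
#'   intervals reverse-complemented.
#' @export
reference_fetch <- function(seqs, gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bad <- !chrom %in% names(seqs)
  if (any(bad)) stop("unknown sequence name: ", chrom[which(bad)[1]])
  len <- Biostrings::width(seqs)[match(chrom, names(seqs))]
  oob <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > len
  if (any(oob)) {
    i <- which(oob)[1]
    stop(
      "interval out of range: ", chrom[i], ":", GenomicRanges::start(gr)[i],
      "-", GenomicRanges::end(gr)[i], " (sequence length ", len[i], ")"
    )
  }
  out <- as.character(Biostrings::subseq(
    seqs[chrom],
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr)
  ))
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  if (any(minus)) out[minus] <- revcomp(out[minus])
  unname(out)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(
    x,
    function(s) {
      chartr(
        "ACGTNacgtn", "TGCANtgcan",
        paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      )
    },
    character(1), USE.NAMES = FALSE
  )
}
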