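#' Spliced coding sequence of a transcript model
#'
#' CDS intervals are concatenated in transcription order; minus-strand
#' models are reverse-complemented so the result always reads 5'->3' on
#' the coding strand.
#'
#' @param model a [transcript_model()].
#' @param seqs reference [Biostrings::DNAStringSet].
#' @return character CDS sequence.
#' @export
spliced_cds <- function(model, seqs) {
  if (!length(model$cds)) stop("transcript ", model$tx_id, " has no CDS")
  pieces <- reference_fetch(
    seqs, genomic_interval(model$chrom, GenomicRanges::start(model$cds),
                           GenomicRanges::end(model$cds))
  )
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds) else cds
}

#' Map a coding SNP to its codon
#'
#' Computes the CDS offset of the variant by concatenating CDS intervals
#' in transcription order, assembles the reference and alternate codon
#' (variants at spliced codons are handled through the spliced CDS, never
#' a genomic run), translates both and classifies the substitution.
#'
#' @param variant one-row data.frame (or list) with `chrom`, `pos`,
#'   `ref`, `alt` in genomic coordinates.
#' @param model a scorable [transcript_model()] whose CDS contains the
#'   variant.
#' @param seqs reference [Biostrings::DNAStringSet].
#' @return a one-row data.frame (class keeps plain): `gene_id`, `tx_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `ref_codon`, `alt_codon`, `codon_pos`,
#'   `ref_aa`, `alt_aa`, `residue_index`, `status`.
#' @export
map_to_codon <- function(variant, model, seqs) {
  if (!model$scorable) {
    stop("transcript ", model$tx_id,
         " is non-scorable (CDS length not divisible by 3)")
  }
  pos <- as.integer(variant$pos)
  s <- GenomicRanges::start(model$cds)
  e <- GenomicRanges::end(model$cds)
  inside <- which(pos >= s & pos <= e)
  if (length(inside) != 1L) {
    stop("variant ", variant$chrom, ":", pos, " not in CDS of ", model$tx_id)
  }
  genomic_base <- reference_fetch(
    seqs, genomic_interval(variant$chrom, pos, pos)
  )
  if (genomic_base != variant$ref) {
    stop("REF allele mismatch vs reference at ", variant$chrom, ":", pos,
         " (variant ", variant$ref, ", genome ", genomic_base, ")")
  }
  if (model$strand == "-") {
    offset <- sum(e[seq_along(e) > inside] - s[seq_along(s) > inside] + 1L) +
      (e[inside] - pos)
    ref_base <- revcomp(variant$ref)
    alt_base <- revcomp(variant$alt)
  } else {
    offset <- sum(e[seq_along(e) < inside] - s[seq_along(s) < inside] + 1L) +
      (pos - s[inside])
    ref_base <- variant$ref
    alt_base <- variant$alt
  }
  cds <- spliced_cds(model, seqs)
  codon_idx <- offset %/% 3L
  codon_pos <- offset %% 3L + 1L
  ref_codon <- substr(cds, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  if (substr(ref_codon, codon_pos, codon_pos) != ref_base) {
    stop("internal codon assembly error at ", variant$chrom, ":", pos)
  }
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_base
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  data.frame(
    gene_id = model$gene_id, tx_id = model$tx_id,
    chrom = variant$chrom, pos = pos,
    ref = variant$ref, alt = variant$alt,
    ref_codon = ref_codon, alt_codon = alt_codon,
    codon_pos = codon_pos, ref_aa = ref_aa, alt_aa = alt_aa,
    residue_index = codon_idx + 1L,
    status = classify_substitution(ref_aa, alt_aa, codon_idx + 1L),
    stringsAsFactors = FALSE
  )
}

#' Classify an amino-acid substitution
#'
#' @param ref_aa,alt_aa one-letter amino acids (`"*"` = stop).
#' @param residue_index 1-based residue position (start-loss detection).
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`,
#'   `"start-loss"`.
#' @export
classify_substitution <- function(ref_aa, alt_aa, residue_index = NA_integer_) {
  stopifnot(length(ref_aa) == length(alt_aa))
  out <- character(length(ref_aa))
  out[ref_aa == alt_aa] <- "synonymous"
  out[ref_aa != alt_aa] <- "nonsynonymous"
  out[ref_aa != alt_aa & alt_aa == "*"] <- "nonsense"
  start_loss <- !is.na(residue_index) & residue_index == 1L &
    ref_aa == "M" & alt_aa != "M" & alt_aa != "*"
  out[start_loss] <- "start-loss"
  out
}

#' Codon-level effects for all coding variants in a call set
#'
#' Maps every variant lying in the CDS of a primary transcript to its
#' codon. One transcript per gene is used (see [primary_transcripts()]).
#'
#' @param variants data.frame with `id`, `chrom`, `pos`, `ref`, `alt`
#'   (e.g. [call_consensus()] output).
#' @param models list of [transcript_model()]s (all isoforms; reduced
#'   internally).
#' @param seqs reference [Biostrings::DNAStringSet].
#' @return data.frame of substitution effects (one row per variant x
#'   gene), with the variant `id` carried through.
#' @export
coding_effects <- function(variants, models, seqs) {
  prim <- primary_transcripts(models)
  rows <- list()
  for (m in prim) {
    if (!length(m$cds) || !m$scorable) next
    ov <- GenomicRanges::findOverlaps(
      genomic_interval(variants$chrom, variants$pos, variants$pos),
      GenomicRanges::granges(m$cds), ignore.strand = TRUE
    )
    for (qi in unique(queryHits(ov))) {
      eff <- map_to_codon(variants[qi, , drop = FALSE], m, seqs)
      eff$id <- variants$id[qi]
      rows[[length(rows) + 1L]] <- eff
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      gene_id = character(), tx_id = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      ref_codon = character(), alt_codon = character(),
      codon_pos = integer(), ref_aa = character(), alt_aa = character(),
      residue_index = integer(), status = character(), id = character(),
      stringsAsFactors = FALSE
    )
  }
  out <- out[order(out$chrom, out$pos, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
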