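# independent brute-force oracles used across tests

# consensus oracle: direct per-variant check of the rule's definition
consensus_oracle <- function(geno_row, manifest, presence_min, absence_max,
                             carrier_rule = "any-alt") {
  carrier <- if (carrier_rule == "any-alt") {
    !is.na(geno_row) & geno_row >= 1L
  } else {
    !is.na(geno_row) & geno_row == 2L
  }
  for (g in c("QQ", "qq")) {
    own <- manifest$sample[manifest$group == g]
    oth <- manifest$sample[manifest$group != g]
    if (sum(carrier[own]) >= presence_min && sum(carrier[oth]) <= absence_max) {
      return(g)
    }
  }
  NA_character_
}

# CpG oracle: enumerate every window of exactly `min_length` bases, keep
# qualifiers, merge into maximal runs (no prefix sums, no shared code)
cpg_oracle <- function(seq, min_length = 200L, min_gc = 0.5, min_oe = 0.6) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < min_length) return(matrix(integer(0), ncol = 2))
  covered <- logical(n)
  for (i in seq_len(n - min_length + 1L)) {
    w <- b[i:(i + min_length - 1L)]
    if (any(!w %in% c("A", "C", "G", "T"))) next
    nc <- sum(w == "C"); ng <- sum(w == "G")
    ncg <- sum(w[-min_length] == "C" & w[-1] == "G")
    gc <- (nc + ng) / min_length
    oe <- if (nc * ng > 0) ncg * min_length / (nc * ng) else 0
    if (gc >= min_gc && oe >= min_oe) covered[i:(i + min_length - 1L)] <- TRUE
  }
  r <- rle(covered)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  cbind(start = s[r$values], end = e[r$values])
}

# Table-1-shaped fabricated calls + annotations with given qq cell counts
fabricate_category_inputs <- function(counts) {
  # counts: named vector nsSNP/UTR/splice/CpG/promoter per group list
  calls <- list(); anns <- list(); effs <- list()
  pos <- 0L
  for (g in names(counts)) {
    for (cat in names(counts[[g]])) {
      for (k in seq_len(counts[[g]][[cat]])) {
        pos <- pos + 10L
        id <- paste0("chr1:", pos, "_A>C")
        calls[[length(calls) + 1L]] <- data.frame(
          id = id, chrom = "chr1", pos = pos, ref = "A", alt = "C",
          group = g, carriers = 5L, group_size = 5L, carriers_other = 0L,
          stringsAsFactors = FALSE
        )
        ann_cat <- switch(cat, nsSNP = "CDS", UTR = "UTR5", cat)
        anns[[length(anns) + 1L]] <- data.frame(
          id = id, chrom = "chr1", pos = pos, gene_id = "geneX",
          category = ann_cat, stringsAsFactors = FALSE
        )
        if (cat == "nsSNP") {
          effs[[length(effs) + 1L]] <- data.frame(
            gene_id = "geneX", tx_id = "geneX.t1", chrom = "chr1",
            pos = pos, ref = "A", alt = "C", ref_codon = "ACT",
            alt_codon = "CCT", codon_pos = 1L, ref_aa = "T", alt_aa = "P",
            residue_index = 10L, status = "nonsynonymous", id = id,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(
    calls = do.call(rbind, calls),
    annotations = do.call(rbind, anns),
    effects = if (length(effs)) do.call(rbind, effs) else NULL
  )
}
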