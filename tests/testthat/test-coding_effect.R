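test_that("codon translation follows the standard code", {
  expect_equal(translate_codon(c("ACT", "CCT")), c("T", "P"))
  expect_equal(translate_codon(c("GGT", "AGT")), c("G", "S"))
  expect_equal(translate_codon(c("TTT", "ATT")), c("F", "I"))
  expect_equal(translate_codon(c("GCA", "GGA")), c("A", "G"))
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_error(translate_codon("ANT"), "unambiguous")
  expect_error(translate_codon("AC"), "unambiguous")
})

test_that("classification matches an exhaustive oracle over all 576 mutations", {
  # oracle built on an external code table (Biostrings), not the package's
  oracle_code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  got <- character(0)
  expected <- character(0)
  for (cod in names(oracle_code)) {
    if (oracle_code[[cod]] == "*") next # stop reference codons not scored
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        got <- c(got, classify_substitution(translate_codon(cod),
                                            translate_codon(alt)))
        ref_aa <- oracle_code[[cod]]
        alt_aa <- oracle_code[[alt]]
        expected <- c(expected,
                      if (alt_aa == "*") "nonsense"
                      else if (ref_aa == alt_aa) "synonymous"
                      else "nonsynonymous")
      }
    }
  }
  expect_equal(got, expected)
})

test_that("status semantics: synonymous, nonsense, start-loss", {
  expect_equal(classify_substitution("T", "P"), "nonsynonymous")
  expect_equal(classify_substitution("L", "L"), "synonymous")
  expect_equal(classify_substitution("R", "*"), "nonsense")
  expect_equal(classify_substitution("M", "V", residue_index = 1L),
               "start-loss")
  expect_equal(classify_substitution("M", "V", residue_index = 7L),
               "nonsynonymous")
})

# tiny single-exon gene: ATG + 5 codons + stop on a 100-base contig
tiny_world <- function(strand = "+") {
  cds_seq <- "ATGACTGGTTTTGCACTTTAA" # M T G F A L *
  pad5 <- strrep("A", 30)
  pad3 <- strrep("T", 49)
  fwd <- paste0(pad5, cds_seq, pad3)
  seq <- if (strand == "-") revcomp(fwd) else fwd
  # CDS occupies 31..51 on the forward layout; mirror for minus
  if (strand == "-") {
    s <- nchar(fwd) - 51 + 1
    e <- nchar(fwd) - 31 + 1
  } else {
    s <- 31; e <- 51
  }
  model <- transcript_model(
    gene_id = "g", tx_id = "g.t1",
    exons = genomic_interval("chrT", s - 10, e + 10, strand),
    cds = genomic_interval("chrT", s, e, strand)
  )
  seqs <- Biostrings::DNAStringSet(setNames(seq, "chrT"))
  list(model = model, seqs = seqs, cds_start = s, cds_end = e)
}

test_that("map_to_codon: first CDS base, residue arithmetic", {
  w <- tiny_world("+")
  v <- data.frame(chrom = "chrT", pos = w$cds_start, ref = "A", alt = "G")
  eff <- map_to_codon(v, w$model, w$seqs)
  expect_equal(eff$residue_index, 1L)
  expect_equal(eff$codon_pos, 1L)
  expect_equal(eff$ref_codon, "ATG")
  expect_equal(eff$status, "start-loss") # ATG -> GTG = M1V
})

test_that("CDS offset 534 lands on residue 179", {
  sim <- small_sim()
  prim <- primary_transcripts(sim$models)
  long <- Filter(function(m) sum(width(m$cds)) >= 537, prim)[[1]]
  pos <- cds_offset_to_genomic(long, 534L)
  ref <- reference_fetch(sim$seqs, genomic_interval(long$chrom, pos, pos))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  eff <- map_to_codon(
    data.frame(chrom = long$chrom, pos = pos, ref = ref, alt = alt),
    long, sim$seqs
  )
  expect_equal(eff$residue_index, 179L) # floor(534/3) + 1
  expect_equal(eff$codon_pos, 1L)       # 534 %% 3 == 0
})

test_that("strand invariance: mirrored gene gives the identical effect", {
  plus <- tiny_world("+")
  minus <- tiny_world("-")
  # mutate codon 2 position 1 (A of ACT): T>P as in the classic example
  pos_p <- plus$cds_start + 3L
  v_p <- data.frame(chrom = "chrT", pos = pos_p, ref = "A", alt = "C")
  # same coding-strand base sits mirrored on the minus world
  pos_m <- nchar(as.character(minus$seqs[[1]])) - pos_p + 1L
  v_m <- data.frame(chrom = "chrT", pos = pos_m, ref = "T", alt = "G")
  e_p <- map_to_codon(v_p, plus$model, plus$seqs)
  e_m <- map_to_codon(v_m, minus$model, minus$seqs)
  for (f in c("ref_codon", "alt_codon", "codon_pos", "ref_aa", "alt_aa",
              "residue_index", "status")) {
    expect_equal(e_p[[f]], e_m[[f]], info = f)
  }
  expect_equal(e_p$ref_codon, "ACT")
  expect_equal(e_p$alt_codon, "CCT")
  expect_equal(e_p$status, "nonsynonymous")
})

test_that("map_to_codon validates its preconditions", {
  w <- tiny_world("+")
  expect_error(
    map_to_codon(data.frame(chrom = "chrT", pos = 5, ref = "A", alt = "C"),
                 w$model, w$seqs),
    "not in CDS"
  )
  expect_error(
    map_to_codon(data.frame(chrom = "chrT", pos = w$cds_start, ref = "C",
                            alt = "G"), w$model, w$seqs),
    "REF allele mismatch"
  )
  broken <- w$model
  broken$scorable <- FALSE
  expect_error(
    map_to_codon(data.frame(chrom = "chrT", pos = w$cds_start, ref = "A",
                            alt = "G"), broken, w$seqs),
    "non-scorable"
  )
})

test_that("full-CDS retranslation differs exactly at the reported residue", {
  sim <- small_sim()
  prim <- primary_transcripts(sim$models)
  coding <- sim$truth[sim$truth$category %in% c("nsSNP", "synonymous"), ]
  expect_gt(nrow(coding), 0L)
  strands_seen <- character(0)
  for (i in seq_len(nrow(coding))) {
    tr <- coding[i, ]
    model <- prim[[tr$gene_id]]
    strands_seen <- c(strands_seen, model$strand)
    eff <- map_to_codon(tr, model, sim$seqs)
    # oracle: mutate the genome, retranslate the whole CDS
    mutated <- sim$seqs
    stopifnot(as.character(subseq(mutated[[tr$chrom]], tr$pos, tr$pos)) ==
                tr$ref)
    subseq(mutated[[tr$chrom]], tr$pos, tr$pos) <- Biostrings::DNAString(tr$alt)
    prot_ref <- translate_cds(spliced_cds(model, sim$seqs))
    prot_alt <- translate_cds(spliced_cds(model, mutated))
    diff_at <- which(strsplit(prot_ref, "")[[1]] != strsplit(prot_alt, "")[[1]])
    if (eff$status == "synonymous") {
      expect_length(diff_at, 0L)
    } else {
      expect_equal(diff_at, eff$residue_index)
    }
    # and the planted intent is honored
    expect_equal(eff$ref_aa, tr$ref_aa)
    expect_equal(eff$alt_aa, tr$alt_aa)
    expect_equal(eff$residue_index, tr$residue_index)
  }
  expect_setequal(strands_seen, c("+", "-")) # both strands exercised
})

test_that("plant_coding_snp realizes substitutions or fails loudly", {
  sim <- small_sim()
  prim <- primary_transcripts(sim$models)
  plus <- Filter(function(m) m$strand == "+", prim)[[1]]
  minus <- Filter(function(m) m$strand == "-", prim)[[1]]
  set.seed(3)
  for (model in list(plus, minus)) {
    tp <- plant_coding_snp(model, sim$seqs, "T", "P")
    expect_equal(translate_codon(tp$ref_codon), "T")
    expect_equal(translate_codon(tp$alt_codon), "P")
    # codons differ at exactly the codon position
    d <- which(strsplit(tp$ref_codon, "")[[1]] != strsplit(tp$alt_codon, "")[[1]])
    expect_equal(d, tp$codon_pos)
    # genomic ref matches the genome
    expect_equal(
      reference_fetch(sim$seqs, genomic_interval("chr1", tp$pos, tp$pos)),
      tp$ref
    )
    gs <- plant_coding_snp(model, sim$seqs, "G", "S")
    expect_equal(translate_codon(gs$ref_codon), "G")
    expect_equal(translate_codon(gs$alt_codon), "S")
  }
  # M>W needs two base changes (ATG -> TGG): brute-force-verified error
  expect_error(plant_coding_snp(plus, sim$seqs, "M", "W"),
               "not realizable")
})
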