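test_that("sample manifest validates its invariants", {
  m <- sample_manifest(c("a", "b"), c("QQ", "qq"))
  expect_equal(nrow(m), 2L)
  expect_error(sample_manifest(c("a", "a"), c("QQ", "qq")), "duplicated")
  expect_error(sample_manifest(c("a", "b"), c("QQ", "QQ")), "non-empty")
  expect_error(sample_manifest(c("a", "b"), c("QQ", "XX")), "QQ or qq")
})

write_test_vcf <- function(lines, samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines
  ), path)
  path
}

test_that("read_vcf maps genotypes, splits multiallelics, skips indels", {
  samples <- c(paste0("Q", 1:5), paste0("q", 1:5))
  manifest <- sample_manifest(samples, rep(c("QQ", "qq"), each = 5))
  gt <- function(...) paste(c(...), collapse = "\t")
  lines <- c(
    # 5 hom-alt QQ, 5 hom-ref qq
    paste("chr1", 101, ".", "A", "C", ".", "PASS", ".", "GT",
          gt(rep("1/1", 5), rep("0/0", 5)), sep = "\t"),
    # multiallelic SNP -> split in two
    paste("chr1", 205, ".", "G", "A,T", ".", "PASS", ".", "GT",
          gt("1/2", "0/1", "2/2", rep("0/0", 7)), sep = "\t"),
    # indel -> skipped
    paste("chr1", 300, ".", "AT", "A", ".", "PASS", ".", "GT",
          gt(rep("0/1", 10)), sep = "\t"),
    # missing + het handling
    paste("chr1", 404, ".", "T", "G", ".", "PASS", ".", "GT",
          gt("./.", "0/1", rep("0/0", 8)), sep = "\t")
  )
  snps <- suppressMessages(read_vcf(write_test_vcf(lines, samples), manifest))
  expect_s3_class(snps, "snp_set")
  expect_equal(length(snps), 4L) # 1 + 2 (split) + 0 (indel) + 1
  expect_equal(attr(snps, "skipped"), 1L)

  v <- snps$variants
  expect_equal(unname(snps$geno[v$pos == 101L, ]),
               c(rep(2L, 5), rep(0L, 5)))
  # split multiallelic: per-alt doses
  gA <- snps$geno[v$pos == 205L & v$alt == "A", ]
  gT <- snps$geno[v$pos == 205L & v$alt == "T", ]
  expect_equal(unname(gA[1:3]), c(1L, 1L, 0L))
  expect_equal(unname(gT[1:3]), c(1L, 0L, 2L))
  expect_true(is.na(snps$geno[v$pos == 404L, "Q1"]))
  expect_equal(unname(snps$geno[v$pos == 404L, "Q2"]), 1L)
})

test_that("read_vcf validates samples and REF alleles", {
  samples <- c("s1", "s2")
  manifest <- sample_manifest(samples, c("QQ", "qq"))
  path <- write_test_vcf(
    paste("chr1", 3, ".", "A", "C", ".", "PASS", ".", "GT", "1/1\t0/0",
          sep = "\t"),
    samples
  )
  expect_error(
    read_vcf(path, sample_manifest(c("s1", "sX"), c("QQ", "qq"))),
    "unknown sample.*s2"
  )
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGGGG"))
  expect_error(read_vcf(path, manifest, ref_seqs = ref),
               "REF allele mismatch.*chr1:3")
  ref2 <- Biostrings::DNAStringSet(c(chr1 = "GGAGG"))
  expect_equal(length(read_vcf(path, manifest, ref_seqs = ref2)), 1L)
})

test_that("VCF round-trip preserves alleles, positions and genotypes", {
  samples <- sprintf("s%02d", 1:8)
  manifest <- sample_manifest(samples, rep(c("QQ", "qq"), each = 4))
  for (seed in 1:3) {
    set.seed(seed)
    n <- 25L
    pos <- sort(sample.int(5000L, n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    geno <- matrix(sample(c(0:2, NA), n * 8, replace = TRUE), n, 8,
                   dimnames = list(NULL, samples))
    snps <- snp_set(data.frame(chrom = "chr1", pos = pos, ref = ref,
                               alt = alt, stringsAsFactors = FALSE), geno)
    path <- tempfile(fileext = ".vcf")
    write_vcf(snps, path)
    back <- read_vcf(path, manifest)
    expect_equal(back$variants$pos, snps$variants$pos)
    expect_equal(back$variants$ref, snps$variants$ref)
    expect_equal(back$variants$alt, snps$variants$alt)
    expect_equal(back$geno, snps$geno)
  }
})

test_that("coordinate converters are self-inverse", {
  p <- sample.int(2e6, 200)
  expect_equal(internal_to_vcf_pos(vcf_to_internal_pos(p)), p)
  expect_equal(bed_to_internal_start(internal_to_bed_start(p)), p)
})

test_that("gene models derive UTRs strand-awarely from GFF3", {
  gff <- tempfile(fileext = ".gff3")
  make_gff <- function(strand) {
    writeLines(c(
      "##gff-version 3",
      paste("chr1\ttest\tgene\t101\t400\t.", strand, ".\tID=g1", sep = "\t"),
      paste("chr1\ttest\tmRNA\t101\t400\t.", strand, ".\tID=t1;Parent=g1",
            sep = "\t"),
      paste("chr1\ttest\texon\t101\t400\t.", strand, ".\tParent=t1",
            sep = "\t"),
      paste("chr1\ttest\tCDS\t151\t350\t.", strand, "0\tParent=t1",
            sep = "\t")
    ), gff)
  }
  # plus strand: [100,150) half-open -> 101..150 is the 5' UTR
  make_gff("+")
  m <- read_gene_models(gff)[["t1"]]
  expect_equal(start(m$utr5), 101L); expect_equal(end(m$utr5), 150L)
  expect_equal(start(m$utr3), 351L); expect_equal(end(m$utr3), 400L)
  expect_equal(m$tss, 101L)
  expect_false(m$scorable) # 200 bases, not divisible by 3
  # minus strand: UTR roles swap, TSS at the high end
  make_gff("-")
  m <- read_gene_models(gff)[["t1"]]
  expect_equal(start(m$utr5), 351L); expect_equal(end(m$utr5), 400L)
  expect_equal(start(m$utr3), 101L); expect_equal(end(m$utr3), 150L)
  expect_equal(m$tss, 400L)
})

test_that("orphan CDS is an error; 13-gene annotation loads 13 models", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t10\t30\t.\t+\t0\tParent=ghost"
  ), gff)
  expect_error(read_gene_models(gff), "orphan CDS")

  models <- read_gene_models(default_sim()$paths$gff3)
  expect_length(models, 13L)
  expect_setequal(vapply(models, `[[`, character(1), "gene_id"),
                  sprintf("gene%02d", 1:13))
})

test_that("every exon base is exactly one of UTR5, CDS, UTR3", {
  for (m in small_sim()$models) {
    exon_bases <- sort(unlist(mapply(seq, start(m$exons), end(m$exons))))
    parts <- lapply(list(m$utr5, m$cds, m$utr3), function(gr) {
      if (!length(gr)) integer(0) else
        sort(unlist(mapply(seq, start(gr), end(gr))))
    })
    expect_equal(sort(unlist(parts)), exon_bases) # partition: union == exons
    expect_equal(sum(lengths(parts)), length(exon_bases)) # and disjoint
  }
})

test_that("write_report_tsv sorts deterministically and handles empties", {
  path <- tempfile(fileext = ".tsv")
  write_report_tsv(data.frame(chrom = character(), pos = integer()), path)
  expect_equal(readLines(path), "chrom\tpos")

  rows <- data.frame(chrom = "chr1", pos = c(500L, 100L), x = c("b", "a"))
  write_report_tsv(rows, path)
  got <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(got$pos, c(100L, 500L))

  expect_error(
    write_report_tsv(rows, file.path(tempfile(), "nope", "x.tsv")),
    "cannot write"
  )
})
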