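# a hand-built two-gene toy: plus-strand g1 and minus-strand g2 on 10 kb
toy_models <- function() {
  g1 <- transcript_model(
    gene_id = "g1", tx_id = "g1.t1",
    exons = genomic_interval("chr1", c(3001, 3501), c(3200, 3900), "+"),
    cds = genomic_interval("chr1", c(3101, 3501), c(3200, 3700), "+")
  )
  g2 <- transcript_model(
    gene_id = "g2", tx_id = "g2.t1",
    exons = genomic_interval("chr1", c(7001, 7501), c(7200, 7800), "-"),
    cds = genomic_interval("chr1", c(7101, 7501), c(7200, 7600), "-")
  )
  list(g1.t1 = g1, g2.t1 = g2)
}

test_that("derive_promoters is strand-aware and clips at bounds", {
  m <- toy_models()
  pr <- derive_promoters(m, upstream = 2000)
  p1 <- pr[pr$gene_id == "g1"]
  expect_equal(c(start(p1), end(p1)), c(1001L, 3000L))
  # minus strand: promoter extends to higher coordinates from the 3' end
  p2 <- pr[pr$gene_id == "g2"]
  expect_equal(c(start(p2), end(p2)), c(7801L, 9800L))
  # clipping: TSS near the origin
  g <- transcript_model(
    gene_id = "g3", tx_id = "g3.t1",
    exons = genomic_interval("chr1", 501, 900, "+"),
    cds = genomic_interval("chr1", 601, 900, "+")
  )
  p3 <- derive_promoters(list(g), upstream = 2000)
  expect_equal(c(start(p3), end(p3)), c(1L, 500L))
})

test_that("single variants get the expected category", {
  m <- toy_models()
  ann1 <- function(pos) {
    v <- data.frame(id = "v", chrom = "chr1", pos = pos)
    a <- annotate_variants(v, m)
    a$category
  }
  expect_equal(ann1(3201), "splice")   # first intronic base after CDS exon
  expect_equal(ann1(3050), "UTR5")     # exonic 5' UTR, plus strand
  expect_equal(ann1(3150), "CDS")
  expect_equal(ann1(3750), "UTR3")
  expect_equal(ann1(7050), "UTR3")     # minus strand: low coords are 3'
  expect_equal(ann1(7700), "UTR5")
  expect_equal(ann1(2500), "promoter") # in g1's 2 kb upstream window
  expect_true(is.na(ann1(5500)))       # intergenic
})

test_that("annotation matches a per-base membership oracle over 10 kb", {
  m <- toy_models()
  promoters <- derive_promoters(m, upstream = 2000)
  cpg <- genomic_interval("chr1", 5001, 5300)
  w <- 2L
  # oracle: direct, by-hand membership rules per base
  oracle <- function(p) {
    cats <- character(0)
    for (mod in m) {
      in_any <- function(gr) length(gr) > 0 &&
        any(p >= start(gr) & p <= end(gr))
      if (in_any(mod$cds)) cats <- c(cats, "CDS")
      if (in_any(mod$utr5)) cats <- c(cats, "UTR5")
      if (in_any(mod$utr3)) cats <- c(cats, "UTR3")
      ex <- sort(c(start(mod$exons), end(mod$exons)))
      intron <- c(ex[2] + 1, ex[3] - 1) # single intron in each toy gene
      if ((p >= intron[1] && p <= intron[1] + w - 1) ||
          (p <= intron[2] && p >= intron[2] - w + 1)) {
        cats <- c(cats, "splice")
      }
    }
    if (any(p >= start(promoters) & p <= end(promoters))) {
      cats <- c(cats, "promoter")
    }
    if (p >= 5001 && p <= 5300) cats <- c(cats, "CpG")
    sort(unique(cats))
  }
  pos <- 1:10000
  v <- data.frame(id = paste0("v", pos), chrom = "chr1", pos = pos)
  ann <- annotate_variants(v, m, cpg = cpg, promoters = promoters,
                           splice_window = w)
  got <- split(ann$category[!is.na(ann$category)],
               ann$id[!is.na(ann$category)])
  for (p in pos) {
    expected <- oracle(p)
    mine <- sort(unique(got[[paste0("v", p)]]))
    if (is.null(mine)) mine <- character(0)
    if (!identical(mine, expected)) {
      fail(sprintf("position %d: got {%s}, oracle {%s}", p,
                   paste(mine, collapse = ","),
                   paste(expected, collapse = ",")))
    }
  }
  succeed()
})

test_that("annotation is invariant under transcript input order", {
  sim <- small_sim()
  calls <- call_consensus(sim$snps, sim$manifest)
  a <- annotate_variants(calls, sim$models, cpg = sim$cpg,
                         promoters = sim$promoters)
  b <- annotate_variants(calls, rev(sim$models), cpg = sim$cpg,
                         promoters = sim$promoters)
  expect_equal(a, b)
})

test_that("CpG detector: degenerate sequences", {
  expect_length(detect_cpg_islands(strrep("AT", 300)), 0L)
  isl <- detect_cpg_islands(strrep("CG", 200))
  expect_length(isl, 1L)
  expect_equal(c(start(isl), end(isl)), c(1L, 400L))
  expect_equal(isl$gc, 1.0)
  # obs/exp = (N_CG * L) / (N_C * N_G), far above the 0.6 threshold
  expect_gte(isl$oe, 1.9)
})

test_that("CpG detector skips windows containing N", {
  s <- paste0(strrep("CG", 150), strrep("N", 10), strrep("AT", 150))
  expect_message(isl <- detect_cpg_islands(s), "skipped.*containing N")
  expect_true(all(end(isl) < 301L))
})

test_that("CpG detector agrees with the all-substrings oracle on fuzz", {
  for (seed in 1:8) {
    set.seed(100 + seed)
    # GC-enriched so that islands actually occur
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                      prob = c(.15, .35, .35, .15)), collapse = "")
    got <- detect_cpg_islands(s)
    exp <- cpg_oracle(s)
    expect_equal(start(got), unname(exp[, "start"]),
                 info = paste("seed", seed))
    expect_equal(end(got), unname(exp[, "end"]),
                 info = paste("seed", seed))
  }
})

test_that("every planted SNP gets exactly its ground-truth category", {
  sim <- small_sim()
  truth <- sim$truth
  ann <- annotate_variants(sim$snps, sim$models, cpg = sim$cpg,
                           promoters = sim$promoters)
  cat_map <- c(nsSNP = "CDS", synonymous = "CDS", UTR = "UTR",
               splice = "splice", CpG = "CpG", promoter = "promoter")
  for (i in seq_len(nrow(truth))) {
    cats <- ann$category[ann$id == truth$id[i]]
    cats <- unique(cats[!is.na(cats)])
    cats[cats %in% c("UTR5", "UTR3")] <- "UTR"
    expected <- truth$category[i]
    if (expected %in% names(cat_map)) {
      expect_equal(unique(cats), unname(cat_map[expected]),
                   info = paste("snp", truth$id[i], "category", expected))
      # gene linkage agrees with the planted gene
      genes <- unique(ann$gene_id[ann$id == truth$id[i]])
      expect_equal(genes[!is.na(genes)], truth$gene_id[i],
                   info = paste("gene of", truth$id[i]))
    } else {
      expect_length(cats, 0L) # decoys: no gene-related category
    }
  }
})
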