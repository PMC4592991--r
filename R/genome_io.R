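#' Two-group sample manifest
#'
#' Maps each sequenced sample to its inferred QTL genotype group, `QQ`
#' (high allele, homozygous) or `qq` (low allele, homozygous).
#'
#' @param samples character vector of sample ids.
#' @param groups character vector of group labels, `"QQ"` or `"qq"`.
#' @return a `data.frame` with columns `sample`, `group`.
#' @export
sample_manifest <- function(samples, groups) {
  samples <- as.character(samples)
  groups <- as.character(groups)
  if (length(samples) != length(groups)) {
    stop("samples and groups must have equal length")
  }
  if (anyDuplicated(samples)) {
    stop("duplicated sample id: ", samples[duplicated(samples)][1])
  }
  bad <- !groups %in% c("QQ", "qq")
  if (any(bad)) stop("group label must be QQ or qq, got: ", groups[bad][1])
  if (!all(c("QQ", "qq") %in% groups)) {
    stop("both groups (QQ and qq) must be non-empty")
  }
  data.frame(sample = samples, group = groups, stringsAsFactors = FALSE)
}

#' Read / write a sample manifest TSV (columns `sample`, `group`)
#'
#' @param path file path (plain or gzip).
#' @return `read_manifest()` returns a validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("manifest must have columns 'sample' and 'group'")
  }
  sample_manifest(df$sample, df$group)
}

#' @rdname read_manifest
#' @param manifest a manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference FASTA into a named DNAStringSet
#'
#' @param path FASTA path (plain or gzip).
#' @return named [Biostrings::DNAStringSet]; names truncated at the first
#'   whitespace as usual.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Construct a SNP set
#'
#' The package's variant container: a table of biallelic SNPs plus a
#' genotype dose matrix (variants x samples; 0 = homozygous ref,
#' 1 = heterozygous, 2 = homozygous alt, `NA` = missing).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param geno integer matrix, one row per variant, one named column per
#'   sample.
#' @return an object of class `snp_set`.
#' @export
snp_set <- function(variants, geno) {
  stopifnot(is.data.frame(variants), is.matrix(geno))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(variants) != nrow(geno)) stop("variants/geno row mismatch")
  if (is.null(colnames(geno))) stop("geno must have sample column names")
  bad <- variants$ref == variants$alt |
    !grepl("^[ACGT]$", variants$ref) | !grepl("^[ACGT]$", variants$alt)
  if (any(bad)) {
    stop("not a biallelic SNP at row ", which(bad)[1], ": ",
         variants$ref[bad][1], ">", variants$alt[bad][1])
  }
  variants$pos <- as.integer(variants$pos)
  variants$id <- paste0(variants$chrom, ":", variants$pos, "_",
                        variants$ref, ">", variants$alt)
  rownames(geno) <- variants$id
  structure(list(variants = variants, geno = geno), class = "snp_set")
}

#' @export
length.snp_set <- function(x) nrow(x$variants)

#' @export
print.snp_set <- function(x, ...) {
  cat("snp_set:", nrow(x$variants), "SNPs x", ncol(x$geno), "samples\n")
  print(utils::head(x$variants, 5))
  invisible(x)
}

# parse one-allele-indexed dose from GT strings for a given alt index
.gt_dose <- function(gt, alt_index) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) == 0L || any(p == ".")) return(NA_integer_)
    sum(p == as.character(alt_index))
  }, integer(1))
}

#' Read a multi-sample VCF into a SNP set
#'
#' Multiallelic records are split into one biallelic record per ALT
#' allele (the genotype dose counts only that allele). Indels and other
#' non-SNP alleles are skipped and counted. Sample columns must match the
#' manifest exactly.
#'
#' @param path VCF v4.x file (plain or bgzip/gzip).
#' @param manifest a [sample_manifest()] data.frame.
#' @param ref_seqs optional reference [Biostrings::DNAStringSet]; when
#'   supplied, every REF allele is checked against it and a mismatch is an
#'   error naming the coordinate.
#' @return a `snp_set`; the number of skipped non-SNP allele records is
#'   attached as `attr(, "skipped")` and reported via `message()`.
#' @export
read_vcf <- function(path, manifest, ref_seqs = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf_samples <- colnames(vcf)
  unknown <- setdiff(vcf_samples, manifest$sample)
  if (length(unknown)) stop("unknown sample in VCF header: ", unknown[1])
  missing <- setdiff(manifest$sample, vcf_samples)
  if (length(missing)) stop("manifest sample absent from VCF: ", missing[1])

  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf) # DNAStringSetList-like
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)

  rows <- list()
  geno_rows <- list()
  skipped <- 0L
  for (i in seq_along(rr)) {
    a_i <- as.character(alts[[i]])
    for (k in seq_along(a_i)) {
      if (nchar(refs[i]) == 1L && grepl("^[ACGT]$", refs[i]) &&
          nchar(a_i[k]) == 1L && grepl("^[ACGT]$", a_i[k])) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom[i], pos = pos[i], ref = refs[i], alt = a_i[k],
          stringsAsFactors = FALSE
        )
        geno_rows[[length(geno_rows) + 1L]] <- .gt_dose(gt[i, ], k)
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  if (skipped > 0L) message("read_vcf: skipped ", skipped, " non-SNP allele record(s)")
  if (!length(rows)) {
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character())
    geno <- matrix(integer(), 0, length(vcf_samples),
                   dimnames = list(NULL, vcf_samples))
  } else {
    variants <- do.call(rbind, rows)
    geno <- do.call(rbind, geno_rows)
    colnames(geno) <- vcf_samples
  }
  # keep manifest column order
  geno <- geno[, manifest$sample, drop = FALSE]
  if (!is.null(ref_seqs) && nrow(variants)) {
    obs <- reference_fetch(
      ref_seqs, genomic_interval(variants$chrom, variants$pos, variants$pos)
    )
    bad <- obs != variants$ref
    if (any(bad)) {
      i <- which(bad)[1]
      stop("REF allele mismatch vs reference at ", variants$chrom[i], ":",
           variants$pos[i], " (VCF ", variants$ref[i], ", genome ", obs[i], ")")
    }
  }
  out <- snp_set(variants, geno)
  attr(out, "skipped") <- skipped
  out
}

#' Write a SNP set as a minimal VCF v4.2
#'
#' One biallelic record per SNP, GT-only FORMAT; doses 0/1/2/NA become
#' `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param snps a `snp_set`.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @export
write_vcf <- function(snps, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=snpconsensus",
    if (!is.null(contigs)) {
      paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">")
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(snps$geno)), collapse = "\t")
  ), con)
  if (nrow(snps$variants)) {
    v <- snps$variants[order(snps$variants$chrom, snps$variants$pos), ,
                       drop = FALSE]
    g <- snps$geno[v$id, , drop = FALSE]
    gt_str <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
    gt_str[is.na(gt_str)] <- "./."
    lines <- paste(
      v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
      apply(gt_str, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Build a transcript model
#'
#' Strand-aware gene structure used for functional classification and
#' codon mapping. UTRs are derived from `exons` minus `cds` when not
#' supplied. The total CDS length must be divisible by 3, otherwise the
#' model is loaded but flagged non-scorable.
#'
#' @param gene_id,tx_id identifiers.
#' @param exons,cds `GRanges` of exon and CDS intervals (1-based closed),
#'   CDS must be contained in exons.
#' @param utr5,utr3 optional `GRanges`; derived when `NULL`.
#' @return an object of class `transcript_model` with fields `gene_id`,
#'   `tx_id`, `chrom`, `strand`, `exons`, `cds`, `utr5`, `utr3`, `tss`,
#'   `scorable`.
#' @export
transcript_model <- function(gene_id, tx_id, exons, cds,
                             utr5 = NULL, utr3 = NULL) {
  exons <- GenomicRanges::sort(exons)
  cds <- GenomicRanges::sort(cds)
  strand <- unique(as.character(GenomicRanges::strand(exons)))
  chrom <- unique(as.character(GenomicRanges::seqnames(exons)))
  if (length(strand) != 1L || length(chrom) != 1L) {
    stop("transcript ", tx_id, ": exons must share one chrom and strand")
  }
  if (length(GenomicRanges::reduce(exons)) != length(exons)) {
    stop("transcript ", tx_id, ": overlapping exons")
  }
  if (length(cds) &&
      !all(IRanges::overlapsAny(cds, exons, type = "within"))) {
    stop("transcript ", tx_id, ": CDS not contained in exons")
  }
  if (is.null(utr5) || is.null(utr3)) {
    utr <- GenomicRanges::setdiff(exons, cds, ignore.strand = TRUE)
    GenomicRanges::strand(utr) <- strand
    if (length(cds)) {
      cds_start <- min(GenomicRanges::start(cds))
      cds_end <- max(GenomicRanges::end(cds))
      left <- utr[GenomicRanges::end(utr) < cds_start]
      right <- utr[GenomicRanges::start(utr) > cds_end]
      if (strand == "-") {
        utr5 <- right; utr3 <- left
      } else {
        utr5 <- left; utr3 <- right
      }
    } else {
      utr5 <- utr[0]; utr3 <- utr
    }
  }
  cds_len <- sum(GenomicRanges::width(cds))
  tss <- if (strand == "-") max(GenomicRanges::end(exons)) else
    min(GenomicRanges::start(exons))
  structure(list(
    gene_id = gene_id, tx_id = tx_id, chrom = chrom, strand = strand,
    exons = exons, cds = cds, utr5 = GenomicRanges::sort(utr5),
    utr3 = GenomicRanges::sort(utr3), tss = tss,
    scorable = length(cds) > 0L && cds_len %% 3L == 0L
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model ", x$tx_id, " (gene ", x$gene_id, ", ", x$strand,
      "): ", length(x$exons), " exons, CDS ",
      sum(GenomicRanges::width(x$cds)), " bp",
      if (!x$scorable) " [non-scorable]", "\n", sep = "")
  invisible(x)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 must contain `gene`/`mRNA` (or `transcript`) features plus `exon`
#' and `CDS` children; `five_prime_UTR`/`three_prime_UTR` are used when
#' present and derived otherwise. BED12 blocks become exons and the thick
#' interval the CDS. A CDS whose total length is not divisible by 3 loads
#' with `scorable = FALSE`; a CDS without a parent transcript is an error.
#'
#' @param path GFF3 (`.gff`, `.gff3`, optionally `.gz`) or BED12 file.
#' @return named list of [transcript_model()] objects (names = tx id).
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (fmt == "bed") {
    bed <- rtracklayer::import(path, format = "bed")
    models <- lapply(seq_along(bed), function(i) {
      b <- bed[i]
      name <- if (!is.null(b$name)) b$name else paste0("tx", i)
      exons <- if (!is.null(b$blocks) && length(b$blocks[[1]])) {
        GenomicRanges::shift(
          GenomicRanges::GRanges(
            GenomicRanges::seqnames(b), b$blocks[[1]],
            strand = GenomicRanges::strand(b)
          ),
          GenomicRanges::start(b) - 1L
        )
      } else {
        b
      }
      thick <- if (!is.null(b$thick)) {
        GenomicRanges::GRanges(GenomicRanges::seqnames(b), b$thick[1],
                               strand = GenomicRanges::strand(b))
      } else {
        b
      }
      cds <- GenomicRanges::intersect(exons, thick, ignore.strand = TRUE)
      GenomicRanges::strand(cds) <- as.character(GenomicRanges::strand(b))
      transcript_model(gene_id = name, tx_id = name, exons = exons, cds = cds)
    })
    names(models) <- vapply(models, `[[`, character(1), "tx_id")
    return(models)
  }
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  tx_mask <- type %in% c("mRNA", "transcript")
  tx <- gff[tx_mask]
  tx_ids <- as.character(tx$ID)
  tx_parent <- vapply(tx$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  first_parent <- function(x) {
    vapply(x$Parent, function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p[1])
    }, character(1))
  }
  exons <- gff[type == "exon"]
  cds <- gff[type == "CDS"]
  utr5 <- gff[type == "five_prime_UTR"]
  utr3 <- gff[type == "three_prime_UTR"]
  exon_parent <- first_parent(exons)
  cds_parent <- first_parent(cds)
  orphan <- is.na(cds_parent) | !cds_parent %in% tx_ids
  if (any(orphan)) {
    stop("orphan CDS without parent transcript at ",
         as.character(GenomicRanges::seqnames(cds))[orphan][1], ":",
         GenomicRanges::start(cds)[orphan][1])
  }
  u5_parent <- first_parent(utr5)
  u3_parent <- first_parent(utr3)
  models <- lapply(seq_along(tx), function(i) {
    id <- tx_ids[i]
    gene <- if (!is.na(tx_parent[i])) tx_parent[i] else id
    e <- exons[!is.na(exon_parent) & exon_parent == id]
    if (!length(e)) stop("transcript ", id, " has no exons")
    k <- cds[cds_parent == id]
    u5 <- utr5[!is.na(u5_parent) & u5_parent == id]
    u3 <- utr3[!is.na(u3_parent) & u3_parent == id]
    transcript_model(
      gene_id = gene, tx_id = id,
      exons = GenomicRanges::granges(e), cds = GenomicRanges::granges(k),
      utr5 = if (length(u5)) GenomicRanges::granges(u5) else NULL,
      utr3 = if (length(u3)) GenomicRanges::granges(u3) else NULL
    )
  })
  names(models) <- tx_ids
  models
}

#' Pick one transcript per gene for coding-effect analysis
#'
#' The transcript with the longest total CDS represents its gene; ties
#' broken by the lexicographically smallest transcript id.
#'
#' @param models list of `transcript_model`s.
#' @return named list, one model per gene.
#' @export
primary_transcripts <- function(models) {
  genes <- vapply(models, `[[`, character(1), "gene_id")
  cds_len <- vapply(models, function(m) sum(GenomicRanges::width(m$cds)),
                    numeric(1))
  tx <- vapply(models, `[[`, character(1), "tx_id")
  keep <- unlist(lapply(split(seq_along(models), genes), function(i) {
    i[order(-cds_len[i], tx[i])][1]
  }))
  out <- models[keep]
  names(out) <- genes[keep]
  out[order(names(out))]
}

#' Write a report table as TSV
#'
#' Tab-separated with a single header line. Rows are sorted
#' deterministically: by `(chrom, pos)` or `(chrom, coordinate)` when
#' those columns exist, then by the remaining columns left to right.
#'
#' @param rows a data.frame (may have zero rows: header-only output).
#' @param path output path.
#' @export
write_report_tsv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows)) {
    poscol <- intersect(c("pos", "coordinate"), names(rows))[1]
    keys <- c(
      intersect("chrom", names(rows)),
      if (!is.na(poscol)) poscol,
      setdiff(names(rows), c("chrom", poscol))
    )
    rows <- rows[do.call(order, rows[keys]), , drop = FALSE]
  }
  ok <- tryCatch({
    suppressWarnings(utils::write.table(rows, path, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
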