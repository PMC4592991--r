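#' Derive strand-aware promoter intervals from transcript models
#'
#' One interval per transcript: `upstream` bases before the TSS plus
#' `downstream` bases into the transcript, clipped at sequence bounds.
#' On the minus strand the promoter extends to higher genomic
#' coordinates.
#'
#' @param models list of [transcript_model()]s.
#' @param upstream,downstream extent in bases (defaults 2000 / 0, a
#'   common promoter convention).
#' @param seq_lengths optional named vector of chromosome lengths for
#'   right-clipping.
#' @return `GRanges` with metadata columns `gene_id`, `tx_id`.
#' @export
derive_promoters <- function(models, upstream = 2000L, downstream = 0L,
                             seq_lengths = NULL) {
  grs <- lapply(models, function(m) {
    if (m$strand == "-") {
      start <- m$tss + 1L - downstream
      end <- m$tss + upstream
    } else {
      start <- m$tss - upstream
      end <- m$tss - 1L + downstream
    }
    start <- max(1L, start)
    if (!is.null(seq_lengths) && m$chrom %in% names(seq_lengths)) {
      end <- min(end, seq_lengths[[m$chrom]])
    }
    if (end < start) return(GenomicRanges::GRanges())
    gr <- genomic_interval(m$chrom, start, end, m$strand)
    gr$gene_id <- m$gene_id
    gr$tx_id <- m$tx_id
    gr
  })
  out <- suppressWarnings(do.call(c, unname(grs)))
  out
}

#' Detect CpG islands with sliding-window GC / CpG observed-expected criteria
#'
#' A position belongs to an island when at least one window of exactly
#' `min_length` bases containing it has GC fraction >= `min_gc` and
#' CpG observed/expected ratio >= `min_oe`, where
#' `obs/exp = (N_CG * L) / (N_C * N_G)`. Islands are the maximal runs of
#' such positions; GC and obs/exp over each whole island are reported.
#' Windows containing `N` are skipped (and counted in a message). With
#' `strict = TRUE` each island is trimmed window-by-window from its ends
#' until the whole run itself satisfies all three criteria.
#'
#' @param seq a single character DNA sequence, [Biostrings::DNAString] or
#'   one-element `DNAStringSet`.
#' @param chrom sequence name for the returned ranges.
#' @param min_length,min_gc,min_oe island criteria (defaults 200 / 0.5 /
#'   0.6, the classic Gardiner-Garden & Frommer thresholds).
#' @param strict re-impose the criteria on whole merged islands.
#' @return `GRanges` (1-based closed) with metadata columns `gc` and
#'   `oe`.
#' @export
detect_cpg_islands <- function(seq, chrom = "chr1", min_length = 200L,
                               min_gc = 0.5, min_oe = 0.6, strict = FALSE) {
  if (methods::is(seq, "DNAStringSet")) seq <- as.character(seq[[1]])
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- GenomicRanges::GRanges()
  empty$gc <- numeric(0)
  empty$oe <- numeric(0)
  if (n < min_length) return(empty)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  isC <- b == "C"
  isG <- b == "G"
  isN <- !b %in% c("A", "C", "G", "T")
  isCG <- c(isC[-n] & isG[-1], FALSE)
  csC <- cumsum(isC); csG <- cumsum(isG)
  csCG <- cumsum(isCG); csN <- cumsum(isN)
  win_sum <- function(cs, i, j) cs[j] - c(0, cs)[i]
  L <- as.integer(min_length)
  i <- seq_len(n - L + 1L)
  j <- i + L - 1L
  nN <- win_sum(csN, i, j)
  nC <- win_sum(csC, i, j)
  nG <- win_sum(csG, i, j)
  nCG <- win_sum(csCG, i, j - 1L) # dinucleotides fully inside the window
  gc <- (nC + nG) / L
  oe <- ifelse(nC * nG > 0, nCG * L / (nC * nG), 0)
  ok <- nN == 0L & gc >= min_gc & oe >= min_oe
  n_skipped <- sum(nN > 0L)
  if (n_skipped > 0L) {
    message("detect_cpg_islands: skipped ", n_skipped, " window(s) containing N")
  }
  if (!any(ok)) return(empty)
  cov <- integer(n + 1L)
  cov[i[ok]] <- cov[i[ok]] + 1L
  cov[j[ok] + 1L] <- cov[j[ok] + 1L] - 1L
  covered <- cumsum(cov)[seq_len(n)] > 0L
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  stat <- function(s, e) {
    len <- e - s + 1L
    cc <- win_sum(csC, s, e); gg <- win_sum(csG, s, e)
    cg <- if (e > s) win_sum(csCG, s, e - 1L) else 0L
    c(gc = (cc + gg) / len, oe = if (cc * gg > 0) cg * len / (cc * gg) else 0)
  }
  if (strict) {
    for (k in seq_along(starts)) {
      repeat {
        st <- stat(starts[k], ends[k])
        if ((ends[k] - starts[k] + 1L) < L ||
            (st["gc"] >= min_gc && st["oe"] >= min_oe)) break
        # drop the least-qualifying end base
        starts[k] <- starts[k] + 1L
        ends[k] <- ends[k] - 1L
      }
    }
    long_enough <- (ends - starts + 1L) >= L
    starts <- starts[long_enough]; ends <- ends[long_enough]
    if (!length(starts)) return(empty)
  }
  stats <- t(mapply(stat, starts, ends))
  gr <- genomic_interval(chrom, starts, ends)
  gr$gc <- as.numeric(stats[, "gc"])
  gr$oe <- as.numeric(stats[, "oe"])
  gr
}

# intronic splice windows (first/last `w` intron bases) for one model
.splice_windows <- function(m, w) {
  if (length(m$exons) < 2L) return(GenomicRanges::GRanges())
  introns <- GenomicRanges::setdiff(
    range(GenomicRanges::granges(m$exons), ignore.strand = TRUE),
    GenomicRanges::granges(m$exons), ignore.strand = TRUE
  )
  if (!length(introns)) return(GenomicRanges::GRanges())
  s <- GenomicRanges::start(introns)
  e <- GenomicRanges::end(introns)
  wl <- pmin(w, e - s + 1L)
  left <- genomic_interval(m$chrom, s, s + wl - 1L)
  right <- genomic_interval(m$chrom, e - wl + 1L, e)
  GenomicRanges::reduce(c(left, right))
}

#' Classify consensus SNPs by gene-related functional context
#'
#' Assigns each variant the categories it overlaps: `CDS`, `UTR5`,
#' `UTR3`, `splice` (within `splice_window` intronic bases of an
#' exon-intron boundary; default 2, the canonical GT/AG dinucleotides),
#' `CpG` (island intervals) and `promoter`. A variant may carry several
#' categories and is reported once per gene per category; intergenic
#' variants return a single row with `NA` gene and category.
#'
#' @param variants a [snp_set()], or any data.frame with `id`, `chrom`,
#'   `pos` columns (e.g. [call_consensus()] output).
#' @param models list of [transcript_model()]s.
#' @param cpg `GRanges` of CpG islands (e.g. planted truth or
#'   [detect_cpg_islands()] output); `NULL` disables the category.
#' @param promoters `GRanges` of promoter intervals with a `gene_id`
#'   column; derived via [derive_promoters()] when `NULL`.
#' @param splice_window intronic bases around exon-intron boundaries.
#' @return long-format data.frame: `id`, `chrom`, `pos`, `gene_id`,
#'   `category`.
#' @export
annotate_variants <- function(variants, models, cpg = NULL,
                              promoters = NULL, splice_window = 2L) {
  v <- if (inherits(variants, "snp_set")) variants$variants else variants
  stopifnot(all(c("id", "chrom", "pos") %in% names(v)))
  if (is.null(promoters)) promoters <- derive_promoters(models)
  pos_gr <- genomic_interval(v$chrom, v$pos, v$pos)

  hit_rows <- function(feature_gr, gene_ids, category) {
    if (is.null(feature_gr) || !length(feature_gr)) return(NULL)
    ov <- GenomicRanges::findOverlaps(pos_gr, feature_gr,
                                      ignore.strand = TRUE)
    if (!length(ov)) return(NULL)
    data.frame(
      id = v$id[queryHits(ov)], chrom = v$chrom[queryHits(ov)],
      pos = v$pos[queryHits(ov)],
      gene_id = gene_ids[subjectHits(ov)], category = category,
      stringsAsFactors = FALSE
    )
  }

  pieces <- list()
  for (m in models) {
    gene <- m$gene_id
    pieces[[length(pieces) + 1L]] <- hit_rows(m$cds, rep(gene, length(m$cds)), "CDS")
    pieces[[length(pieces) + 1L]] <- hit_rows(m$utr5, rep(gene, length(m$utr5)), "UTR5")
    pieces[[length(pieces) + 1L]] <- hit_rows(m$utr3, rep(gene, length(m$utr3)), "UTR3")
    sw <- .splice_windows(m, splice_window)
    pieces[[length(pieces) + 1L]] <- hit_rows(sw, rep(gene, length(sw)), "splice")
  }
  if (length(promoters)) {
    pieces[[length(pieces) + 1L]] <-
      hit_rows(promoters, promoters$gene_id, "promoter")
  }
  if (!is.null(cpg) && length(cpg)) {
    cpg_rows <- hit_rows(cpg, rep(NA_character_, length(cpg)), "CpG")
    if (!is.null(cpg_rows)) {
      # link island SNPs to a gene via gene body or promoter overlap
      spans <- lapply(models, function(m)
        range(GenomicRanges::granges(m$exons), ignore.strand = TRUE))
      span_gr <- suppressWarnings(do.call(c, unname(spans)))
      span_gene <- vapply(models, `[[`, character(1), "gene_id")
      link <- c(span_gr, GenomicRanges::granges(promoters))
      link_gene <- c(span_gene, promoters$gene_id)
      p <- genomic_interval(cpg_rows$chrom, cpg_rows$pos, cpg_rows$pos)
      ov <- GenomicRanges::findOverlaps(p, link, ignore.strand = TRUE,
                                        select = "first")
      cpg_rows$gene_id <- ifelse(is.na(ov), NA_character_, link_gene[ov])
      pieces[[length(pieces) + 1L]] <- cpg_rows
    }
  }
  ann <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(ann)) {
    ann <- data.frame(id = character(), chrom = character(),
                      pos = integer(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE)
  }
  ann <- unique(ann)
  # intergenic variants: keep one empty row each
  miss <- !v$id %in% ann$id
  if (any(miss)) {
    ann <- rbind(ann, data.frame(
      id = v$id[miss], chrom = v$chrom[miss], pos = v$pos[miss],
      gene_id = NA_character_, category = NA_character_,
      stringsAsFactors = FALSE
    ))
  }
  ann <- ann[order(ann$chrom, ann$pos, ann$gene_id, ann$category,
                   na.last = TRUE), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}
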