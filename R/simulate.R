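#' Configuration for the synthetic QTL-interval dataset
#'
#' The defaults restate the study design the generator emulates: a
#' ~1.2 Mb fine-mapped interval holding 13 genes, resequenced in two
#' groups of 5 birds homozygous for opposite QTL alleles, with planted
#' group-consensus SNPs whose per-category counts default to the
#' category-count table of the original analysis (QQ: 3 nsSNP, 28 UTR,
#' 1 splice, 3 CpG, 23 promoter; qq: 1 nsSNP, 25 UTR, 3 splice, 5 CpG,
#' 38 promoter), plus synonymous coding SNPs and discordant decoys.
#' The first QQ nonsynonymous SNP always gets support n-1 of n
#' (the "4/5" case); additionally a fraction `almost_frac` of all planted
#' consensus SNPs drop one carrier.
#'
#' @param seed integer seed; mandatory, every run is fully reproducible.
#' @param interval_length interval size in bases.
#' @param n_genes number of genes placed in the interval.
#' @param samples_per_group samples per genotype group.
#' @param planted named list `QQ`/`qq` of per-category planted consensus
#'   SNP counts (categories `nsSNP`, `synonymous`, `UTR`, `splice`,
#'   `CpG`, `promoter`).
#' @param almost_frac fraction of planted consensus SNPs carried by only
#'   n-1 samples of their group.
#' @param decoy_discordant number of decoy SNPs violating the consensus
#'   rule (present in both groups, sub-threshold support, or absence
#'   violations).
#' @param decoy_intergenic number of consensus-patterned SNPs planted
#'   outside every gene-related feature (they are real consensus SNPs
#'   but must land in no functional category).
#' @param target_substitutions named list `QQ`/`qq` of amino-acid
#'   substitutions (e.g. `"T>P"`) to realize for the first planted
#'   nonsynonymous SNPs; extras beyond the list are drawn randomly.
#' @param n_orthologs sequences per ortholog protein alignment.
#' @param conservation baseline per-column identity of ortholog
#'   alignments (planted substitution columns are fully conserved).
#' @param promoter_upstream promoter extent upstream of the TSS (bases).
#' @param splice_window intronic bases treated as splice site.
#' @param chrom contig name.
#' @return validated configuration list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       interval_length = 1200000L,
                       n_genes = 13L,
                       samples_per_group = 5L,
                       planted = list(
                         QQ = c(nsSNP = 3L, synonymous = 2L, UTR = 28L,
                                splice = 1L, CpG = 3L, promoter = 23L),
                         qq = c(nsSNP = 1L, synonymous = 2L, UTR = 25L,
                                splice = 3L, CpG = 5L, promoter = 38L)
                       ),
                       almost_frac = 0.1,
                       decoy_discordant = 40L,
                       decoy_intergenic = 8L,
                       target_substitutions = list(
                         QQ = c("T>P", "G>S", "F>I"), qq = c("A>G")
                       ),
                       n_orthologs = 8L,
                       conservation = 0.9,
                       promoter_upstream = 2000L,
                       splice_window = 2L,
                       chrom = "chr1") {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cats <- c("nsSNP", "synonymous", "UTR", "splice", "CpG", "promoter")
  for (g in c("QQ", "qq")) {
    if (!all(cats %in% names(planted[[g]]))) {
      stop("planted$", g, " must name counts for: ",
           paste(cats, collapse = ", "))
    }
    if (any(planted[[g]] < 0L)) stop("planted counts must be >= 0")
  }
  stopifnot(
    interval_length > 50000L, n_genes >= 1L, samples_per_group >= 2L,
    almost_frac >= 0, almost_frac <= 1, decoy_discordant >= 0L,
    decoy_intergenic >= 0L, n_orthologs >= 2L,
    conservation >= 0, conservation <= 1
  )
  structure(as.list(environment()), class = "sim_config")
}

# restore the caller's RNG state on exit
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.BASES <- c("A", "C", "G", "T")

# CpG-depleted random background, as vector of single characters
.random_background <- function(n) {
  b <- sample(.BASES, n, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
  cg <- which(b[-n] == "C" & b[-1] == "G")
  if (length(cg)) {
    kill <- cg[runif(length(cg)) < 0.85]
    b[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
  }
  b
}

.sense_codons <- function() {
  tab <- standard_genetic_code()
  names(tab)[tab != "*"]
}

.random_cds <- function(n_codons) {
  sense <- setdiff(.sense_codons(), "ATG") # avoid internal starts for tidiness
  stops <- c("TAA", "TAG", "TGA")
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), sample(stops, 1L))
}

# GC- and CpG-rich island sequence satisfying the classic criteria
.island_sequence <- function(len) {
  out <- character(0)
  while (sum(nchar(out)) < len) {
    out <- c(out, if (runif(1) < 0.45) "CG" else
      sample(.BASES, 1L, prob = c(0.2, 0.3, 0.3, 0.2)))
  }
  substr(paste(out, collapse = ""), 1L, len)
}

# one synthetic gene laid out on the coding strand; returns local-coordinate
# structure plus the unspliced local sequence
.build_gene_local <- function(n_exons, cds_codons, utr5_len, utr3_len,
                              long_intron1) {
  cds_len <- 3L * cds_codons
  tlen <- utr5_len + cds_len + utr3_len
  # transcript-space exon cuts, every exon >= 80 bases
  repeat {
    cuts <- sort(sample(seq(80L, tlen - 80L), n_exons - 1L))
    if (all(diff(c(0L, cuts, tlen)) >= 80L)) break
  }
  ex_t_start <- c(0L, cuts) + 1L
  ex_t_end <- c(cuts, tlen)
  intron_len <- sample(400:900, n_exons - 1L, replace = TRUE)
  if (long_intron1 && n_exons >= 2L) intron_len[1] <- 1600L
  intron_seq <- vapply(intron_len, function(l)
    paste0("GT", paste(.random_background(l - 4L), collapse = ""), "AG"),
    character(1))
  cds_seq <- .random_cds(cds_codons)
  tseq <- paste0(
    paste(.random_background(utr5_len), collapse = ""),
    cds_seq,
    paste(.random_background(utr3_len), collapse = "")
  )
  intron_before <- c(0L, cumsum(intron_len)) # offset added to exon j
  ex_l_start <- ex_t_start + intron_before[seq_len(n_exons)]
  ex_l_end <- ex_t_end + intron_before[seq_len(n_exons)]
  # transcript -> local mapping for the CDS span
  t2l <- function(tp) {
    j <- findInterval(tp, ex_t_start)
    tp + intron_before[j]
  }
  cds_t <- c(utr5_len + 1L, utr5_len + cds_len)
  cds_l <- IRanges::IRanges(integer(0), integer(0))
  cds_ivs <- list()
  for (j in seq_len(n_exons)) {
    s <- max(ex_t_start[j], cds_t[1])
    e <- min(ex_t_end[j], cds_t[2])
    if (s <= e) cds_ivs[[length(cds_ivs) + 1L]] <- c(t2l(s), t2l(e))
  }
  pieces <- character(2L * n_exons - 1L)
  for (j in seq_len(n_exons)) {
    pieces[2L * j - 1L] <- substr(tseq, ex_t_start[j], ex_t_end[j])
    if (j < n_exons) pieces[2L * j] <- intron_seq[j]
  }
  local_seq <- paste(pieces, collapse = "")
  list(
    len = nchar(local_seq), seq = local_seq,
    exons = cbind(start = ex_l_start, end = ex_l_end),
    cds = do.call(rbind, cds_ivs),
    intron1 = if (n_exons >= 2L) c(ex_l_end[1] + 1L, ex_l_start[2] - 1L)
  )
}

#' Map a 0-based CDS offset to its genomic position
#'
#' @param model a [transcript_model()].
#' @param offset 0-based offset into the spliced CDS (transcription
#'   order).
#' @return genomic 1-based position.
#' @export
cds_offset_to_genomic <- function(model, offset) {
  w <- GenomicRanges::width(model$cds)
  if (offset < 0L || offset >= sum(w)) stop("CDS offset out of range")
  if (model$strand == "-") {
    # transcription runs right to left
    ends <- rev(GenomicRanges::end(model$cds))
    starts <- rev(GenomicRanges::start(model$cds))
    w <- rev(w)
    k <- findInterval(offset, c(0L, cumsum(w)), rightmost.closed = TRUE)
    ends[k] - (offset - c(0L, cumsum(w))[k])
  } else {
    starts <- GenomicRanges::start(model$cds)
    k <- findInterval(offset, c(0L, cumsum(w)), rightmost.closed = TRUE)
    starts[k] + (offset - c(0L, cumsum(w))[k])
  }
}

#' Plant a coding SNP realizing a target amino-acid substitution
#'
#' Searches the model's CDS for a codon translating to `ref_aa` that can
#' reach `alt_aa` with a single base change, picks one (seeded RNG) and
#' returns the corresponding genomic SNP; minus-strand genes get the
#' reverse-complement base in genomic coordinates.
#'
#' @param model a scorable [transcript_model()].
#' @param seqs reference [Biostrings::DNAStringSet].
#' @param ref_aa,alt_aa one-letter amino acids of the substitution.
#' @param exclude_pos genomic positions to avoid.
#' @return list with `pos`, `ref`, `alt` (genomic), `ref_codon`,
#'   `alt_codon`, `codon_pos`, `ref_aa`, `alt_aa`, `residue_index`.
#' @export
plant_coding_snp <- function(model, seqs, ref_aa, alt_aa,
                             exclude_pos = integer(0)) {
  if (!model$scorable) stop("transcript ", model$tx_id, " is non-scorable")
  tab <- codon_table()
  # is the substitution reachable at all by one base change?
  reachable <- FALSE
  for (cod in names(tab)[tab == ref_aa]) {
    for (p in 1:3) {
      for (b in setdiff(.BASES, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        if (tab[[alt]] == alt_aa) reachable <- TRUE
      }
    }
  }
  if (!reachable) {
    stop("substitution ", ref_aa, ">", alt_aa,
         " is not realizable by a single base change")
  }
  cds <- spliced_cds(model, seqs)
  n_codons <- nchar(cds) %/% 3L
  candidates <- list()
  for (ci in seq_len(n_codons - 1L)[-1]) { # skip start and stop codons
    cod <- substr(cds, 3L * ci - 2L, 3L * ci)
    if (tab[[cod]] != ref_aa) next
    for (p in 1:3) {
      for (b in setdiff(.BASES, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        if (tab[[alt]] != alt_aa) next
        offset <- 3L * (ci - 1L) + (p - 1L)
        gpos <- cds_offset_to_genomic(model, offset)
        if (gpos %in% exclude_pos) next
        candidates[[length(candidates) + 1L]] <- list(
          pos = gpos,
          ref = if (model$strand == "-") revcomp(substr(cod, p, p)) else
            substr(cod, p, p),
          alt = if (model$strand == "-") revcomp(b) else b,
          ref_codon = cod, alt_codon = alt, codon_pos = p,
          ref_aa = ref_aa, alt_aa = alt_aa, residue_index = ci
        )
      }
    }
  }
  if (!length(candidates)) {
    stop("no available codon in ", model$tx_id, " realizes ",
         ref_aa, ">", alt_aa)
  }
  candidates[[sample.int(length(candidates), 1L)]]
}

.parse_sub <- function(x) {
  m <- regmatches(x, regexec("^([A-Z*])>([A-Z*])$", x))[[1]]
  if (length(m) != 3L) stop("substitution must look like 'T>P', got ", x)
  c(ref = m[2], alt = m[3])
}

#' Simulate a self-contained two-group resequencing dataset
#'
#' Generates a reference contig, gene models with realistic structure
#' (UTRs, multi-exon CDS divisible by 3, canonical GT/AG introns),
#' intronic CpG islands, promoter intervals, per-gene ortholog protein
#' alignments, and a two-group VCF with planted consensus SNPs in every
#' functional category plus discordant decoys — together with the ground
#' truth of everything planted. Byte-identical outputs for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all files are written
#'   (`ref.fa`, `genes.gff3`, `cpg_islands.bed`, `promoters.bed`,
#'   `variants.vcf`, `manifest.tsv`, `alignments/<gene>.faa`,
#'   `ground_truth.json`).
#' @return invisible list: `seqs`, `models`, `snps`, `manifest`, `truth`
#'   (data.frame), `cpg`, `promoters`, `alignments`, `paths` (when
#'   written).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_dataset_impl(config, out_dir))
}

.simulate_dataset_impl <- function(config, out_dir) {
  chrom <- config$chrom
  L <- as.integer(config$interval_length)
  n <- config$samples_per_group
  groups <- c("QQ", "qq")
  manifest <- sample_manifest(
    c(sprintf("QQ_%02d", seq_len(n)), sprintf("qq_%02d", seq_len(n))),
    rep(groups, each = n)
  )

  background <- .random_background(L)

  ## ---- genes -------------------------------------------------------
  n_islands_needed <- sum(vapply(config$planted, `[[`, integer(1), "CpG"))
  n_island_genes <- min(config$n_genes, max(2L, ceiling(n_islands_needed / 3L)))
  gene_ids <- sprintf("gene%02d", seq_len(config$n_genes))
  models <- list()
  island_ranges <- list()
  cursor <- 6000L
  for (i in seq_len(config$n_genes)) {
    strand <- if (i %% 2L == 0L) "-" else "+"
    hosts_island <- i <= n_island_genes
    g <- .build_gene_local(
      n_exons = sample(3:5, 1L),
      cds_codons = sample(150:350, 1L),
      utr5_len = sample(100:300, 1L),
      utr3_len = sample(150:400, 1L),
      long_intron1 = hosts_island
    )
    gs <- cursor
    ge <- gs + g$len - 1L
    if (ge + config$promoter_upstream + 4000L > L) {
      stop("interval_length too small for ", config$n_genes, " genes")
    }
    loc2gen <- function(iv) {
      if (strand == "-") cbind(start = gs + g$len - iv[, 2],
                               end = gs + g$len - iv[, 1])
      else cbind(start = gs - 1L + iv[, 1], end = gs - 1L + iv[, 2])
    }
    seq_chars <- strsplit(if (strand == "-") revcomp(g$seq) else g$seq,
                          "", fixed = TRUE)[[1]]
    background[gs:ge] <- seq_chars
    exn <- loc2gen(g$exons)
    cdn <- loc2gen(g$cds)
    if (hosts_island && !is.null(g$intron1)) {
      # island embedded mid-intron, clear of the splice windows
      iv <- g$intron1
      ilen <- 300L
      istart_local <- iv[1] + 500L
      if (istart_local + ilen - 1L <= iv[2] - 500L) {
        iseq <- .island_sequence(ilen)
        ig <- loc2gen(cbind(istart_local, istart_local + ilen - 1L))
        background[ig[1, "start"]:ig[1, "end"]] <-
          strsplit(if (strand == "-") revcomp(iseq) else iseq, "",
                   fixed = TRUE)[[1]]
        island_ranges[[length(island_ranges) + 1L]] <-
          c(ig[1, "start"], ig[1, "end"], i)
      }
    }
    models[[i]] <- transcript_model(
      gene_id = gene_ids[i], tx_id = paste0(gene_ids[i], ".t1"),
      exons = genomic_interval(chrom, exn[, "start"], exn[, "end"], strand),
      cds = genomic_interval(chrom, cdn[, "start"], cdn[, "end"], strand)
    )
    cursor <- ge + config$promoter_upstream + sample(2000:4000, 1L)
  }
  names(models) <- vapply(models, `[[`, character(1), "tx_id")
  seqs <- Biostrings::DNAStringSet(paste(background, collapse = ""))
  names(seqs) <- chrom

  cpg <- if (length(island_ranges)) {
    ir <- do.call(rbind, island_ranges)
    gr <- genomic_interval(chrom, ir[, 1], ir[, 2])
    gr$gene_id <- gene_ids[ir[, 3]]
    gr
  } else {
    GenomicRanges::GRanges()
  }
  promoters <- derive_promoters(models, upstream = config$promoter_upstream,
                                seq_lengths = setNames(L, chrom))

  ## ---- plant SNPs --------------------------------------------------
  used <- integer(0)
  truth <- list()
  base_at <- function(p) background[p]
  mutate <- function(ref) sample(setdiff(.BASES, ref), 1L)
  add_truth <- function(pos, ref, alt, category, group, gene_id,
                        support, expect_call, ref_codon = NA, alt_codon = NA,
                        ref_aa = NA, alt_aa = NA, residue_index = NA) {
    used <<- c(used, pos)
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, category = category,
      group = group, gene_id = gene_id, support = support,
      expect_call = expect_call, ref_codon = as.character(ref_codon),
      alt_codon = as.character(alt_codon), ref_aa = as.character(ref_aa),
      alt_aa = as.character(alt_aa),
      residue_index = as.integer(residue_index),
      stringsAsFactors = FALSE
    )
  }
  pick_from <- function(pool, k, label) {
    pool <- setdiff(pool, used)
    if (length(pool) < k) {
      stop("not enough positions to plant ", k, " ", label,
           " SNPs (", length(pool), " available)")
    }
    if (k == 0L) return(integer(0))
    sample(pool, k)
  }
  gr_pool <- function(gr) {
    unlist(lapply(seq_along(gr), function(i)
      seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))
  }

  prim <- primary_transcripts(models)
  coding_gene_pool <- rev(names(prim)) # distinct genes for coding SNPs

  # support counts: flagship QQ nsSNP always n-1; others Bernoulli(almost_frac)
  support_of <- function(is_flagship) {
    if (is_flagship || runif(1) < config$almost_frac) n - 1L else n
  }

  for (g in groups) {
    counts <- config$planted[[g]]
    # --- coding: nonsynonymous then synonymous
    subs <- config$target_substitutions[[g]]
    gene_cursor <- if (g == "QQ") 1L else 4L # distinct genes across groups
    for (k in seq_len(counts[["nsSNP"]])) {
      target <- if (k <= length(subs)) .parse_sub(subs[k]) else {
        repeat {
          cods <- sample(.sense_codons(), 1L)
          p <- sample(1:3, 1L); b <- mutate(substr(cods, p, p))
          altc <- cods; substr(altc, p, p) <- b
          if (codon_table()[[altc]] != "*" &&
              codon_table()[[altc]] != codon_table()[[cods]]) {
            break
          }
        }
        c(ref = codon_table()[[cods]], alt = codon_table()[[altc]])
      }
      planted <- NULL
      for (try in seq_along(coding_gene_pool)) {
        gene <- coding_gene_pool[gene_cursor]
        gene_cursor <- gene_cursor %% length(coding_gene_pool) + 1L
        planted <- tryCatch(
          plant_coding_snp(prim[[gene]], seqs, target[["ref"]],
                           target[["alt"]], exclude_pos = used),
          error = function(e) NULL
        )
        if (!is.null(planted)) break
      }
      if (is.null(planted)) {
        stop("could not realize substitution ", target[["ref"]], ">",
             target[["alt"]], " in any gene")
      }
      add_truth(planted$pos, planted$ref, planted$alt, "nsSNP", g, gene,
                support = support_of(g == "QQ" && k == 1L),
                expect_call = TRUE,
                ref_codon = planted$ref_codon, alt_codon = planted$alt_codon,
                ref_aa = planted$ref_aa, alt_aa = planted$alt_aa,
                residue_index = planted$residue_index)
    }
    for (k in seq_len(counts[["synonymous"]])) {
      planted <- NULL
      for (try in seq_along(coding_gene_pool)) {
        gene <- coding_gene_pool[gene_cursor]
        gene_cursor <- gene_cursor %% length(coding_gene_pool) + 1L
        # synonymous: same aa on both sides
        aa <- sample(c("L", "S", "R", "A", "G", "P", "T", "V"), 1L)
        planted <- tryCatch(
          plant_coding_snp(prim[[gene]], seqs, aa, aa, exclude_pos = used),
          error = function(e) NULL
        )
        if (!is.null(planted)) break
      }
      if (is.null(planted)) stop("could not plant a synonymous SNP")
      add_truth(planted$pos, planted$ref, planted$alt, "synonymous", g, gene,
                support = support_of(FALSE), expect_call = TRUE,
                ref_codon = planted$ref_codon, alt_codon = planted$alt_codon,
                ref_aa = planted$ref_aa, alt_aa = planted$alt_aa,
                residue_index = planted$residue_index)
    }
    # --- UTR
    utr_pool <- unlist(lapply(models, function(m)
      c(gr_pool(m$utr5), gr_pool(m$utr3))))
    for (p in pick_from(utr_pool, counts[["UTR"]], "UTR")) {
      gene <- NA_character_
      for (m in models) {
        if (any(p >= GenomicRanges::start(m$exons) &
                p <= GenomicRanges::end(m$exons))) gene <- m$gene_id
      }
      add_truth(p, base_at(p), mutate(base_at(p)), "UTR", g, gene,
                support = support_of(FALSE), expect_call = TRUE)
    }
    # --- splice (the canonical GT/AG dinucleotide bases)
    splice_pool <- unlist(lapply(models, function(m)
      gr_pool(.splice_windows(m, config$splice_window))))
    for (p in pick_from(splice_pool, counts[["splice"]], "splice")) {
      gene <- NA_character_
      for (m in models) {
        if (any(p >= GenomicRanges::start(m$exons[1]) &
                p <= max(GenomicRanges::end(m$exons)))) gene <- m$gene_id
      }
      add_truth(p, base_at(p), mutate(base_at(p)), "splice", g, gene,
                support = support_of(FALSE), expect_call = TRUE)
    }
    # --- CpG islands
    for (p in pick_from(gr_pool(cpg), counts[["CpG"]], "CpG")) {
      gene <- cpg$gene_id[
        p >= GenomicRanges::start(cpg) & p <= GenomicRanges::end(cpg)][1]
      add_truth(p, base_at(p), mutate(base_at(p)), "CpG", g, gene,
                support = support_of(FALSE), expect_call = TRUE)
    }
    # --- promoters
    for (p in pick_from(gr_pool(promoters), counts[["promoter"]],
                        "promoter")) {
      gene <- promoters$gene_id[
        p >= GenomicRanges::start(promoters) &
        p <= GenomicRanges::end(promoters)][1]
      add_truth(p, base_at(p), mutate(base_at(p)), "promoter", g, gene,
                support = support_of(FALSE), expect_call = TRUE)
    }
  }

  ## ---- decoys ------------------------------------------------------
  feature_pool <- unique(c(
    unlist(lapply(models, function(m) {
      sp <- range(GenomicRanges::granges(m$exons), ignore.strand = TRUE)
      gr_pool(sp)
    })),
    gr_pool(promoters), if (length(cpg)) gr_pool(cpg)
  ))
  intergenic_pool <- setdiff(seq(3000L, L - 3000L), feature_pool)
  for (p in pick_from(intergenic_pool, config$decoy_intergenic,
                      "intergenic consensus")) {
    g <- sample(groups, 1L)
    add_truth(p, base_at(p), mutate(base_at(p)), "intergenic-decoy", g,
              NA_character_, support = n, expect_call = TRUE)
  }
  decoy_patterns <- c("both-groups", "sub-threshold", "absence-violated",
                      "singleton")
  decoy_pos <- pick_from(intergenic_pool, config$decoy_discordant,
                         "discordant decoy")
  for (idx in seq_len(config$decoy_discordant)) {
    p <- decoy_pos[idx]
    pat <- decoy_patterns[(idx - 1L) %% length(decoy_patterns) + 1L]
    add_truth(p, base_at(p), mutate(base_at(p)), "discordant-decoy",
              pat, NA_character_, support = NA_integer_, expect_call = FALSE)
  }

  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  ## ---- genotypes ---------------------------------------------------
  geno <- matrix(0L, nrow(truth), 2L * n,
                 dimnames = list(NULL, manifest$sample))
  for (i in seq_len(nrow(truth))) {
    cat_i <- truth$category[i]
    if (cat_i == "discordant-decoy") {
      pat <- truth$group[i]
      qq_cols <- manifest$sample[manifest$group == "qq"]
      QQ_cols <- manifest$sample[manifest$group == "QQ"]
      if (pat == "both-groups") {
        geno[i, ] <- 2L
      } else if (pat == "sub-threshold") {
        geno[i, QQ_cols[seq_len(max(0L, n - 2L))]] <- 2L
      } else if (pat == "absence-violated") {
        geno[i, QQ_cols[seq_len(n - 1L)]] <- 2L
        geno[i, qq_cols[1L]] <- 1L
      } else { # singleton
        geno[i, qq_cols[1L]] <- 2L
      }
    } else {
      own <- manifest$sample[manifest$group == truth$group[i]]
      geno[i, own[seq_len(truth$support[i])]] <- 2L
    }
  }
  truth$group[truth$category == "discordant-decoy"] <- NA_character_
  snps <- snp_set(
    data.frame(chrom = chrom, pos = truth$pos, ref = truth$ref,
               alt = truth$alt, stringsAsFactors = FALSE),
    geno
  )
  truth$id <- snps$variants$id

  ## ---- ortholog alignments ----------------------------------------
  residues <- setdiff(rownames(aa_properties()), character(0))
  alignments <- list()
  for (gene in names(prim)) {
    prot <- translate_cds(spliced_cds(prim[[gene]], seqs))
    prot <- sub("\\*$", "", prot)
    refrow <- strsplit(prot, "", fixed = TRUE)[[1]]
    keep_cols <- truth$residue_index[
      truth$gene_id == gene & truth$category == "nsSNP" &
        !is.na(truth$residue_index)]
    aln <- matrix(rep(refrow, config$n_orthologs),
                  nrow = config$n_orthologs, byrow = TRUE)
    for (r in 2:config$n_orthologs) {
      flip <- runif(length(refrow)) >= config$conservation
      flip[keep_cols] <- FALSE
      for (j in which(flip)) {
        aln[r, j] <- if (runif(1) < 0.1) "-" else
          sample(setdiff(residues, refrow[j]), 1L)
      }
    }
    alignments[[gene]] <- aln
  }

  out <- list(
    seqs = seqs, models = models, snps = snps, manifest = manifest,
    truth = truth, cpg = cpg, promoters = promoters,
    alignments = alignments, config = config
  )

  ## ---- serialization ----------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "ref.fa"),
      gff3 = file.path(out_dir, "genes.gff3"),
      cpg = file.path(out_dir, "cpg_islands.bed"),
      promoters = file.path(out_dir, "promoters.bed"),
      vcf = file.path(out_dir, "variants.vcf"),
      manifest = file.path(out_dir, "manifest.tsv"),
      truth = file.path(out_dir, "ground_truth.json"),
      alignments = file.path(out_dir, "alignments")
    )
    Biostrings::writeXStringSet(seqs, paths$fasta)
    .write_gff3(models, paths$gff3)
    .write_bed(cpg, paths$cpg)
    .write_bed(promoters, paths$promoters)
    write_vcf(snps, paths$vcf, contigs = setNames(L, chrom))
    write_manifest(manifest, paths$manifest)
    jsonlite::write_json(truth, paths$truth, digits = NA, na = "null")
    for (gene in names(alignments)) {
      aln <- alignments[[gene]]
      ss <- Biostrings::AAStringSet(apply(aln, 1, paste, collapse = ""))
      names(ss) <- c(paste0(gene, "_ref"),
                     paste0(gene, "_ortholog", seq_len(nrow(aln) - 1L)))
      Biostrings::writeXStringSet(ss, file.path(paths$alignments,
                                                paste0(gene, ".faa")))
    }
    out$paths <- paths
  }
  invisible(out)
}

# minimal deterministic GFF3 serialization (gene/mRNA/exon/CDS)
.write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, s, e, strand, attrs, phase = ".") {
    paste(chrom, "snpconsensus", type, s, e, ".", strand, phase, attrs,
          sep = "\t")
  }
  for (m in models[order(vapply(models, `[[`, character(1), "tx_id"))]) {
    span <- range(GenomicRanges::granges(m$exons), ignore.strand = TRUE)
    lines <- c(lines,
      fmt(m$chrom, "gene", GenomicRanges::start(span),
          GenomicRanges::end(span), m$strand,
          paste0("ID=", m$gene_id)),
      fmt(m$chrom, "mRNA", GenomicRanges::start(span),
          GenomicRanges::end(span), m$strand,
          paste0("ID=", m$tx_id, ";Parent=", m$gene_id))
    )
    for (j in seq_along(m$exons)) {
      lines <- c(lines, fmt(
        m$chrom, "exon", GenomicRanges::start(m$exons)[j],
        GenomicRanges::end(m$exons)[j], m$strand,
        paste0("ID=", m$tx_id, ".exon", j, ";Parent=", m$tx_id)
      ))
    }
    cds <- if (m$strand == "-") rev(seq_along(m$cds)) else seq_along(m$cds)
    cum <- 0L
    for (j in cds) {
      phase <- (3L - cum %% 3L) %% 3L
      lines <- c(lines, fmt(
        m$chrom, "CDS", GenomicRanges::start(m$cds)[j],
        GenomicRanges::end(m$cds)[j], m$strand,
        paste0("ID=", m$tx_id, ".cds;Parent=", m$tx_id), phase
      ))
      cum <- cum + GenomicRanges::width(m$cds)[j]
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# BED6 (0-based half-open) serialization
.write_bed <- function(gr, path) {
  if (!length(gr)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if (!is.null(gr$gene_id)) gr$gene_id else "."
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  writeLines(paste(
    as.character(GenomicRanges::seqnames(gr)),
    internal_to_bed_start(GenomicRanges::start(gr)),
    GenomicRanges::end(gr), name, 0L, strand, sep = "\t"
  ), path)
  invisible(path)
}
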