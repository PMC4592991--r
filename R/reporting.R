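#' Category-count matrix of consensus SNPs in gene-related regions
#'
#' Tallies consensus calls into the report categories `nsSNP`, `UTR`,
#' `splice`, `CpG`, `promoter` per genotype group. A SNP carrying several
#' categories increments each once; `UTR5`/`UTR3` collapse into `UTR`;
#' coding calls count as `nsSNP` when their substitution status is
#' nonsynonymous-like (`nonsynonymous`, `nonsense`, `start-loss`).
#' Group and column totals are always recomputed from the cells, never
#' taken from input. Calls with no category land in buckets attached as
#' attributes: `"synonymous"` (coding but silent) and `"unlinked"`
#' (no gene-related feature at all).
#'
#' @param calls [call_consensus()] output.
#' @param annotations [annotate_variants()] output for the same calls.
#' @param effects optional [coding_effects()] output (enables the
#'   `nsSNP` column).
#' @return 3 x 6 integer matrix (rows `QQ`, `qq`, `Total`; columns
#'   `nsSNP`, `UTR`, `splice`, `CpG`, `promoter`, `Total`) with
#'   attributes `synonymous` and `unlinked` (counts).
#' @export
build_category_matrix <- function(calls, annotations, effects = NULL) {
  cols <- c("nsSNP", "UTR", "splice", "CpG", "promoter", "Total")
  m <- matrix(0L, 3L, 6L, dimnames = list(c("QQ", "qq", "Total"), cols))
  syn <- 0L
  unlinked <- 0L
  ns_ids <- if (!is.null(effects) && nrow(effects)) {
    unique(effects$id[effects$status %in%
                        c("nonsynonymous", "nonsense", "start-loss")])
  } else {
    character(0)
  }
  syn_ids <- if (!is.null(effects) && nrow(effects)) {
    unique(effects$id[effects$status == "synonymous"])
  } else {
    character(0)
  }
  for (i in seq_len(nrow(calls))) {
    id <- calls$id[i]
    g <- calls$group[i]
    cats <- annotations$category[annotations$id == id]
    cats <- cats[!is.na(cats)]
    hit <- character(0)
    if (id %in% ns_ids) hit <- c(hit, "nsSNP")
    if (any(cats %in% c("UTR5", "UTR3"))) hit <- c(hit, "UTR")
    if ("splice" %in% cats) hit <- c(hit, "splice")
    if ("CpG" %in% cats) hit <- c(hit, "CpG")
    if ("promoter" %in% cats) hit <- c(hit, "promoter")
    if (length(hit)) {
      m[g, hit] <- m[g, hit] + 1L
    } else if (id %in% syn_ids) {
      syn <- syn + 1L
    } else {
      unlinked <- unlinked + 1L
    }
  }
  m[, "Total"] <- rowSums(m[, cols[-6]])
  m["Total", ] <- colSums(m[c("QQ", "qq"), ])
  if (unlinked > 0L) {
    message("build_category_matrix: ", unlinked,
            " call(s) without gene-related annotation (unlinked bucket)")
  }
  attr(m, "synonymous") <- syn
  attr(m, "unlinked") <- unlinked
  m
}

#' Ranked nonsynonymous-SNP report
#'
#' One row per scored substitution with its consensus support, ordered
#' by descending conservation, ties by descending physicochemical score,
#' then by coordinate (`NA` conservation sorts last).
#'
#' @param scored [score_substitutions()] output.
#' @param calls [call_consensus()] output (provides group and support).
#' @return data.frame: `gene_id`, `group`, `chrom`, `coordinate`,
#'   `codon`, `substitution`, `support`, `physchem`, `conservation`.
#' @export
rank_effects <- function(scored, calls) {
  if (!nrow(scored)) {
    return(data.frame(
      gene_id = character(), group = character(), chrom = character(),
      coordinate = integer(), codon = character(),
      substitution = character(), support = character(),
      physchem = numeric(), conservation = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  j <- match(scored$id, calls$id)
  out <- data.frame(
    gene_id = scored$gene_id,
    group = calls$group[j],
    chrom = scored$chrom,
    coordinate = scored$pos,
    codon = paste0(scored$ref_codon, "/", scored$alt_codon),
    substitution = paste0(scored$ref_aa, scored$residue_index,
                          scored$alt_aa),
    support = paste0(calls$carriers[j], "/", calls$group_size[j]),
    physchem = scored$physchem,
    conservation = scored$conservation,
    stringsAsFactors = FALSE
  )
  ord <- order(-ifelse(is.na(out$conservation), -Inf, out$conservation),
               -out$physchem, out$coordinate)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full prioritization pipeline
#'
#' Reads the inputs, calls consensus SNPs, annotates them, computes and
#' scores coding effects, and writes every intermediate plus the two
#' final reports (`category_matrix.tsv`, `ranked_effects.tsv`) to
#' `out_dir`. Deterministic given fixed inputs.
#'
#' @param config named list (or path to a JSON file) with entries:
#'   `vcf`, `manifest`, `fasta`, `gff` (paths, required); `cpg_bed`,
#'   `promoters_bed`, `alignments_dir`, `matrix_tsv` (paths, optional);
#'   `out_dir` (required); and optional parameters `presence_min`,
#'   `absence_max`, `carrier_rule`, `missing_rule`, `splice_window`,
#'   `promoter_upstream`, `conservation_method`.
#' @return invisible list: `calls`, `annotations`, `effects`, `scored`,
#'   `matrix`, `ranked`, `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  need <- c("vcf", "manifest", "fasta", "gff", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("pipeline config is missing: ",
                         paste(miss, collapse = ", "))
  cfg <- modifyList(list(
    presence_min = NULL, absence_max = 0L, carrier_rule = "any-alt",
    missing_rule = "lenient", splice_window = 2L,
    promoter_upstream = 2000L, promoter_downstream = 0L,
    conservation_method = "identity",
    cpg_bed = NULL, promoters_bed = NULL, alignments_dir = NULL,
    matrix_tsv = NULL
  ), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- stage("manifest", read_manifest(cfg$manifest))
  seqs <- stage("reference", read_reference(cfg$fasta))
  models <- stage("gene_models", read_gene_models(cfg$gff))
  snps <- stage("vcf", read_vcf(cfg$vcf, manifest, ref_seqs = seqs))
  seq_lengths <- setNames(Biostrings::width(seqs), names(seqs))
  cpg <- if (!is.null(cfg$cpg_bed)) {
    stage("cpg_bed", .read_bed_intervals(cfg$cpg_bed))
  } else {
    stage("cpg_detect", detect_cpg_islands(
      seqs[[1]], chrom = names(seqs)[1]
    ))
  }
  promoters <- if (!is.null(cfg$promoters_bed)) {
    stage("promoters_bed", .read_bed_intervals(cfg$promoters_bed))
  } else {
    derive_promoters(models, upstream = cfg$promoter_upstream,
                     downstream = cfg$promoter_downstream,
                     seq_lengths = seq_lengths)
  }
  alignments <- if (!is.null(cfg$alignments_dir)) {
    stage("alignments", read_alignments(cfg$alignments_dir))
  } else {
    list()
  }
  dist_matrix <- if (!is.null(cfg$matrix_tsv)) {
    stage("matrix", read_distance_matrix(cfg$matrix_tsv))
  } else {
    grantham_matrix()
  }

  calls <- stage("consensus", call_consensus(
    snps, manifest, presence_min = cfg$presence_min,
    absence_max = cfg$absence_max, carrier_rule = cfg$carrier_rule,
    missing_rule = cfg$missing_rule
  ))
  annotations <- stage("annotation", annotate_variants(
    calls, models, cpg = cpg, promoters = promoters,
    splice_window = cfg$splice_window
  ))
  effects <- stage("coding_effects", coding_effects(calls, models, seqs))
  ns <- effects[effects$status %in% c("nonsynonymous", "start-loss"), ,
                drop = FALSE]
  scored <- stage("scoring", score_substitutions(
    ns, alignments, matrix = dist_matrix, method = cfg$conservation_method
  ))
  mat <- stage("matrix_build",
               build_category_matrix(calls, annotations, effects))
  ranked <- stage("ranking", rank_effects(scored, calls))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    consensus = file.path(cfg$out_dir, "consensus.tsv"),
    annotations = file.path(cfg$out_dir, "annotations.tsv"),
    effects = file.path(cfg$out_dir, "effects.tsv"),
    scores = file.path(cfg$out_dir, "scores.tsv"),
    matrix = file.path(cfg$out_dir, "category_matrix.tsv"),
    ranked = file.path(cfg$out_dir, "ranked_effects.tsv")
  )
  write_report_tsv(calls, files$consensus)
  write_report_tsv(annotations, files$annotations)
  write_report_tsv(effects, files$effects)
  write_report_tsv(scored, files$scores)
  mat_df <- data.frame(group = rownames(mat), as.data.frame(mat),
                       check.names = FALSE)
  utils::write.table(mat_df, files$matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # ranked report keeps its ranking order (documented sort key)
  utils::write.table(ranked, files$ranked, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(
    calls = calls, annotations = annotations, effects = effects,
    scored = scored, matrix = mat, ranked = ranked, files = files
  ))
}

.read_bed_intervals <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gr <- genomic_interval(
    df[[1]], bed_to_internal_start(df[[2]]), df[[3]],
    strand = if (ncol(df) >= 6) ifelse(df[[6]] == ".", "*", df[[6]]) else "*"
  )
  if (ncol(df) >= 4) gr$gene_id <- ifelse(df[[4]] == ".", NA, df[[4]])
  gr
}
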