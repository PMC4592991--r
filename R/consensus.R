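#' Call consensus SNPs between two QTL genotype groups
#'
#' A *consensus SNP* is carried by (almost) every sample of one genotype
#' group and absent from every sample of the other. "Carried" is
#' controlled by `carrier_rule`: `"any-alt"` counts heterozygotes as
#' carriers, `"hom-alt"` requires homozygous-alt. A variant can satisfy
#' the rule for at most one group as long as
#' `presence_min > absence_max`, which is enforced.
#'
#' Missing genotypes (`./.`) never count as carriers; under
#' `missing_rule = "lenient"` (default) they also do not violate absence
#' in the opposite group, under `"strict"` a missing genotype in the
#' opposite group is treated as a potential carrier and blocks the call.
#'
#' @param snps a [snp_set()].
#' @param manifest a [sample_manifest()] covering every genotype column.
#' @param presence_min minimum carriers in the concordant group; default
#'   group size minus one ("almost every sample").
#' @param absence_max maximum carriers tolerated in the other group
#'   (default 0: strictly absent).
#' @param carrier_rule `"any-alt"` or `"hom-alt"`.
#' @param missing_rule `"lenient"` or `"strict"` (see Details).
#' @return data.frame of consensus calls: `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `group`, `carriers`, `group_size`, `carriers_other`.
#' @examples
#' m <- sample_manifest(paste0("s", 1:4), c("QQ", "QQ", "qq", "qq"))
#' g <- rbind(c(2L, 2L, 0L, 0L))
#' colnames(g) <- m$sample
#' v <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "C")
#' call_consensus(snp_set(v, g), m)
#' @export
call_consensus <- function(snps, manifest,
                           presence_min = NULL, absence_max = 0L,
                           carrier_rule = c("any-alt", "hom-alt"),
                           missing_rule = c("lenient", "strict")) {
  carrier_rule <- match.arg(carrier_rule)
  missing_rule <- match.arg(missing_rule)
  stopifnot(inherits(snps, "snp_set"))
  if (!all(colnames(snps$geno) %in% manifest$sample)) {
    stop("genotype column not in manifest: ",
         setdiff(colnames(snps$geno), manifest$sample)[1])
  }
  groups <- c("QQ", "qq")
  members <- lapply(groups, function(g)
    intersect(manifest$sample[manifest$group == g], colnames(snps$geno)))
  names(members) <- groups
  sizes <- lengths(members)
  if (any(sizes == 0L)) stop("both groups must have genotyped samples")
  if (is.null(presence_min)) presence_min <- min(sizes) - 1L
  if (presence_min <= absence_max) {
    stop("non-discriminating configuration: presence_min (", presence_min,
         ") must exceed absence_max (", absence_max, ")")
  }
  if (presence_min > max(sizes)) {
    stop("presence_min (", presence_min, ") exceeds group size (",
         max(sizes), ")")
  }

  is_carrier <- function(g) {
    if (carrier_rule == "any-alt") !is.na(g) & g >= 1L else !is.na(g) & g == 2L
  }
  out <- vector("list", 2L)
  for (gi in 1:2) {
    own <- members[[groups[gi]]]
    oth <- members[[groups[3 - gi]]]
    carry_own <- is_carrier(snps$geno[, own, drop = FALSE])
    carry_oth <- is_carrier(snps$geno[, oth, drop = FALSE])
    n_own <- rowSums(carry_own)
    n_oth <- rowSums(carry_oth)
    if (missing_rule == "strict") {
      n_oth <- n_oth + rowSums(is.na(snps$geno[, oth, drop = FALSE]))
    }
    hit <- n_own >= presence_min & n_oth <= absence_max
    if (any(hit)) {
      v <- snps$variants[hit, , drop = FALSE]
      out[[gi]] <- data.frame(
        id = v$id, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        group = groups[gi], carriers = as.integer(n_own[hit]),
        group_size = length(own),
        carriers_other = as.integer(rowSums(carry_oth)[hit]),
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(
      id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), group = character(),
      carriers = integer(), group_size = integer(),
      carriers_other = integer(), stringsAsFactors = FALSE
    )
  }
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Per-group consensus-call totals
#'
#' @param calls output of [call_consensus()].
#' @return list with elements `QQ`, `qq` and `total` (their sum).
#' @export
summarize_concordance <- function(calls) {
  n_QQ <- sum(calls$group == "QQ")
  n_qq <- sum(calls$group == "qq")
  list(QQ = n_QQ, qq = n_qq, total = n_QQ + n_qq)
}
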