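#' Amino-acid physicochemical property values (composition, polarity, volume)
#'
#' The classic property triple behind the Grantham distance: atomic
#' composition c (non-carbon atoms on side chains), polarity p and
#' molecular volume v.
#'
#' @return 20 x 3 numeric matrix, rows named by one-letter amino acid.
#' @export
aa_properties <- function() {
  m <- rbind(
    S = c(1.42, 9.2, 32), R = c(0.65, 10.5, 124), L = c(0, 4.9, 111),
    P = c(0.39, 8.0, 32.5), T = c(0.71, 8.6, 61), A = c(0, 8.1, 31),
    V = c(0, 5.9, 84), G = c(0.74, 9.0, 3), I = c(0, 5.2, 111),
    F = c(0, 5.2, 132), Y = c(0.20, 6.2, 136), C = c(2.75, 5.5, 55),
    H = c(0.58, 10.4, 96), Q = c(0.89, 10.5, 85), N = c(1.33, 11.6, 56),
    K = c(0.33, 11.3, 119), D = c(1.38, 13.0, 54), E = c(0.92, 12.3, 83),
    M = c(0, 5.7, 105), W = c(0.13, 5.4, 170)
  )
  colnames(m) <- c("composition", "polarity", "volume")
  m
}

.grantham_cache <- NULL

#' Grantham amino-acid distance matrix
#'
#' Recomputed from the property values with the published weighting
#' (`D = rho * sqrt(1.833 dc^2 + 0.1018 dp^2 + 0.000399 dv^2)`, `rho`
#' scaling the mean of the 190 pairwise distances to 100) and rounded to
#' integers. Reproduces the well-known entries (L-I = 5, C-W = 215 = the
#' matrix maximum); a handful of cells differ by 1 from commonly
#' reprinted tables due to rounding.
#'
#' @return symmetric 20 x 20 integer matrix with zero diagonal.
#' @export
grantham_matrix <- function() {
  if (!is.null(.grantham_cache)) return(.grantham_cache)
  p <- aa_properties()
  n <- nrow(p)
  raw <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      raw[i, j] <- sqrt(
        1.833 * (p[i, 1] - p[j, 1])^2 +
        0.1018 * (p[i, 2] - p[j, 2])^2 +
        0.000399 * (p[i, 3] - p[j, 3])^2
      )
    }
  }
  d <- round(raw * 100 / mean(raw[upper.tri(raw)]))
  utils::assignInMyNamespace(".grantham_cache", d)
  d
}

#' Read a substitution-distance matrix from TSV
#'
#' Expects a 20 x 20 symmetric, nonnegative, zero-diagonal table with
#' one-letter amino-acid row and column names.
#'
#' @param path TSV path.
#' @return validated numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  validate_distance_matrix(m)
  m
}

validate_distance_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !identical(rownames(m), colnames(m))) {
    stop("distance matrix must be square with matching dimnames")
  }
  if (any(m < 0) || any(diag(m) != 0) || !isTRUE(all.equal(m, t(m)))) {
    stop("distance matrix must be symmetric, nonnegative, zero-diagonal")
  }
  invisible(m)
}

#' Physicochemical-change score of an amino-acid substitution
#'
#' `distance(ref, alt) / max(matrix)`, guaranteeing a score in \[0,1\]
#' with 0 for identity substitutions ("0 is neutral"). The default matrix
#' is the Grantham distance; any symmetric nonnegative zero-diagonal
#' matrix can be plugged in.
#'
#' @param ref_aa,alt_aa one-letter amino acids (vectors recycle).
#' @param matrix distance matrix (default [grantham_matrix()]).
#' @return numeric score(s) in \[0,1\].
#' @examples
#' physchem_score("L", "I") # 5/215, a near-neutral pair
#' @export
physchem_score <- function(ref_aa, alt_aa, matrix = grantham_matrix()) {
  validate_distance_matrix(matrix)
  bad <- !(ref_aa %in% rownames(matrix)) | !(alt_aa %in% rownames(matrix))
  if (any(bad)) {
    stop("not a standard amino acid: ",
         paste(unique(c(ref_aa[bad], alt_aa[bad])), collapse = ", "))
  }
  unname(matrix[cbind(ref_aa, alt_aa)] / max(matrix))
}

#' Conservation score of an alignment column
#'
#' Default rule (`"identity"`): the fraction of non-gap symbols equal to
#' the reference residue. Alternative rule (`"entropy"`): one minus the
#' Shannon entropy of the non-gap residue distribution normalized by
#' `log(20)`. Both lie in \[0,1\], higher = more conserved. An all-gap
#' column has no defined conservation and returns `NA` (flagged absent,
#' never 0).
#'
#' @param column character vector of one-letter residues (`"-"` = gap).
#' @param reference reference residue for the identity rule (default:
#'   first non-gap symbol).
#' @param method `"identity"` or `"entropy"`.
#' @return numeric score in \[0,1\], or `NA` for an all-gap column.
#' @export
conservation_score <- function(column, reference = NULL,
                               method = c("identity", "entropy")) {
  method <- match.arg(method)
  if (!length(column)) stop("empty alignment column")
  res <- column[column != "-"]
  if (!length(res)) return(NA_real_)
  if (method == "identity") {
    if (is.null(reference)) reference <- res[1]
    return(sum(res == reference) / length(res))
  }
  p <- table(res) / length(res)
  h <- -sum(p * log(p))
  max(0, 1 - h / log(20))
}

#' Read per-gene protein alignments (aligned FASTA)
#'
#' @param dir directory of `<gene_id>.faa` aligned FASTA files, or a
#'   character vector of file paths.
#' @return named list of character matrices (sequences x columns).
#' @export
read_alignments <- function(dir) {
  paths <- if (length(dir) == 1L && dir.exists(dir)) {
    list.files(dir, pattern = "\\.(faa|fa|fasta)(\\.gz)?$", full.names = TRUE)
  } else {
    dir
  }
  out <- lapply(paths, function(p) {
    aln <- Biostrings::readAAStringSet(p)
    w <- Biostrings::width(aln)
    if (length(unique(w)) != 1L) stop("unaligned sequences in ", p)
    do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
  })
  names(out) <- sub("\\.(faa|fa|fasta)(\\.gz)?$", "", basename(paths))
  out
}

#' Score nonsynonymous substitutions
#'
#' Attaches the two-component effect score to each substitution: the
#' physicochemical-change score (always computable) and the conservation
#' score at the substituted residue of the gene's ortholog alignment.
#' Substitutions without an alignment, with a residue index beyond the
#' alignment length, or hitting an all-gap column get `NA` conservation
#' (flagged absent, logged), never an invented 0.
#'
#' @param effects data.frame from [coding_effects()]; every row must be
#'   nonsynonymous-like (`nonsynonymous` or `start-loss`; `nonsense` and
#'   `synonymous` rows are rejected — stops have no property distance).
#' @param alignments named list of character matrices keyed by gene id
#'   (see [read_alignments()]); the first row is the reference protein.
#' @param matrix substitution-distance matrix (default Grantham).
#' @param method conservation rule, see [conservation_score()].
#' @return `effects` with `physchem` and `conservation` columns appended,
#'   input order preserved.
#' @export
score_substitutions <- function(effects, alignments = list(),
                                matrix = grantham_matrix(),
                                method = c("identity", "entropy")) {
  method <- match.arg(method)
  if (!nrow(effects)) {
    effects$physchem <- numeric(0)
    effects$conservation <- numeric(0)
    return(effects)
  }
  bad <- !effects$status %in% c("nonsynonymous", "start-loss")
  if (any(bad)) {
    stop("only nonsynonymous substitutions can be scored; got status '",
         effects$status[bad][1], "' at ", effects$chrom[bad][1], ":",
         effects$pos[bad][1])
  }
  effects$physchem <- physchem_score(effects$ref_aa, effects$alt_aa, matrix)
  cons <- rep(NA_real_, nrow(effects))
  for (i in seq_len(nrow(effects))) {
    aln <- alignments[[effects$gene_id[i]]]
    if (is.null(aln)) next
    ri <- effects$residue_index[i]
    if (ri > ncol(aln)) {
      message("score_substitutions: residue ", ri, " beyond alignment for ",
              effects$gene_id[i], "; conservation flagged absent")
      next
    }
    cons[i] <- conservation_score(aln[, ri], reference = effects$ref_aa[i],
                                  method = method)
  }
  effects$conservation <- cons
  effects
}
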