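---
title: "Prioritizing candidate causal SNPs in a fine-mapped QTL interval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate causal SNPs in a fine-mapped QTL interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpconsensus)
```

## The problem

Fine mapping narrows a quantitative trait locus (QTL) to an interval of
roughly a megabase, but that interval still holds thousands of variants
and a dozen genes. Targeted resequencing of individuals that are
homozygous for opposite QTL alleles (call the groups `QQ` and `qq`)
gives a direct way to shortlist candidates: a causal variant must track
the QTL genotype, so variants carried by (almost) every `QQ` bird and by
no `qq` bird — or vice versa — are the interesting ones. We call these
**consensus SNPs**. The package implements that filter, classifies
consensus SNPs by gene-related functional context, and ranks the coding
ones by their predicted effect on the protein.

## The procedure

1. **Consensus calling** (`call_consensus()`). For each biallelic SNP
   the carriers per group are counted. A SNP is a consensus SNP for
   group $g$ when

   $$\#\{\text{carriers in } g\} \ge k_\text{presence}
     \quad\text{and}\quad
     \#\{\text{carriers in the other group}\} \le k_\text{absence}.$$

   Defaults are $k_\text{presence} = n - 1$ (with $n$ the group size,
   capturing "almost every sample": a variant missed in a single bird —
   by chance, a miscall, or residual heterozygosity — should not be
   discarded) and $k_\text{absence} = 0$ (strict absence). Because
   $k_\text{presence} > k_\text{absence}$ is enforced, a SNP can be
   concordant with at most one group. The carrier definition is a
   parameter: `any-alt` (default; heterozygotes carry) or `hom-alt`.
   The samples are nominally homozygous at the QTL, but individual
   sites can still be heterozygous, hence the lenient default. Missing
   genotypes count as neither carriers nor absence violations; a strict
   mode treats a missing genotype in the opposite group as a potential
   carrier.

2. **Functional annotation** (`annotate_variants()`). Each consensus
   SNP is assigned every category it overlaps: `CDS`, `UTR5`/`UTR3`,
   `splice` (within 2 intronic bases of an exon–intron boundary — the
   canonical GT/AG dinucleotides; configurable up to wider windows),
   `CpG` (island intervals) and `promoter`. A SNP may carry several
   categories and is reported once per gene per category.

3. **Coding effects** (`coding_effects()`, `map_to_codon()`). For SNPs
   in coding sequence the CDS offset is computed by concatenating CDS
   intervals in transcription order (minus-strand models are
   reverse-complemented), the reference and alternate codons are
   assembled from the *spliced* CDS — so codons split across splice
   junctions are handled correctly — and translated with the standard
   genetic code. Residue index is $\lfloor o/3 \rfloor + 1$ for 0-based
   CDS offset $o$. One transcript represents each gene: the one with
   the longest CDS, ties broken by smallest transcript id (isoform
   choice is not specified by the underlying study; this rule is
   deterministic and favors the most complete protein).

4. **Effect scoring** (`score_substitutions()`). Nonsynonymous
   substitutions get a two-component score, each component in $[0,1]$
   with 0 neutral:

   * **physicochemical change** — the Grantham distance between the
     two residues divided by the matrix maximum (215, the Cys–Trp
     pair). The matrix is recomputed from the published composition /
     polarity / volume property values with the mean-100 scaling; a few
     cells differ by ±1 from commonly reprinted tables because of the
     rounding of the scale constant, and the normalization makes the
     $[0,1]$ contract exact. Any symmetric, nonnegative, zero-diagonal
     matrix can be substituted.
   * **conservation** — by default the fraction of non-gap residues in
     the ortholog-alignment column that match the reference residue; an
     entropy-based variant ($1 - H/\log 20$) is available. A missing
     alignment, a residue beyond the alignment, or an all-gap column
     yields an *absent* conservation score (`NA`), never a fabricated 0.

   The two components are reported separately, never collapsed into a
   single number, because they answer different questions (how drastic
   is the exchange vs how intolerant is the site).

5. **Reporting** (`build_category_matrix()`, `rank_effects()`,
   `run_pipeline()`). The category matrix counts consensus SNPs per
   group per category; a multi-category SNP increments each of its
   categories once. Totals are always recomputed from the cells —
   printed tables in the literature occasionally disagree with their
   own marginals, so user-supplied totals are never trusted. The ranked
   report orders substitutions by descending conservation, ties by
   descending physicochemical score, then coordinate; the informal
   notion of "ranking by effect" needs a total order to be
   deterministic, and conservation is put first because an exchange at
   an invariant site is the stronger signal.

## Coordinates

Internally everything is 1-based, closed-interval, carried in
`GenomicRanges` objects — the universal Bioconductor convention. VCF
and GFF3 positions map through unchanged; BED input/output shifts the
start by one. These converters are the only places an offset appears.

## The synthetic world

`simulate_dataset()` builds a fully self-contained dataset emulating
the targeted-resequencing design: a single ~1.2 Mb contig, 13 genes
with realistic structure (5′/3′ UTRs, 3–5 exons, in-frame CDS starting
ATG and ending in a stop, canonical GT/AG introns, strands
alternating), intronic GC/CpG-rich islands written into the sequence,
2 kb promoters, and two groups of 5 samples. The background sequence is
CpG-depleted (as real vertebrate sequence is) so islands stand out.

Planted SNPs come with a serialized ground truth. Default per-category
counts per group restate the category-count table of the motivating
study (QQ: 3 nsSNP, 28 UTR, 1 splice, 3 CpG, 23 promoter; qq: 1 nsSNP,
25 UTR, 3 splice, 5 CpG, 38 promoter) plus two synonymous coding SNPs
per group. The first QQ nonsynonymous SNP always has support $n-1$ of
$n$ — the "4/5" case — and a 10% fraction of the other planted SNPs
drop one carrier, a realistic missed-call rate at high coverage. The
default nonsynonymous substitutions are T→P, G→S, F→I (QQ) and A→G
(qq), realized wherever a single-base change in some codon can produce
them (`plant_coding_snp()`); their alignment columns are fully
conserved so the planted conservation score is exactly 1. Negative
space is stressed by two decoy kinds: *discordant decoys* (present in
both groups, sub-threshold support, absence violations, singletons)
that must never be called, and *intergenic consensus decoys* that
genuinely satisfy the consensus rule but overlap no gene-related
feature, so they must be called yet land in no category.

What the generator deliberately does **not** model: read-level noise
(no FASTQ, no sequencing-error or coverage model), linkage structure
beyond group concordance, transition/transversion bias (mutations are
uniform over the three alternatives), overlapping genes and isoforms.
A green planted-truth test therefore establishes the correctness of the
bookkeeping — consensus logic, interval arithmetic, strand handling,
codon mapping, counting — not robustness to miscalled genotypes or
annotation errors.

## Numerical and degenerate-input choices

* CpG islands (when no interval file is supplied;
  `detect_cpg_islands()`): the classic window criteria — length ≥ 200,
  GC ≥ 0.5, CpG observed/expected ≥ 0.6 with
  $\text{obs/exp} = N_{CG} \cdot L / (N_C \cdot N_G)$. An island is a
  maximal run of positions covered by at least one qualifying window of
  exactly the minimum length; every reported position is thus inside a
  window that satisfies all three criteria, and island-level GC and
  obs/exp are reported. In rare corner cases the merged run as a whole
  can dilute below a threshold; `strict = TRUE` trims run ends until
  the whole island qualifies. Windows containing `N` are skipped and
  counted. A supplied island file always wins over detection.
* A transcript whose CDS length is not divisible by 3 loads with a
  non-scorable flag; asking for its codon effects is an error naming
  the transcript, never a silent frame guess.
* Multiallelic VCF records are split into biallelic records; each alt
  allele is tested for consensus independently. Indel and other
  non-SNP alleles are skipped with a logged count.
* REF alleles are checked against the reference sequence whenever one
  is supplied; a mismatch is an error with the offending coordinate.
* Out-of-range sequence lookups are errors, never silent truncation.

## Known limitations

* One transcript per gene for coding effects; effects on minor
  isoforms are not reported.
* Conservation requires a user-supplied (or simulated) protein
  alignment; the package does not fetch orthologs.
* The consensus rule is a deterministic filter, not an association
  test; no allele-frequency modeling, phasing or imputation.
* Study-scale SNP counts from the motivating experiment depend on its
  raw sequencing data and annotation snapshot and are out of scope; the
  package reproduces the method, the worked codon examples and the
  table arithmetic, as exercised in `tests/testthat/test-acceptance.R`.
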