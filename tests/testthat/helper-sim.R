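# cached synthetic datasets so the suite simulates each world once

.sim_env <- new.env(parent = emptyenv())

# compact world for unit tests: same structure, smaller counts
small_config <- function(seed = 7, ...) {
  sim_config(
    seed = seed,
    interval_length = 300000L,
    n_genes = 6L,
    planted = list(
      QQ = c(nsSNP = 2L, synonymous = 1L, UTR = 5L, splice = 1L,
             CpG = 2L, promoter = 4L),
      qq = c(nsSNP = 1L, synonymous = 1L, UTR = 4L, splice = 2L,
             CpG = 2L, promoter = 5L)
    ),
    decoy_discordant = 12L,
    decoy_intergenic = 4L,
    ...
  )
}

small_sim <- function() {
  if (is.null(.sim_env$small)) {
    dir <- file.path(tempdir(), "snpconsensus-small-sim")
    .sim_env$small <- simulate_dataset(small_config(), out_dir = dir)
  }
  .sim_env$small
}

# the stated world: default config, seed 42
default_sim <- function() {
  if (is.null(.sim_env$default)) {
    dir <- file.path(tempdir(), "snpconsensus-default-sim")
    .sim_env$default <- simulate_dataset(sim_config(seed = 42),
                                         out_dir = dir)
  }
  .sim_env$default
}

default_pipeline <- function() {
  if (is.null(.sim_env$default_run)) {
    p <- default_sim()$paths
    .sim_env$default_run <- run_pipeline(list(
      vcf = p$vcf, manifest = p$manifest, fasta = p$fasta, gff = p$gff3,
      cpg_bed = p$cpg, promoters_bed = p$promoters,
      alignments_dir = p$alignments,
      out_dir = file.path(tempdir(), "snpconsensus-default-out")
    ))
  }
  .sim_env$default_run
}
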