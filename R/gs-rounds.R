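#' Run the recursive genome-shuffling protocol
#'
#' Simulates the full breeding scheme: a wild-type haploid pool is UV
#' mutagenized, pre-enriched by `founder_boost` rounds of truncation
#' selection (this is how a single multi-mutation founder clone comes to
#' dominate the UV pool), and archived as the `UV` sample. Each shuffling
#' round then applies selection to the haploid pool, mates it pool-wise,
#' archives the resulting diploid pool as that round's sample (the pool
#' frozen for population sequencing and from which tolerant colonies are
#' picked), sporulates it, and selects among the spores to seed the next
#' round.
#'
#' @param config a [sim_config()]; `config$seed` drives all randomness.
#' @param catalogue a [locus_catalogue()].
#' @param founder_loci optional character vector of catalogue locus ids
#'   carried jointly by a founder clone: after mutagenesis,
#'   `config$founder_cells` genomes of each mating type additionally
#'   receive the alternate allele at these loci, and the `founder_boost`
#'   selection rounds then let the clone rise to pool dominance
#'   emergently. This reproduces the inferred UV architecture — several
#'   mutations at virtually identical pool frequency because they entered
#'   on a single highly tolerant haploid.
#' @return A named list of population samples: `UV` (haploid), then `R1`,
#'   `R2`, ... (diploid), one per round.
#' @export
run_gs_rounds <- function(config, catalogue, founder_loci = NULL) {
  config <- validate_sim_config(config)
  catalogue <- validate_locus_catalogue(catalogue)
  set.seed(config$seed)

  uv <- uv_mutagenize(wildtype_pool(config$population_size, catalogue), config)
  if (!is.null(founder_loci)) {
    cols <- match(founder_loci, catalogue$id)
    abort_if(anyNA(cols), "founder_loci absent from catalogue: ",
             paste(founder_loci[is.na(cols)], collapse = ", "))
    for (mt in c("a", "alpha")) {
      pool_mt <- which(uv$mating_type == mt)
      rows <- pool_mt[sample.int(length(pool_mt),
                                 min(config$founder_cells, length(pool_mt)))]
      uv$alleles[rows, cols] <- 1L
    }
  }
  for (i in seq_len(config$founder_boost)) uv <- select_population(uv, config)
  uv$round_label <- "UV"
  samples <- list(UV = uv)

  pool <- uv
  for (r in seq_len(config$rounds)) {
    label <- paste0("R", r)
    selected <- select_population(pool, config)
    diploids <- mate_pool(selected)
    diploids$round_label <- label
    samples[[label]] <- diploids
    spores <- sporulate_pool(diploids, config)
    pool <- select_population(spores, config)
    pool$round_label <- label
  }
  samples
}
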