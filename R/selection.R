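#' Truncation selection on a population sample
#'
#' Models gradient-plate screening: genomes are ranked by additive fitness
#' plus Gaussian noise, the top `selection_fraction` are kept (ties broken
#' uniformly at random), and the survivors are multinomially resampled back
#' to `population_size`.
#'
#' @param pop a `haploid_pop` or `diploid_pop`.
#' @param config a [sim_config()] supplying `selection_fraction`,
#'   `fitness_noise_sd` and `population_size`.
#' @return A population sample of the same ploidy and label.
#' @export
select_population <- function(pop, config) {
  n <- n_genomes(pop)
  abort_if(n == 0L, "cannot select from an empty population")
  w <- genome_fitness(pop) + stats::rnorm(n, 0, config$fitness_noise_sd)
  n_keep <- max(1L, ceiling(config$selection_fraction * n))
  # random tiebreak: order by (w, uniform jitter)
  keep <- order(w, stats::runif(n), decreasing = TRUE)[seq_len(n_keep)]
  idx <- keep[sample.int(n_keep, config$population_size, replace = TRUE)]
  subset_pop(pop, idx)
}

subset_pop <- function(pop, idx) {
  if (is_haploid(pop)) {
    haploid_pop(pop$alleles[idx, , drop = FALSE], pop$mating_type[idx],
                pop$catalogue, pop$round_label, tetrad = pop$tetrad[idx])
  } else {
    diploid_pop(pop$hap1[idx, , drop = FALSE], pop$hap2[idx, , drop = FALSE],
                pop$catalogue, pop$round_label)
  }
}
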