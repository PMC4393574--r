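#' UV mutagenesis of a haploid pool
#'
#' Each genome independently gains alternate alleles at a Poisson-distributed
#' number of catalogue loci drawn uniformly without replacement (draws are
#' capped at the catalogue size for the rare genome whose Poisson draw
#' exceeds it). Mating types are untouched.
#'
#' @param pop a haploid [haploid_pop()] (the wild-type pool).
#' @param config a [sim_config()]; `uv_mutation_rate` is the Poisson mean and
#'   must not exceed the catalogue size.
#' @return A mutagenized `haploid_pop`.
#' @export
uv_mutagenize <- function(pop, config) {
  abort_if(!is_haploid(pop), "uv_mutagenize requires a haploid pool")
  n_loci <- ncol(pop$alleles)
  rate <- config$uv_mutation_rate
  abort_if(rate > n_loci,
           "uv_mutation_rate (", rate, ") exceeds catalogue size (", n_loci,
           "): cannot draw loci without replacement")
  if (rate == 0) return(pop)
  n <- nrow(pop$alleles)
  k <- pmin(stats::rpois(n, rate), n_loci)
  alleles <- pop$alleles
  for (i in which(k > 0L)) {
    hit <- sample.int(n_loci, k[i])
    alleles[i, hit] <- 1L
  }
  haploid_pop(alleles, pop$mating_type, pop$catalogue, pop$round_label,
              tetrad = pop$tetrad)
}
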