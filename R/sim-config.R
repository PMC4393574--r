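#' Simulation configuration for the genome-shuffling protocol
#'
#' Parameters of the forward-time simulator: the mutagenized pool size, the
#' UV mutational load, the strength of gradient-plate (truncation) selection,
#' and the breeding schedule. Gradient-plate selection is modelled as
#' additive-fitness truncation selection with Gaussian noise; the protocol
#' itself gives no quantitative growth model, so `selection_fraction` is a
#' free parameter documented as such.
#'
#' @param population_size number of genomes carried per pool (>= 2).
#' @param uv_mutation_rate mean number of catalogue loci mutated per genome
#'   during UV mutagenesis (Poisson); must not exceed the catalogue size.
#' @param founder_boost number of truncation-selection rounds applied to the
#'   freshly mutagenized pool before it is archived as the UV sample; this is
#'   what lets a single multi-mutation founder clone rise to dominate the
#'   UV pool emergently rather than by construction.
#' @param founder_cells number of genomes per mating type that carry the
#'   founder-clone mutations before the boost rounds (the clone's expansion
#'   during post-mutagenesis outgrowth); only used when
#'   [run_gs_rounds()] is given `founder_loci`.
#' @param selection_fraction truncation quantile in (0, 1]: the proportion of
#'   the pool, ranked by fitness, retained at each selection step.
#' @param fitness_noise_sd standard deviation of the Gaussian noise added to
#'   each genome's additive fitness before truncation.
#' @param selfing_probability probability that a diploid's spores stay
#'   together as a tetrad so that the next mating preferentially pairs
#'   sister spores (modelling incompletely segregated spores, the route to
#'   homozygous mutations).
#' @param rounds number of genome-shuffling rounds to run.
#' @param seed integer seed driving all randomness in [run_gs_rounds()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(population_size = 1000,
                       uv_mutation_rate = 0.05,
                       founder_boost = 5,
                       founder_cells = 60,
                       selection_fraction = 0.2,
                       fitness_noise_sd = 1,
                       selfing_probability = 0.1,
                       rounds = 5,
                       seed = 1L) {
  cfg <- list(
    population_size = population_size,
    uv_mutation_rate = uv_mutation_rate,
    founder_boost = founder_boost,
    founder_cells = founder_cells,
    selection_fraction = selection_fraction,
    fitness_noise_sd = fitness_noise_sd,
    selfing_probability = selfing_probability,
    rounds = rounds,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  abort_if(!is_count(cfg$population_size) || cfg$population_size < 2,
           "population_size must be an integer >= 2")
  abort_if(!is_number(cfg$uv_mutation_rate) || cfg$uv_mutation_rate < 0,
           "uv_mutation_rate must be a non-negative number")
  abort_if(!is_count(cfg$founder_boost), "founder_boost must be a non-negative integer")
  abort_if(!is_count(cfg$founder_cells) || cfg$founder_cells < 1,
           "founder_cells must be a positive integer")
  abort_if(!is_number(cfg$selection_fraction) ||
             cfg$selection_fraction <= 0 || cfg$selection_fraction > 1,
           "selection_fraction must lie in (0, 1]")
  abort_if(!is_number(cfg$fitness_noise_sd) || cfg$fitness_noise_sd < 0,
           "fitness_noise_sd must be non-negative")
  abort_if(!is_prob(cfg$selfing_probability),
           "selfing_probability must lie in [0, 1]")
  abort_if(!is_count(cfg$rounds), "rounds must be a non-negative integer")
  abort_if(!is_count(abs(cfg$seed)), "seed must be an integer")
  class(cfg) <- "sim_config"
  cfg
}
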