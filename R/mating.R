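#' Pool-wise mating of a haploid population
#'
#' Randomly pairs MATa with MATalpha genomes without replacement; surplus
#' cells of the majority mating type are discarded (plate mating has no
#' replacement mechanism). Spores carrying a tetrad tag (see
#' [sporulate_pool()]) are preferentially paired with sister spores of the
#' opposite mating type first, modelling incompletely segregated spores —
#' the route by which a mutation can become homozygous.
#'
#' @param pop a `haploid_pop` with both mating types present.
#' @return A `diploid_pop` with one member per mated pair.
#' @export
mate_pool <- function(pop) {
  abort_if(!is_haploid(pop), "mate_pool requires a haploid pool")
  is_a <- pop$mating_type == "a"
  abort_if(!any(is_a) || !any(!is_a),
           "mating requires both mating types in the pool")

  a_idx <- which(is_a)
  alpha_idx <- which(!is_a)
  pairs_a <- integer(0)
  pairs_alpha <- integer(0)

  # sister-spore (tetrad) pairing first
  tet <- pop$tetrad
  for (g in unique(tet[!is.na(tet)])) {
    in_g <- which(!is.na(tet) & tet == g)
    ga <- intersect(in_g, a_idx)
    gal <- intersect(in_g, alpha_idx)
    k <- min(length(ga), length(gal))
    if (k > 0L) {
      ga <- ga[sample.int(length(ga), k)]
      gal <- gal[sample.int(length(gal), k)]
      pairs_a <- c(pairs_a, ga)
      pairs_alpha <- c(pairs_alpha, gal)
    }
  }

  rest_a <- setdiff(a_idx, pairs_a)
  rest_alpha <- setdiff(alpha_idx, pairs_alpha)
  k <- min(length(rest_a), length(rest_alpha))
  if (k > 0L) {
    pairs_a <- c(pairs_a, rest_a[sample.int(length(rest_a), k)])
    pairs_alpha <- c(pairs_alpha, rest_alpha[sample.int(length(rest_alpha), k)])
  }

  diploid_pop(pop$alleles[pairs_a, , drop = FALSE],
              pop$alleles[pairs_alpha, , drop = FALSE],
              pop$catalogue, pop$round_label)
}
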