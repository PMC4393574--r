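#' Haldane map function
#'
#' Converts genetic map distance to recombinant fraction under crossovers
#' that form a Poisson process with no interference:
#' \deqn{r = (1 - e^{-2d}) / 2}
#'
#' @param d_morgans map distance in Morgans.
#' @return Recombinant fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_morgans) (1 - exp(-2 * d_morgans)) / 2

#' Sporulation: meiosis of every diploid in a pool
#'
#' Each diploid yields four spores (two complementary gamete pairs, so 2:2
#' Mendelian segregation holds exactly at every locus). Crossovers follow
#' the Haldane model — a Poisson process along the genetic map with no
#' interference — realised as a Markov walk over the loci of each
#' chromosome: the parental strand at the first locus is uniform, and the
#' strand switches across an interval of d Morgans with probability
#' [haldane_r()]. Chromosomes assort independently. Spores within a pair
#' take opposite mating types. With probability `selfing_probability`, the
#' four spores of a diploid are tagged as a tetrad so that the next
#' [mate_pool()] preferentially pairs sister spores.
#'
#' @param pop a `diploid_pop`.
#' @param config a [sim_config()].
#' @return A `haploid_pop` of 4x as many spores.
#' @export
sporulate_pool <- function(pop, config) {
  abort_if(!is_diploid(pop), "sporulate_pool requires a diploid pool")
  n <- nrow(pop$hap1)
  s1 <- gamete_source(n, pop$catalogue)
  s2 <- gamete_source(n, pop$catalogue)
  g <- function(src) pop$hap1 * (1L - src) + pop$hap2 * src
  alleles <- rbind(g(s1), g(1L - s1), g(s2), g(1L - s2))
  mating_type <- rep(c("a", "alpha", "alpha", "a"), each = n)
  tagged <- stats::runif(n) < config$selfing_probability
  tetrad <- rep(ifelse(tagged, seq_len(n), NA_integer_), times = 4L)
  haploid_pop(alleles, mating_type, pop$catalogue, pop$round_label,
              tetrad = tetrad)
}

# strand-of-origin matrix for n independent gametes (0 = haplotype 1,
# 1 = haplotype 2), Haldane recombination along each chromosome
gamete_source <- function(n, catalogue) {
  L <- nrow(catalogue)
  src <- matrix(0L, n, L)
  for (chr in unique(catalogue$chromosome)) {
    loci <- which(catalogue$chromosome == chr)
    loci <- loci[order(catalogue$map_position_cM[loci])]
    cur <- stats::rbinom(n, 1L, 0.5)
    src[, loci[1L]] <- cur
    if (length(loci) > 1L) {
      d <- diff(catalogue$map_position_cM[loci]) / 100  # cM -> Morgans
      r <- haldane_r(d)
      for (j in seq_along(d)) {
        flip <- stats::rbinom(n, 1L, r[j])
        cur <- (cur + flip) %% 2L
        src[, loci[j + 1L]] <- cur
      }
    }
  }
  src
}
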