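#' Population samples
#'
#' A population sample is a concrete pool of genomes tied to a locus
#' catalogue and labelled by evolution round (`"UV"`, `"R1"`, ...). Haploid
#' pools store one 0/1 allele matrix (rows = genomes, columns = catalogue
#' loci) plus a mating type per genome; diploid pools store two haplotype
#' matrices of equal shape.
#'
#' @param alleles integer 0/1 matrix, one row per haploid genome.
#' @param mating_type character vector of `"a"` / `"alpha"`, one per genome.
#' @param catalogue the [locus_catalogue()] the columns refer to.
#' @param round_label sample label, e.g. `"UV"` or `"R3"`.
#' @param tetrad optional integer tag grouping sister spores from one
#'   meiosis (NA = untagged); used by [mate_pool()] to model incompletely
#'   segregated spores.
#' @return An object of class `haploid_pop` or `diploid_pop`.
#' @export
haploid_pop <- function(alleles, mating_type, catalogue, round_label = "UV",
                        tetrad = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  abort_if(nrow(alleles) == 0L, "population must contain at least one genome")
  abort_if(ncol(alleles) != nrow(catalogue),
           "allele matrix width must equal catalogue size")
  abort_if(!all(alleles %in% c(0L, 1L)), "alleles must be 0 (ref) or 1 (alt)")
  abort_if(length(mating_type) != nrow(alleles),
           "one mating type per genome required")
  abort_if(!all(mating_type %in% c("a", "alpha")),
           "mating types must be 'a' or 'alpha'")
  structure(
    list(alleles = alleles,
         mating_type = as.character(mating_type),
         tetrad = tetrad %||% rep(NA_integer_, nrow(alleles)),
         catalogue = catalogue,
         round_label = round_label),
    class = "haploid_pop"
  )
}

#' @param hap1,hap2 integer 0/1 haplotype matrices of identical shape.
#' @rdname haploid_pop
#' @export
diploid_pop <- function(hap1, hap2, catalogue, round_label = "UV") {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  abort_if(nrow(hap1) == 0L, "population must contain at least one genome")
  abort_if(!identical(dim(hap1), dim(hap2)),
           "the two haplotype matrices must have identical shape")
  abort_if(ncol(hap1) != nrow(catalogue),
           "haplotype matrix width must equal catalogue size")
  structure(
    list(hap1 = hap1, hap2 = hap2,
         catalogue = catalogue, round_label = round_label),
    class = "diploid_pop"
  )
}

#' Create a wild-type haploid pool
#'
#' All-reference genomes split evenly between the two mating types, the
#' starting point of the protocol (two haploid progenitor strains of
#' opposite mating type).
#'
#' @param n pool size.
#' @inheritParams haploid_pop
#' @return A `haploid_pop`.
#' @export
wildtype_pool <- function(n, catalogue) {
  haploid_pop(
    alleles = matrix(0L, nrow = n, ncol = nrow(catalogue)),
    mating_type = rep(c("a", "alpha"), length.out = n),
    catalogue = catalogue
  )
}

is_haploid <- function(pop) inherits(pop, "haploid_pop")
is_diploid <- function(pop) inherits(pop, "diploid_pop")

#' @export
print.haploid_pop <- function(x, ...) {
  cat("haploid pool '", x$round_label, "': ", nrow(x$alleles), " genomes, ",
      ncol(x$alleles), " loci (", sum(x$mating_type == "a"), " MATa / ",
      sum(x$mating_type == "alpha"), " MATalpha)\n", sep = "")
  invisible(x)
}

#' @export
print.diploid_pop <- function(x, ...) {
  cat("diploid pool '", x$round_label, "': ", nrow(x$hap1), " genomes, ",
      ncol(x$hap1), " loci\n", sep = "")
  invisible(x)
}

#' Number of genomes in a population sample
#' @param pop a `haploid_pop` or `diploid_pop`.
#' @return Integer count.
#' @export
n_genomes <- function(pop) {
  if (is_haploid(pop)) nrow(pop$alleles) else nrow(pop$hap1)
}

#' Allele dose matrix
#'
#' Per-genome, per-locus count of alternate alleles: 0/1 for haploids,
#' 0/1/2 for diploids.
#'
#' @inheritParams n_genomes
#' @return Integer matrix, rows = genomes, columns = loci.
#' @export
allele_dose <- function(pop) {
  if (is_haploid(pop)) pop$alleles else pop$hap1 + pop$hap2
}

#' True pooled alternate-allele frequencies
#'
#' @inheritParams n_genomes
#' @return Named numeric vector (per catalogue locus) of alt-allele
#'   frequencies, i.e. total alt dose over total allele copies.
#' @export
allele_frequencies <- function(pop) {
  ploidy <- if (is_haploid(pop)) 1L else 2L
  f <- colSums(allele_dose(pop)) / (ploidy * n_genomes(pop))
  names(f) <- pop$catalogue$id
  f
}

#' Additive genome fitness
#'
#' Fitness of each genome under the additive selection model: the sum over
#' loci of `effect_size` times the allele dose, with the heterozygote dose
#' scaled by the locus dominance coefficient in diploids (haploid dose is
#' 0/1, no dominance).
#'
#' @inheritParams n_genomes
#' @return Numeric vector of fitness values, one per genome.
#' @export
genome_fitness <- function(pop) {
  cat <- pop$catalogue
  if (is_haploid(pop)) {
    drop(pop$alleles %*% cat$effect_size)
  } else {
    dose <- pop$hap1 + pop$hap2
    # effective dose: het contributes 2*h, hom alt contributes 2 (scaled to
    # match the haploid per-allele effect the alt allele carries there)
    het <- dose == 1L
    eff <- matrix(0, nrow(dose), ncol(dose))
    eff[dose == 2L] <- 1
    eff[het] <- rep(cat$dominance, each = nrow(dose))[het]
    drop(eff %*% cat$effect_size)
  }
}
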