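#' Construct a locus catalogue
#'
#' A locus catalogue describes the mutation sites tracked by the simulator
#' and by the pooled-sequencing analysis: one row per site with its genetic
#' map location, reference/alternate alleles, the genomic region class, and
#' the selection model parameters (additive fitness effect of the alternate
#' allele and its dominance in heterozygotes).
#'
#' @param id character vector of unique short locus labels.
#' @param chromosome integer chromosome index per locus.
#' @param map_position_cM non-negative genetic map position in centimorgans.
#'   Loci on the same chromosome must have distinct positions.
#' @param ref,alt single-nucleotide reference and alternate alleles
#'   (must differ at every locus).
#' @param region region class, one of `"CDS"`, `"UTR5"`, `"UTR3"`,
#'   `"intergenic"`.
#' @param effect_size additive fitness increment of the alternate allele
#'   (default 0, i.e. neutral).
#' @param dominance dominance coefficient in `[0, 1]` applied to the
#'   heterozygote allele dose in diploids (default 0.5, additive).
#'
#' @return A `data.frame` of class `locus_catalogue`.
#' @export
locus_catalogue <- function(id, chromosome, map_position_cM, ref, alt,
                            region = "intergenic",
                            effect_size = 0, dominance = 0.5) {
  n <- length(id)
  cat <- data.frame(
    id = as.character(id),
    chromosome = as.integer(chromosome),
    map_position_cM = as.numeric(map_position_cM),
    ref = as.character(ref),
    alt = as.character(alt),
    region = rep_len(as.character(region), n),
    effect_size = rep_len(as.numeric(effect_size), n),
    dominance = rep_len(as.numeric(dominance), n),
    stringsAsFactors = FALSE
  )
  validate_locus_catalogue(cat)
}

validate_locus_catalogue <- function(cat) {
  abort_if(nrow(cat) == 0L, "locus catalogue must contain at least one locus")
  abort_if(anyDuplicated(cat$id) > 0L, "locus ids must be unique")
  abort_if(any(cat$map_position_cM < 0), "map positions must be non-negative")
  abort_if(any(cat$ref == cat$alt), "ref and alt alleles must differ")
  nt <- c("A", "C", "G", "T")
  abort_if(!all(cat$ref %in% nt) || !all(cat$alt %in% nt),
           "ref/alt must be single nucleotides (A/C/G/T)")
  abort_if(!all(cat$region %in% c("CDS", "UTR5", "UTR3", "intergenic")),
           "region must be one of CDS, UTR5, UTR3, intergenic")
  abort_if(!all(cat$dominance >= 0 & cat$dominance <= 1),
           "dominance must lie in [0, 1]")
  dup <- duplicated(cat[, c("chromosome", "map_position_cM")])
  abort_if(any(dup), "loci on the same chromosome must have distinct map positions")
  class(cat) <- c("locus_catalogue", "data.frame")
  cat
}

#' Read or write a locus catalogue TSV
#'
#' The on-disk format is a tab-separated table with columns
#' `id, chromosome, map_position_cM, ref, alt, region, effect_size, dominance`.
#'
#' @param path file path.
#' @return `read_locus_catalogue()` returns a validated [locus_catalogue()].
#' @export
read_locus_catalogue <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chromosome", "map_position_cM", "ref", "alt", "region",
            "effect_size", "dominance")
  missing <- setdiff(need, names(tab))
  abort_if(length(missing) > 0L,
           "locus catalogue TSV lacks columns: ", paste(missing, collapse = ", "))
  validate_locus_catalogue(tab[, need])
}

#' @param cat a [locus_catalogue()].
#' @rdname read_locus_catalogue
#' @export
write_locus_catalogue <- function(cat, path) {
  utils::write.table(cat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Demonstration catalogue with a driver + clone-linked passenger architecture
#'
#' Builds a small catalogue mirroring the genetic architecture inferred for
#' the shuffled tolerant population: one strongly beneficial driver locus
#' (`drv1`) and four mildly deleterious passengers (`pas1`-`pas4`) on four
#' other chromosomes — linked to the driver only through co-residence in
#' the founder clone, as the real founder's mutations were — plus three
#' moderately beneficial competitor loci that arise in other mutant clones
#' and two neutral loci. Under the default [sim_config()] with these
#' founder loci, the driver rises toward fixation over five rounds while
#' recombination plus selection cross the passengers out, reproducing the
#' driver-versus-passenger frequency pattern of the original experiment.
#'
#' @param driver_effect fitness effect of the driver allele (default 1).
#' @param passenger_effect fitness effect of each passenger (default
#'   -0.13: non-productive mutations carried by the founder that genome
#'   shuffling can purge).
#' @return A [locus_catalogue()] of 10 loci.
#' @export
demo_catalogue <- function(driver_effect = 1, passenger_effect = -0.13) {
  locus_catalogue(
    id = c("drv1", "pas1", "pas2", "pas3", "pas4",
           "ben1", "ben2", "ben3", "neu1", "neu2"),
    chromosome = c(1, 2, 3, 4, 5, 6, 7, 1, 8, 9),
    map_position_cM = c(10, 20, 30, 40, 50, 15, 25, 60, 35, 45),
    ref = c("C", "T", "C", "A", "G", "C", "T", "A", "C", "G"),
    alt = c("A", "A", "T", "G", "A", "T", "G", "T", "G", "A"),
    region = c("CDS", "intergenic", "UTR5", "CDS", "CDS",
               "CDS", "CDS", "UTR3", "intergenic", "CDS"),
    effect_size = c(driver_effect, rep(passenger_effect, 4), 0.6, 0.5, 0.4, 0, 0),
    dominance = 0.5
  )
}
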