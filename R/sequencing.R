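#' Simulate pooled amplicon sequencing of the tracked loci
#'
#' Emulates PCR amplification and deep sequencing of each catalogue locus
#' from DNA of a heterogeneous population: per-locus coverage is Poisson,
#' and each read reports the alternate allele with probability
#' `p (1 - e) + (1 - p) e / 3`, where `p` is the true pooled alt-allele
#' frequency and `e` the per-base error rate (an erroneous base is one of
#' the three non-template nucleotides with equal probability, so only a
#' third of errors at a ref-carrying read create the alt allele).
#'
#' @param pop a population sample (haploid or diploid).
#' @param mean_coverage mean reads per locus (Poisson), > 0.
#' @param error_rate per-base sequencing error rate in `[0, 1)`.
#' @param qual_sampler function(n) returning a data.frame with numeric
#'   columns `qual_central` and `qual_flank_min` (Phred-like); the default
#'   draws high-confidence scores centred at 45 and 38.
#' @return A data.frame of class `amplicon_counts` with columns
#'   `sample, locus_id, total_reads, alt_reads, qual_central,
#'   qual_flank_min`.
#' @export
simulate_amplicon_counts <- function(pop, mean_coverage, error_rate = 0,
                                     qual_sampler = default_qual_sampler) {
  abort_if(!is_number(mean_coverage) || mean_coverage <= 0,
           "mean_coverage must be a positive number")
  abort_if(!is_prob(error_rate) || error_rate >= 1,
           "error_rate must lie in [0, 1)")
  p <- allele_frequencies(pop)
  L <- length(p)
  coverage <- stats::rpois(L, mean_coverage)
  p_obs <- p * (1 - error_rate) + (1 - p) * error_rate / 3
  alt <- stats::rbinom(L, coverage, p_obs)
  quals <- qual_sampler(L)
  counts <- data.frame(
    sample = pop$round_label,
    locus_id = pop$catalogue$id,
    total_reads = coverage,
    alt_reads = alt,
    qual_central = quals$qual_central,
    qual_flank_min = quals$qual_flank_min,
    stringsAsFactors = FALSE
  )
  class(counts) <- c("amplicon_counts", "data.frame")
  counts
}

#' @rdname simulate_amplicon_counts
#' @param n number of loci to draw quality summaries for.
#' @export
default_qual_sampler <- function(n) {
  data.frame(
    qual_central = pmax(0, round(stats::rnorm(n, 45, 2))),
    qual_flank_min = pmax(0, round(stats::rnorm(n, 38, 2)))
  )
}

#' Simulate Sanger genotyping of picked colonies
#'
#' Draws `n` distinct diploid isolates from a population, with sampling
#' weight proportional to `exp(fitness_bias * w(g))` (colonies are picked
#' from the frontier of growth, so fitter genomes are over-represented
#' when `fitness_bias > 0`), and reports each isolate's zygosity call at
#' every catalogue locus.
#'
#' @param pop a `diploid_pop`.
#' @param n number of isolates, `1 <= n <= n_genomes(pop)`.
#' @param fitness_bias non-negative selection bias of the picking step;
#'   0 gives a uniform draw.
#' @return A character matrix of class `isolate_genotypes`
#'   (rows = isolates, columns = loci) with entries
#'   `"homo"`, `"het"`, `"none"`.
#' @export
simulate_isolates <- function(pop, n, fitness_bias = 0) {
  abort_if(!is_diploid(pop), "simulate_isolates requires a diploid pool")
  abort_if(!is_count(n) || n < 1, "n must be a positive integer")
  abort_if(n > n_genomes(pop), "cannot pick more isolates than the population holds")
  abort_if(!is_number(fitness_bias) || fitness_bias < 0,
           "fitness_bias must be non-negative")
  w <- genome_fitness(pop)
  prob <- exp(fitness_bias * (w - max(w)))
  idx <- sample.int(n_genomes(pop), n, prob = prob)
  dose <- (pop$hap1 + pop$hap2)[idx, , drop = FALSE]
  calls <- matrix(c("none", "het", "homo")[dose + 1L], nrow = n,
                  dimnames = list(sprintf("iso%02d", seq_len(n)),
                                  pop$catalogue$id))
  structure(calls, class = c("isolate_genotypes", class(calls)))
}

#' Read or write isolate genotype matrices as TSV
#'
#' Rows are isolates, columns are loci, entries are `homo`/`het`/`none`;
#' the first column holds the isolate label.
#'
#' @param path file path.
#' @return `read_isolate_genotypes()` returns an `isolate_genotypes` matrix.
#' @export
read_isolate_genotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(names(tab)[1L] != "isolate", "first column must be 'isolate'")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$isolate
  bad <- !(m %in% c("homo", "het", "none"))
  abort_if(any(bad), "genotype calls must be homo/het/none")
  structure(m, class = c("isolate_genotypes", class(m)))
}

#' @param geno an `isolate_genotypes` matrix.
#' @rdname read_isolate_genotypes
#' @export
write_isolate_genotypes <- function(geno, path) {
  tab <- data.frame(isolate = rownames(geno), unclass(geno),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
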