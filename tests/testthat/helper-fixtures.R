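# shared fixtures and independent oracles

# minimal neutral catalogue: `n` loci spread over `n_chr` chromosomes
neutral_catalogue <- function(n, n_chr = max(1L, n %/% 2L), spacing = 10) {
  locus_catalogue(
    id = sprintf("L%02d", seq_len(n)),
    chromosome = rep_len(seq_len(n_chr), n),
    map_position_cM = 10 + spacing * seq_len(n),
    ref = rep_len(c("A", "C", "G", "T"), n),
    alt = rep_len(c("C", "G", "T", "A"), n),
    effect_size = 0
  )
}

# two linked neutral loci at distance d_cM on one chromosome
two_locus_catalogue <- function(d_cM, chromosomes = c(1L, 1L)) {
  locus_catalogue(
    id = c("locA", "locB"),
    chromosome = chromosomes,
    map_position_cM = c(10, 10 + d_cM),
    ref = c("A", "C"), alt = c("G", "T"),
    effect_size = 0
  )
}

# single-row amplicon counts entry
counts_row <- function(locus_id = "L01", sample = "R5", total = 1000L,
                       alt = 0L, qc = 45, qf = 38) {
  data.frame(sample = sample, locus_id = locus_id, total_reads = total,
             alt_reads = alt, qual_central = qc, qual_flank_min = qf,
             stringsAsFactors = FALSE)
}

# independent brute-force re-implementation of the FP filter rule table,
# written directly from the calling rules (kept deliberately naive)
fp_filter_oracle <- function(ev_total, ev_alt, qc, qf, ctl_total, ctl_alt,
                             cfg = caller_config()) {
  ev_frac <- ev_alt / ev_total
  pass_freq <- ev_frac >= cfg$evolved_min_fraction
  pass_qc <- qc >= cfg$qual_central_min
  pass_qf <- qf >= cfg$qual_flank_min
  ctl_known <- ctl_total >= cfg$control_min_coverage
  ctl_high <- ctl_known && (ctl_alt / ctl_total) >= cfg$control_max_fraction
  if (pass_freq && pass_qc && pass_qf) {
    if (ctl_high) "discarded_fp" else "called"
  } else {
    "not_called"
  }
}

# CDS built from filler codons with chosen codons substituted;
# codon_map is a named list index -> codon string
synthetic_cds <- function(n_codons, codon_map = list(), filler = "GCT") {
  codons <- rep(filler, n_codons)
  for (idx in names(codon_map)) codons[as.integer(idx)] <- codon_map[[idx]]
  paste(codons, collapse = "")
}

r57_catalogue_path <- function() {
  system.file("extdata", "r57_catalogue.tsv", package = "gshuffle")
}

founder_ids <- function() c("drv1", "pas1", "pas2", "pas3", "pas4")
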