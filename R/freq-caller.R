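#' Caller configuration
#'
#' Thresholds of the pooled-frequency caller and of the dual-sample
#' false-positive variant filter. Defaults follow the study protocol: a
#' variant is reported in population pools above 1% of reads; a clonal-
#' sample SNP call requires >= 35% of evolved-sample reads, a central base
#' quality >= 40 with flanking bases >= 30, and is discarded as a false
#' positive when the matched wild-type control shows the variant in >= 10%
#' of reads. Controls with fewer than `control_min_coverage` reads are
#' treated as uninformative. Zygosity bands for clonal diploid samples
#' (`het_min_fraction`, `homozygous_min_fraction`) are package-chosen
#' operating points, not protocol values.
#'
#' @param detection_threshold population-pool detection threshold (fraction).
#' @param evolved_min_fraction minimum evolved-sample variant read fraction
#'   for a call.
#' @param control_max_fraction control fraction at or above which a call is
#'   discarded as a false positive.
#' @param qual_central_min,qual_flank_min Phred-like minimum qualities for
#'   the central and flanking bases.
#' @param control_min_coverage reads below which the control is
#'   uninformative.
#' @param homozygous_min_fraction,het_min_fraction zygosity bands for
#'   clonal diploid samples.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(detection_threshold = 0.01,
                          evolved_min_fraction = 0.35,
                          control_max_fraction = 0.10,
                          qual_central_min = 40,
                          qual_flank_min = 30,
                          control_min_coverage = 5,
                          homozygous_min_fraction = 0.90,
                          het_min_fraction = 0.35) {
  cfg <- list(
    detection_threshold = detection_threshold,
    evolved_min_fraction = evolved_min_fraction,
    control_max_fraction = control_max_fraction,
    qual_central_min = qual_central_min,
    qual_flank_min = qual_flank_min,
    control_min_coverage = control_min_coverage,
    homozygous_min_fraction = homozygous_min_fraction,
    het_min_fraction = het_min_fraction
  )
  validate_caller_config(cfg)
}

validate_caller_config <- function(cfg) {
  for (f in c("detection_threshold", "evolved_min_fraction",
              "control_max_fraction", "homozygous_min_fraction",
              "het_min_fraction"))
    abort_if(!is_prob(cfg[[f]]), f, " must lie in [0, 1]")
  abort_if(!(cfg$detection_threshold > 0 &&
               cfg$detection_threshold < cfg$control_max_fraction &&
               cfg$control_max_fraction < cfg$evolved_min_fraction &&
               cfg$evolved_min_fraction <= cfg$homozygous_min_fraction),
           "thresholds must satisfy 0 < detection < control_max < ",
           "evolved_min <= homozygous_min <= 1")
  abort_if(!is_number(cfg$qual_central_min) || cfg$qual_central_min < 0,
           "qual_central_min must be non-negative")
  abort_if(!is_number(cfg$qual_flank_min) || cfg$qual_flank_min < 0,
           "qual_flank_min must be non-negative")
  abort_if(!is_count(cfg$control_min_coverage),
           "control_min_coverage must be a non-negative integer")
  class(cfg) <- "caller_config"
  cfg
}

#' Pooled allele frequency from amplicon read counts
#'
#' The frequency of a mutation in a heterogeneous population is estimated
#' as the fraction of sequence reads spanning the locus that carry the
#' variant; a locus is flagged detected when that fraction reaches the
#' detection threshold (1% of total reads by default, inclusive).
#'
#' @param counts an `amplicon_counts` data.frame (one or more rows) as
#'   produced by [simulate_amplicon_counts()] or [read_amplicon_counts()].
#' @param config a [caller_config()].
#' @return A data.frame with columns
#'   `locus_id, sample, frequency, detected`.
#' @export
allele_frequency <- function(counts, config = caller_config()) {
  abort_if(any(counts$total_reads == 0),
           "no coverage: total_reads is zero for ",
           paste(counts$locus_id[counts$total_reads == 0], collapse = ", "))
  abort_if(any(counts$alt_reads > counts$total_reads),
           "alt_reads exceeds total_reads")
  f <- counts$alt_reads / counts$total_reads
  data.frame(
    locus_id = counts$locus_id,
    sample = counts$sample,
    frequency = f,
    detected = f >= config$detection_threshold,
    stringsAsFactors = FALSE
  )
}

#' Dual-sample false-positive variant filter
#'
#' Implements the SNP-calling rule used for the evolved clonal strain with
#' its wild-type sequencing control: a variant is `called` when it appears
#' in at least `evolved_min_fraction` (35%) of evolved-sample reads with
#' central base quality >= 40 and flanking quality >= 30, and the control
#' shows the variant in fewer than `control_max_fraction` (10%) of reads.
#' A variant passing the evolved gates but present at >= 10% in the control
#' is `discarded_fp`; anything failing the evolved gates is `not_called`.
#' A control with coverage below `control_min_coverage` cannot veto the
#' call; the result is annotated `control_uninformative` and the control
#' fraction reported as `NA`.
#'
#' @param evolved,control single-row `amplicon_counts` entries for the same
#'   locus in the evolved sample and the matched control.
#' @param config a [caller_config()].
#' @return A one-row data.frame with columns `locus_id, status,
#'   evolved_fraction, control_fraction, control_uninformative, zygosity`.
#' @export
fp_filter_call <- function(evolved, control, config = caller_config()) {
  abort_if(evolved$total_reads == 0, "no evolved-sample coverage at ",
           evolved$locus_id)
  ev_frac <- evolved$alt_reads / evolved$total_reads
  evolved_gate <- ev_frac >= config$evolved_min_fraction &&
    evolved$qual_central >= config$qual_central_min &&
    evolved$qual_flank_min >= config$qual_flank_min

  informative <- control$total_reads >= config$control_min_coverage
  ctl_frac <- if (informative) control$alt_reads / control$total_reads else NA_real_

  status <- if (!evolved_gate) {
    "not_called"
  } else if (informative && ctl_frac >= config$control_max_fraction) {
    "discarded_fp"
  } else {
    "called"
  }
  zygosity <- if (status == "called") call_zygosity(ev_frac, config) else "none"
  data.frame(
    locus_id = evolved$locus_id,
    status = status,
    evolved_fraction = ev_frac,
    control_fraction = ctl_frac,
    control_uninformative = !informative,
    zygosity = zygosity,
    stringsAsFactors = FALSE
  )
}

#' Zygosity from a clonal diploid variant read fraction
#'
#' For a clonal diploid sample the variant read fraction is near 1 for a
#' homozygous mutation and near 0.5 for a heterozygous one. Calls `homo`
#' at or above `homozygous_min_fraction`, `het` between `het_min_fraction`
#' and the homozygous band, `none` below the detection threshold, and
#' `ambiguous` otherwise.
#'
#' @param frequency variant read fraction in `[0, 1]` (or a frequency
#'   record row from [allele_frequency()]).
#' @param config a [caller_config()].
#' @return One of `"homo"`, `"het"`, `"ambiguous"`, `"none"`.
#' @export
call_zygosity <- function(frequency, config = caller_config()) {
  if (is.data.frame(frequency)) frequency <- frequency$frequency
  abort_if(!is_prob(frequency), "frequency must lie in [0, 1]")
  if (frequency >= config$homozygous_min_fraction) "homo"
  else if (frequency >= config$het_min_fraction) "het"
  else if (frequency < config$detection_threshold) "none"
  else "ambiguous"
}

#' Read or write amplicon count tables as TSV
#'
#' Columns: `sample, locus_id, total_reads, alt_reads, qual_central,
#' qual_flank_min`.
#'
#' @param path file path.
#' @return `read_amplicon_counts()` returns an `amplicon_counts` data.frame.
#' @export
read_amplicon_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "locus_id", "total_reads", "alt_reads",
            "qual_central", "qual_flank_min")
  missing <- setdiff(need, names(tab))
  abort_if(length(missing) > 0L,
           "amplicon counts TSV lacks columns: ", paste(missing, collapse = ", "))
  abort_if(any(tab$alt_reads > tab$total_reads) || any(tab$alt_reads < 0),
           "require 0 <= alt_reads <= total_reads")
  class(tab) <- c("amplicon_counts", "data.frame")
  tab
}

#' @param counts an `amplicon_counts` data.frame.
#' @rdname read_amplicon_counts
#' @export
write_amplicon_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write variant calls as a minimal VCF
#'
#' Emits a fixed-column VCF 4.2 file (CHROM, POS, REF, ALT; allele
#' frequency in INFO/AF; the filter status in FILTER: `PASS` for called
#' variants, `fp` for control-discarded ones, `lowfreq` otherwise).
#' Positions are the catalogue row order (synthetic coordinates); loci
#' with missing ref/alt are written as `N`.
#'
#' @param calls a data.frame of [fp_filter_call()] rows.
#' @param catalogue the [locus_catalogue()] the calls refer to.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, catalogue, path) {
  m <- match(calls$locus_id, catalogue$id)
  abort_if(anyNA(m), "calls refer to loci absent from the catalogue")
  filter <- c(called = "PASS", discarded_fp = "fp",
              not_called = "lowfreq")[calls$status]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=gshuffle",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant read fraction in evolved sample\">",
    "##FILTER=<ID=fp,Description=\"Discarded: variant present in matched control\">",
    "##FILTER=<ID=lowfreq,Description=\"Below evolved-sample calling threshold or failed quality gates\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tAF=%.6g",
            catalogue$chromosome[m], m, calls$locus_id,
            ifelse(is.na(catalogue$ref[m]), "N", catalogue$ref[m]),
            ifelse(is.na(catalogue$alt[m]), "N", catalogue$alt[m]),
            filter, calls$evolved_fraction)
  )
  writeLines(lines, path)
  invisible(path)
}
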