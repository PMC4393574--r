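#' Classify a single-base coding change at codon level
#'
#' Locates the codon containing a 1-based CDS position, substitutes the
#' alternate base, translates both codons with the standard genetic code
#' and reports the substitution as missense or silent. CDS coordinates are
#' 1-based on the coding strand with the start codon at positions 1-3
#' (matching the `137C > A (P46Q)` notation used for the mutation
#' catalogue).
#'
#' @param cds coding sequence as a character string or
#'   [Biostrings::DNAString]; length must be a multiple of 3.
#' @param position 1-based position of the substituted base within the CDS.
#' @param ref,alt reference and alternate nucleotides; `ref` must match the
#'   CDS at `position`.
#' @return A list of class `effect_class` with fields `kind`
#'   (`"missense"`/`"silent"`), `codon_index`, `aa_ref`, `aa_alt` and a
#'   `label` such as `"P46Q"` or `"S428S (silent)"`.
#' @export
classify_coding_change <- function(cds, position, ref, alt) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  abort_if(n %% 3 != 0, "CDS length (", n, ") is not a multiple of 3")
  abort_if(!is_count(position) || position < 1 || position > n,
           "position ", position, " outside CDS of length ", n)
  abort_if(ref == alt, "ref and alt must differ")
  found <- substr(cds, position, position)
  abort_if(found != ref,
           "reference mismatch at position ", position,
           ": expected ", ref, ", CDS has ", found)
  codon_index <- ceiling(position / 3)
  codon_start <- 3L * (codon_index - 1L) + 1L
  codon_ref <- substr(cds, codon_start, codon_start + 2L)
  offset <- position - codon_start + 1L
  codon_alt <- codon_ref
  substr(codon_alt, offset, offset) <- alt
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  kind <- if (aa_ref == aa_alt) "silent" else "missense"
  label <- if (kind == "silent") {
    sprintf("%s%d%s (silent)", aa_ref, codon_index, aa_alt)
  } else {
    sprintf("%s%d%s", aa_ref, codon_index, aa_alt)
  }
  structure(list(kind = kind, codon_index = codon_index,
                 aa_ref = aa_ref, aa_alt = aa_alt, label = label),
            class = "effect_class")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  abort_if(is.null(aa), "unknown codon: ", codon)
  aa
}

#' SIFT-threshold phenotype prediction
#'
#' An amino-acid substitution is predicted to affect protein function when
#' its SIFT score is at most 0.05, and tolerated otherwise.
#'
#' @param score SIFT score(s) in `[0, 1]`.
#' @param threshold decision threshold (default 0.05, inclusive).
#' @return Character vector of `"affects_function"` / `"tolerated"`.
#' @export
sift_classify <- function(score, threshold = 0.05) {
  abort_if(any(!is.finite(score)) || any(score < 0) || any(score > 1),
           "SIFT scores must lie in [0, 1]")
  ifelse(score <= threshold, "affects_function", "tolerated")
}

#' Load a mutation catalogue TSV
#'
#' Reads and validates the catalogue of point mutations discovered in the
#' evolved strain. Required columns: `gene, chromosome, region, position,
#' ref, alt, protein_change, zygosity, sift_score, group_tag`. Region is
#' one of `CDS, UTR5, UTR3, intergenic`; `position` is the 1-based CDS
#' coordinate for CDS records or the offset in bp for UTR/intergenic
#' records, whose direction is given by `offset_direction`
#' (`5prime`/`3prime`). Validation rules: `protein_change` present iff the
#' record is CDS; `sift_score` only on missense records; ref/alt
#' nucleotides required except on intergenic records with no published
#' base change. Violations are reported with their row number.
#'
#' @param path TSV path; see
#'   `system.file("extdata", "r57_catalogue.tsv", package = "gshuffle")`
#'   for the packaged catalogue.
#' @return A data.frame of class `mutation_catalogue`, one row per record.
#' @export
load_mutation_catalogue <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("gene", "chromosome", "region", "position", "ref", "alt",
            "protein_change", "zygosity", "sift_score", "group_tag",
            "offset_direction")
  missing <- setdiff(need, names(tab))
  abort_if(length(missing) > 0L,
           "mutation catalogue lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("mutation catalogue is empty")
    class(tab) <- c("mutation_catalogue", "data.frame")
    return(tab)
  }
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    abort_if(!(r$region %in% c("CDS", "UTR5", "UTR3", "intergenic")),
             "row ", i, ": unknown region label '", r$region, "'")
    abort_if(!is.finite(r$position) || r$position < 1 ||
               r$position != floor(r$position),
             "row ", i, ": malformed position '", r$position, "'")
    abort_if(!(r$zygosity %in% c("homo", "het")),
             "row ", i, ": zygosity must be homo or het")
    if (r$region == "CDS") {
      abort_if(is.na(r$protein_change),
               "row ", i, ": CDS record lacks protein_change")
      abort_if(!is.na(r$offset_direction),
               "row ", i, ": CDS record must not carry offset_direction")
    } else {
      abort_if(!is.na(r$protein_change),
               "row ", i, ": protein_change only allowed on CDS records")
      abort_if(!(r$offset_direction %in% c("5prime", "3prime")),
               "row ", i, ": UTR/intergenic record needs offset_direction")
    }
    missense <- r$region == "CDS" && !is.na(r$protein_change) &&
      r$protein_change != "silent"
    abort_if(!is.na(r$sift_score) && !missense,
             "row ", i, ": sift_score only allowed on missense records")
    abort_if(!is.na(r$sift_score) &&
               (r$sift_score < 0 || r$sift_score > 1),
             "row ", i, ": sift_score outside [0, 1]")
    nt_ok <- function(x) !is.na(x) && x %in% c("A", "C", "G", "T")
    if (r$region != "intergenic") {
      abort_if(!nt_ok(r$ref) || !nt_ok(r$alt),
               "row ", i, ": ref/alt must be single nucleotides")
      abort_if(r$ref == r$alt, "row ", i, ": ref and alt must differ")
    }
  }
  class(tab) <- c("mutation_catalogue", "data.frame")
  tab
}

#' Summarize a mutation catalogue
#'
#' Counts the record classes of a mutation catalogue: total point
#' mutations, ORF (CDS) records and the distinct genes they affect,
#' missense and silent substitutions, non-ORF (UTR/intergenic) records,
#' homozygous records, and — among missense records with a SIFT score —
#' how many are predicted to affect protein function versus tolerated
#' under the 0.05 threshold.
#'
#' @param records a `mutation_catalogue` from [load_mutation_catalogue()].
#' @return A one-row data.frame with columns `total, orf_snps, orf_genes,
#'   missense, silent, non_orf, homozygous, sift_affects, sift_tolerated`.
#' @export
summarize_catalogue <- function(records) {
  is_orf <- records$region == "CDS"
  is_missense <- is_orf & !is.na(records$protein_change) &
    records$protein_change != "silent"
  is_silent <- is_orf & !is.na(records$protein_change) &
    records$protein_change == "silent"
  scored <- is_missense & !is.na(records$sift_score)
  verdict <- character(0)
  if (any(scored)) verdict <- sift_classify(records$sift_score[scored])
  data.frame(
    total = nrow(records),
    orf_snps = sum(is_orf),
    orf_genes = length(unique(records$gene[is_orf])),
    missense = sum(is_missense),
    silent = sum(is_silent),
    non_orf = sum(!is_orf),
    homozygous = sum(records$zygosity == "homo"),
    sift_affects = sum(verdict == "affects_function"),
    sift_tolerated = sum(verdict == "tolerated")
  )
}

#' Read CDS sequences from a FASTA file
#'
#' @param path FASTA file of coding sequences.
#' @return A named character vector of uppercase sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Annotate a mutation catalogue against CDS sequences
#'
#' Re-derives the codon-level effect of every CDS record whose gene has a
#' sequence in `cds`, checking the recorded protein change, and attaches
#' the SIFT verdict for scored missense records.
#'
#' @param records a `mutation_catalogue`.
#' @param cds named character vector of CDS sequences (names = genes), as
#'   from [read_cds_fasta()].
#' @return `records` with added columns `effect_kind`, `effect_label`,
#'   `sift_verdict` (NA where not applicable).
#' @export
annotate_catalogue <- function(records, cds = character(0)) {
  records$effect_kind <- NA_character_
  records$effect_label <- NA_character_
  records$sift_verdict <- NA_character_
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$region == "CDS" && r$gene %in% names(cds)) {
      eff <- classify_coding_change(cds[[r$gene]], r$position, r$ref, r$alt)
      records$effect_kind[i] <- eff$kind
      records$effect_label[i] <- eff$label
    } else if (r$region == "CDS") {
      records$effect_kind[i] <-
        if (identical(r$protein_change, "silent")) "silent" else "missense"
    }
    if (!is.na(r$sift_score)) {
      records$sift_verdict[i] <- sift_classify(r$sift_score)
    }
  }
  records
}
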