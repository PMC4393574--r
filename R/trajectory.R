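#' Trend-classification configuration
#'
#' Operating points for trajectory trend labels and co-origin clustering.
#' These formalize narrative descriptions ("gained in frequency", "linked
#' mutations at virtually identical frequency") and are package-chosen
#' defaults, not protocol values.
#'
#' @param trend_margin minimum endpoint frequency change to label a
#'   trajectory rising/falling (default 0.02).
#' @param cluster_tolerance maximum pairwise UV-frequency gap joining two
#'   loci in a co-origin cluster (default 0.03).
#' @param cluster_min_frequency minimum mean UV frequency for a cluster to
#'   be reported (default 0.20).
#' @return A list of class `trend_config`.
#' @export
trend_config <- function(trend_margin = 0.02,
                         cluster_tolerance = 0.03,
                         cluster_min_frequency = 0.20) {
  cfg <- list(trend_margin = trend_margin,
              cluster_tolerance = cluster_tolerance,
              cluster_min_frequency = cluster_min_frequency)
  for (f in names(cfg))
    abort_if(!is_number(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1,
             f, " must lie in (0, 1)")
  class(cfg) <- "trend_config"
  cfg
}

#' Build a loci-by-rounds frequency matrix
#'
#' Assembles per-round frequency records into a complete matrix with one
#' row per locus and one column per round, in the order the rounds first
#' appear. Undetected entries are stored as `NA` (absent), not zero; a
#' locus/round combination never measured is also `NA`.
#'
#' @param records a data.frame of [allele_frequency()] rows
#'   (`locus_id, sample, frequency, detected`), possibly concatenated over
#'   rounds.
#' @return A numeric matrix (rows = loci, columns = round labels) with NA
#'   for undetected cells.
#' @export
build_frequency_matrix <- function(records) {
  abort_if(nrow(records) == 0L, "no frequency records")
  dup <- duplicated(records[, c("locus_id", "sample")])
  abort_if(any(dup), "duplicate (locus, round) pairs: ",
           paste(unique(records$locus_id[dup]), collapse = ", "))
  rounds <- unique(records$sample)
  loci <- unique(records$locus_id)
  m <- matrix(NA_real_, length(loci), length(rounds),
              dimnames = list(loci, rounds))
  keep <- records$detected
  m[cbind(match(records$locus_id[keep], loci),
          match(records$sample[keep], rounds))] <- records$frequency[keep]
  m
}

#' Classify one frequency trajectory
#'
#' Assigns exactly one trend label to a locus's frequency series over
#' rounds. Absent (undetected) cells count as 0 in the comparisons.
#' `not_detected` if no round is detected; `rising` if the final frequency
#' exceeds the first by more than the margin; `falling` if it is below the
#' first by more than the margin; `transient` if neither holds but some
#' interior round exceeds both endpoints by the margin; `stable`
#' otherwise.
#'
#' @param row numeric vector of per-round frequencies with `NA` for
#'   undetected rounds (a row of [build_frequency_matrix()]).
#' @param config a [trend_config()].
#' @return One of `"rising"`, `"falling"`, `"transient"`, `"stable"`,
#'   `"not_detected"`.
#' @export
classify_trajectory <- function(row, config = trend_config()) {
  abort_if(length(row) < 2L, "need at least two rounds to classify a trend")
  if (all(is.na(row))) return("not_detected")
  f <- ifelse(is.na(row), 0, row)
  m <- config$trend_margin
  first <- f[1L]; final <- f[length(f)]
  if (final > first + m) return("rising")
  if (final < first - m) return("falling")
  interior <- f[-c(1L, length(f))]
  if (length(interior) > 0L &&
      max(interior) > first + m && max(interior) > final + m) {
    return("transient")
  }
  "stable"
}

#' Infer co-origin (single-founder) mutation clusters from UV frequencies
#'
#' Mutations represented at virtually identical frequency in the UV mutant
#' pool are hypothesized to descend from one founder clone. Groups loci by
#' single linkage on the absolute UV-frequency difference (link if
#' `|f_i - f_j| <= cluster_tolerance`), then keeps clusters of at least
#' two loci whose mean frequency reaches `cluster_min_frequency`.
#'
#' @param uv_frequencies named numeric vector of per-locus UV-pool
#'   frequencies in `[0, 1]`.
#' @param config a [trend_config()].
#' @return A list of clusters, each a list with `member_loci`,
#'   `mean_uv_frequency`, `tolerance_used`.
#' @export
co_origin_clusters <- function(uv_frequencies, config = trend_config()) {
  abort_if(any(uv_frequencies < 0 | uv_frequencies > 1, na.rm = TRUE),
           "frequencies must lie in [0, 1]")
  f <- uv_frequencies[!is.na(uv_frequencies)]
  if (length(f) < 2L) return(list())
  ord <- order(f)
  # 1-D single linkage: split the sorted values where an adjacent gap
  # exceeds the tolerance
  gap <- diff(f[ord]) > config$cluster_tolerance
  grp <- cumsum(c(0L, gap))
  clusters <- list()
  for (g in unique(grp)) {
    members <- names(f)[ord[grp == g]]
    if (length(members) < 2L) next
    mean_f <- mean(f[members])
    if (mean_f < config$cluster_min_frequency) next
    clusters[[length(clusters) + 1L]] <- list(
      member_loci = members,
      mean_uv_frequency = mean_f,
      tolerance_used = config$cluster_tolerance
    )
  }
  clusters
}

#' Allele frequency from an isolate genotype matrix
#'
#' Counts alternate alleles over the diploid isolates Sanger-genotyped at
#' a locus: each homozygous isolate contributes two alleles, each
#' heterozygous one, over `2 N` total.
#'
#' @param geno an `isolate_genotypes` matrix
#'   (see [simulate_isolates()] / [read_isolate_genotypes()]).
#' @param locus locus id (column name); if missing, all loci are returned.
#' @return Named numeric vector of allele frequencies in `[0, 1]`.
#' @export
isolate_allele_frequency <- function(geno, locus = colnames(geno)) {
  abort_if(nrow(geno) == 0L, "isolate genotype matrix is empty")
  abort_if(!all(locus %in% colnames(geno)),
           "unknown locus: ", paste(setdiff(locus, colnames(geno)), collapse = ", "))
  vapply(locus, function(l) {
    calls <- geno[, l]
    (2 * sum(calls == "homo") + sum(calls == "het")) / (2 * nrow(geno))
  }, numeric(1))
}

#' Compare population-sequencing and isolate-derived frequencies
#'
#' Pairs pooled-sequencing frequency estimates with allele frequencies
#' enumerated from single-colony genotyping at the shared loci, reporting
#' the per-locus absolute deviation and the Spearman rank correlation of
#' the two series (NA, flagged, when fewer than two shared loci or a
#' series is constant).
#'
#' @param pop_freqs,isolate_freqs named numeric vectors of per-locus
#'   frequencies.
#' @return A list with `table` (locus, pop_frequency, isolate_frequency,
#'   abs_deviation), `rank_correlation`, `rank_correlation_defined`.
#' @export
compare_population_vs_isolates <- function(pop_freqs, isolate_freqs) {
  shared <- intersect(names(pop_freqs), names(isolate_freqs))
  abort_if(length(shared) == 0L,
           "population and isolate frequency sets share no loci")
  tab <- data.frame(
    locus = shared,
    pop_frequency = unname(pop_freqs[shared]),
    isolate_frequency = unname(isolate_freqs[shared]),
    stringsAsFactors = FALSE
  )
  tab$abs_deviation <- abs(tab$pop_frequency - tab$isolate_frequency)
  rho <- if (length(shared) >= 2L) {
    suppressWarnings(stats::cor(tab$pop_frequency, tab$isolate_frequency,
                                method = "spearman"))
  } else {
    NA_real_
  }
  list(table = tab,
       rank_correlation = rho,
       rank_correlation_defined = is.finite(rho))
}

#' Rank candidate tolerance determinants
#'
#' Orders loci for reverse-engineering priority: mutations that rise in
#' frequency over the evolution come first, then transient/stable ones,
#' then falling or never-detected ones; ties are broken by final-round
#' frequency (descending), then by locus id.
#'
#' @param trajectories a data.frame with columns `locus_id, trend,
#'   final_frequency` (see [trajectory_table()]).
#' @return The same data.frame ordered by priority, with a `rank` column.
#' @export
rank_candidates <- function(trajectories) {
  if (nrow(trajectories) == 0L) {
    trajectories$rank <- integer(0)
    return(trajectories)
  }
  tier <- c(rising = 1L, transient = 2L, stable = 2L,
            falling = 3L, not_detected = 3L)[trajectories$trend]
  abort_if(anyNA(tier), "unknown trend label in trajectories")
  final <- ifelse(is.na(trajectories$final_frequency), 0,
                  trajectories$final_frequency)
  ord <- order(tier, -final, trajectories$locus_id)
  out <- trajectories[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Trajectory table: frequencies, trend and detection per locus
#'
#' Convenience wrapper combining [build_frequency_matrix()] and
#' [classify_trajectory()] into the tabular form used by reports and
#' [rank_candidates()].
#'
#' @inheritParams build_frequency_matrix
#' @param config a [trend_config()].
#' @return A data.frame with `locus_id`, one `freq_<round>` column per
#'   round (NA = undetected), `trend`, `ever_detected`,
#'   `final_frequency`.
#' @export
trajectory_table <- function(records, config = trend_config()) {
  m <- build_frequency_matrix(records)
  trend <- apply(m, 1L, classify_trajectory, config = config)
  out <- data.frame(locus_id = rownames(m), stringsAsFactors = FALSE)
  freq_cols <- as.data.frame(m)
  names(freq_cols) <- paste0("freq_", colnames(m))
  out <- cbind(out, freq_cols)
  out$trend <- unname(trend)
  out$ever_detected <- apply(m, 1L, function(r) any(!is.na(r)))
  last <- m[, ncol(m)]
  out$final_frequency <- ifelse(is.na(last), 0, last)
  rownames(out) <- NULL
  out
}
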