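#' Pipeline configuration
#'
#' Composite configuration for the end-to-end pipeline: the simulator,
#' caller and trend configurations, input/output paths, the archived-round
#' schedule, the sequencing model, and the master seed.
#'
#' @param mode `"simulate"` (generate synthetic data, then analyse it) or
#'   `"analyze"` (run the analysis stages on supplied files).
#' @param seed master integer seed for every source of randomness.
#' @param simulation a [sim_config()] (its `seed` is overridden by `seed`).
#' @param caller a [caller_config()].
#' @param trend a [trend_config()].
#' @param rounds_archived round labels to sequence; defaults to
#'   `UV, R1, R3, R5`, the rounds sampled in the original protocol.
#' @param mean_coverage mean amplicon reads per locus.
#' @param error_rate per-base sequencing error rate.
#' @param n_isolates diploid colonies to genotype from the final archived
#'   round.
#' @param isolate_fitness_bias picking bias passed to [simulate_isolates()].
#' @param founder_loci locus ids carried by the UV founder clone in
#'   simulate mode (see [run_gs_rounds()]); defaults to the driver +
#'   passenger block of [demo_catalogue()] when no locus catalogue is
#'   supplied, otherwise no founder.
#' @param inputs named list of input paths: `locus_catalogue` (simulate
#'   mode, optional — [demo_catalogue()] when absent), and for analyze mode
#'   `counts`, `isolates` (optional), `catalogue` (mutation catalogue TSV,
#'   defaults to the packaged fixture in either mode).
#' @param output_dir directory for report artifacts.
#' @param verbosity 0 = silent, 1 = per-stage record counts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = "simulate",
                            seed = 1L,
                            simulation = sim_config(),
                            caller = caller_config(),
                            trend = trend_config(),
                            rounds_archived = c("UV", "R1", "R3", "R5"),
                            mean_coverage = 1.35e5,
                            error_rate = 0.003,
                            n_isolates = 20,
                            isolate_fitness_bias = 0,
                            founder_loci = NULL,
                            inputs = list(),
                            output_dir = NULL,
                            verbosity = 1) {
  abort_if(!mode %in% c("simulate", "analyze"),
           "mode must be 'simulate' or 'analyze'")
  simulation$seed <- as.integer(seed)
  cfg <- list(mode = mode, seed = as.integer(seed),
              simulation = validate_sim_config(simulation),
              caller = validate_caller_config(caller),
              trend = trend,
              rounds_archived = rounds_archived,
              mean_coverage = mean_coverage,
              error_rate = error_rate,
              n_isolates = n_isolates,
              isolate_fitness_bias = isolate_fitness_bias,
              founder_loci = founder_loci,
              inputs = inputs,
              output_dir = output_dir,
              verbosity = verbosity)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected with their key path; missing keys take
#' defaults; nested sections (`simulation`, `caller`, `trend`, `inputs`)
#' are validated individually. An empty file yields the all-defaults
#' configuration.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  abort_if(!file.exists(path), "config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_known <- c("mode", "seed", "simulation", "caller", "trend",
                 "rounds_archived", "mean_coverage", "error_rate",
                 "n_isolates", "isolate_fitness_bias", "founder_loci",
                 "inputs", "output_dir", "verbosity")
  unknown <- setdiff(names(raw), top_known)
  abort_if(length(unknown) > 0L,
           "unknown config key(s): ", paste(unknown, collapse = ", "))

  merge_section <- function(section, constructor) {
    given <- raw[[section]] %||% list()
    known <- names(formals(constructor))
    unknown <- setdiff(names(given), known)
    abort_if(length(unknown) > 0L, "unknown config key(s): ",
             paste(paste0(section, ".", unknown), collapse = ", "))
    do.call(constructor, given)
  }
  sim <- merge_section("simulation", sim_config)
  cal <- merge_section("caller", caller_config)
  trd <- merge_section("trend", trend_config)
  inputs <- raw$inputs %||% list()
  known_inputs <- c("locus_catalogue", "counts", "control_counts",
                    "isolates", "catalogue")
  unknown <- setdiff(names(inputs), known_inputs)
  abort_if(length(unknown) > 0L, "unknown config key(s): ",
           paste(paste0("inputs.", unknown), collapse = ", "))

  args <- list(simulation = sim, caller = cal, trend = trd, inputs = inputs)
  for (k in c("mode", "seed", "rounds_archived", "mean_coverage",
              "error_rate", "n_isolates", "isolate_fitness_bias",
              "founder_loci", "output_dir", "verbosity")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(pipeline_config, args)
}

pipeline_log <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1) >= 1) message("[gshuffle] ", ...)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the pipeline end to end
#'
#' In simulate mode: runs the genome-shuffling simulator, sequences the
#' archived pools (pooled amplicon counts) and the wild-type control,
#' genotypes isolates from the final round, then runs frequency calling,
#' the false-positive filter, catalogue annotation, trajectory/cluster
#' analysis and candidate ranking. In analyze mode the same analysis
#' stages run on user-supplied count/isolate/catalogue files. All
#' artifacts are written under `config$output_dir` when set, plus a
#' machine-readable JSON summary carrying the seed and a config hash so a
#' run can be reproduced bit-identically.
#'
#' @param config a [pipeline_config()] or [load_config()] result.
#' @return A list of class `report_bundle` with elements
#'   `frequency_records`, `trajectories`, `clusters`, `catalogue_summary`,
#'   `ranking`, `variant_calls`, `isolate_comparison`, `truth` and
#'   `population_genotypes` (simulate mode only: per-genome allele doses of
#'   the final archived pool) and `metadata`.
#' @export
run_end_to_end <- function(config) {
  abort_if(!inherits(config, "pipeline_config"),
           "config must be a pipeline_config")
  set.seed(config$seed)

  mutation_catalogue_path <- config$inputs$catalogue %||%
    system.file("extdata", "r57_catalogue.tsv", package = "gshuffle")
  records <- run_stage("annotate", {
    cat_tab <- load_mutation_catalogue(mutation_catalogue_path)
    annotate_catalogue(cat_tab)
  })
  catalogue_summary <- summarize_catalogue(records)
  pipeline_log(config, "annotate: ", nrow(records), " catalogue records")

  truth <- NULL
  isolates <- NULL
  control_counts <- NULL
  genotypes <- NULL

  if (config$mode == "simulate") {
    founder <- config$founder_loci
    locus_cat <- if (!is.null(config$inputs$locus_catalogue)) {
      read_locus_catalogue(config$inputs$locus_catalogue)
    } else {
      if (is.null(founder)) founder <- c("drv1", "pas1", "pas2", "pas3", "pas4")
      demo_catalogue()
    }
    samples <- run_stage("simulate",
                         run_gs_rounds(config$simulation, locus_cat, founder))
    archived <- intersect(config$rounds_archived, names(samples))
    abort_if(length(archived) == 0L, "no archived rounds available")
    counts <- do.call(rbind, lapply(samples[archived], function(s) {
      simulate_amplicon_counts(s, config$mean_coverage, config$error_rate)
    }))
    truth <- do.call(rbind, lapply(samples[archived], function(s) {
      data.frame(sample = s$round_label, locus_id = locus_cat$id,
                 true_frequency = unname(allele_frequencies(s)),
                 stringsAsFactors = FALSE)
    }))
    rownames(counts) <- rownames(truth) <- NULL
    control_counts <- simulate_amplicon_counts(
      wildtype_pool(config$simulation$population_size, locus_cat),
      config$mean_coverage, config$error_rate)
    control_counts$sample <- "WT"
    final_label <- archived[length(archived)]
    final_pop <- samples[[final_label]]
    genotypes <- as.data.frame(allele_dose(final_pop))
    names(genotypes) <- locus_cat$id
    genotypes <- cbind(genome = seq_len(nrow(genotypes)), genotypes)
    if (is_diploid(samples[[final_label]]) && config$n_isolates >= 1) {
      isolates <- simulate_isolates(
        samples[[final_label]],
        min(config$n_isolates, n_genomes(samples[[final_label]])),
        config$isolate_fitness_bias)
    }
    pipeline_log(config, "simulate: ", length(archived), " archived rounds, ",
                 nrow(locus_cat), " loci")
  } else {
    abort_if(is.null(config$inputs$counts),
             "analyze mode requires inputs.counts")
    counts <- run_stage("callfreq", read_amplicon_counts(config$inputs$counts))
    locus_cat <- if (!is.null(config$inputs$locus_catalogue)) {
      read_locus_catalogue(config$inputs$locus_catalogue)
    } else {
      NULL
    }
    if (!is.null(config$inputs$control_counts)) {
      control_counts <- read_amplicon_counts(config$inputs$control_counts)
    }
    if (!is.null(config$inputs$isolates)) {
      isolates <- read_isolate_genotypes(config$inputs$isolates)
    }
  }

  freq_records <- run_stage("callfreq", {
    covered <- counts$total_reads > 0
    if (!all(covered)) {
      warning(sum(!covered), " locus/round entries had zero coverage; dropped")
    }
    allele_frequency(counts[covered, , drop = FALSE], config$caller)
  })
  pipeline_log(config, "callfreq: ", nrow(freq_records), " frequency records (",
               sum(freq_records$detected), " detected)")

  variant_calls <- NULL
  if (!is.null(control_counts)) {
    variant_calls <- run_stage("filter", {
      final_label <- utils::tail(unique(counts$sample), 1L)
      evolved <- counts[counts$sample == final_label, , drop = FALSE]
      do.call(rbind, lapply(seq_len(nrow(evolved)), function(i) {
        ctl <- control_counts[control_counts$locus_id ==
                                evolved$locus_id[i], , drop = FALSE]
        if (nrow(ctl) == 0L) {
          ctl <- data.frame(locus_id = evolved$locus_id[i], total_reads = 0L,
                            alt_reads = 0L)
        }
        fp_filter_call(evolved[i, ], ctl[1L, ], config$caller)
      }))
    })
    pipeline_log(config, "filter: ", sum(variant_calls$status == "called"),
                 " called / ", sum(variant_calls$status == "discarded_fp"),
                 " discarded of ", nrow(variant_calls))
  }

  trajectories <- run_stage("trajectory", trajectory_table(freq_records, config$trend))
  uv_label <- unique(freq_records$sample)[1L]
  uv <- freq_records[freq_records$sample == uv_label & freq_records$detected, ]
  uv_freqs <- stats::setNames(uv$frequency, uv$locus_id)
  clusters <- co_origin_clusters(uv_freqs, config$trend)
  ranking <- rank_candidates(trajectories[, c("locus_id", "trend", "final_frequency")])
  pipeline_log(config, "trajectory: ", nrow(trajectories), " loci, ",
               length(clusters), " co-origin cluster(s)")

  isolate_comparison <- NULL
  if (!is.null(isolates)) {
    final_label <- utils::tail(unique(freq_records$sample), 1L)
    fin <- freq_records[freq_records$sample == final_label, ]
    pop_freqs <- stats::setNames(fin$frequency, fin$locus_id)
    isolate_comparison <- compare_population_vs_isolates(
      pop_freqs, isolate_allele_frequency(isolates))
  }

  bundle <- structure(list(
    frequency_records = freq_records,
    trajectories = trajectories,
    clusters = clusters,
    catalogue = records,
    catalogue_summary = catalogue_summary,
    ranking = ranking,
    variant_calls = variant_calls,
    isolates = isolates,
    isolate_comparison = isolate_comparison,
    truth = truth,
    population_genotypes = genotypes,
    counts = counts,
    metadata = list(seed = config$seed,
                    mode = config$mode,
                    package_version = as.character(utils::packageVersion("gshuffle")),
                    config = config)
  ), class = "report_bundle")

  if (!is.null(config$output_dir)) {
    write_report_bundle(bundle, config$output_dir, locus_cat = locus_cat)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("gshuffle report bundle (", x$metadata$mode, " mode, seed ",
      x$metadata$seed, ")\n", sep = "")
  cat("  loci:", nrow(x$trajectories),
      " | detected records:", sum(x$frequency_records$detected),
      " | co-origin clusters:", length(x$clusters), "\n")
  cat("  trends:", paste(names(table(x$trajectories$trend)),
                         table(x$trajectories$trend),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the tabular artifacts (TSV), the cluster list and run summary
#' (JSON), the minimal VCF of filtered variant calls when present, and a
#' config echo (YAML) whose MD5 hash is recorded in the summary so that a
#' run can be reproduced from its own output.
#'
#' @param bundle a `report_bundle` from [run_end_to_end()].
#' @param dir output directory (created if needed).
#' @param locus_cat optional [locus_catalogue()] for the VCF writer.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, locus_cat = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(bundle$frequency_records, "frequency_by_round.tsv")
  tsv(bundle$trajectories, "trajectory.tsv")
  tsv(bundle$ranking, "ranking.tsv")
  tsv(bundle$catalogue_summary, "catalogue_summary.tsv")
  tsv(bundle$counts, "amplicon_counts.tsv")
  if (!is.null(bundle$truth)) tsv(bundle$truth, "truth_frequencies.tsv")
  if (!is.null(bundle$population_genotypes)) {
    tsv(bundle$population_genotypes, "population_genotypes.tsv")
  }
  if (!is.null(bundle$variant_calls)) {
    tsv(bundle$variant_calls, "variant_calls.tsv")
    if (!is.null(locus_cat)) {
      ok <- bundle$variant_calls$locus_id %in% locus_cat$id
      write_variant_vcf(bundle$variant_calls[ok, , drop = FALSE], locus_cat,
                        file.path(dir, "variant_calls.vcf"))
    }
  }
  if (!is.null(bundle$isolates)) {
    write_isolate_genotypes(bundle$isolates, file.path(dir, "isolate_genotypes.tsv"))
  }
  if (!is.null(bundle$isolate_comparison)) {
    tsv(bundle$isolate_comparison$table, "population_vs_isolates.tsv")
  }
  jsonlite::write_json(bundle$clusters, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_path <- file.path(dir, "config_echo.yaml")
  yaml::write_yaml(config_as_list(bundle$metadata$config), cfg_path)
  summary <- list(
    seed = bundle$metadata$seed,
    mode = bundle$metadata$mode,
    package_version = bundle$metadata$package_version,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_loci = nrow(bundle$trajectories),
    n_detected = sum(bundle$frequency_records$detected),
    n_clusters = length(bundle$clusters),
    catalogue_summary = as.list(bundle$catalogue_summary)
  )
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# config echo for reproduction: scientific parameters only — where outputs
# land (output_dir) and how chatty the run is (verbosity) do not affect
# results and are excluded so the echoed hash identifies the computation
config_as_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  out <- strip(cfg)
  out$output_dir <- NULL
  out$verbosity <- NULL
  out
}
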