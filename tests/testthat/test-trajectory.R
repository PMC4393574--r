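freq_rec <- function(locus, sample, f, detected = f >= 0.01) {
  data.frame(locus_id = locus, sample = sample, frequency = f,
             detected = detected, stringsAsFactors = FALSE)
}

test_that("the frequency matrix is complete with absent (not zero) undetected cells", {
  rec <- rbind(
    freq_rec("A", "UV", 0.5), freq_rec("A", "R1", 0.6),
    freq_rec("A", "R3", 0.7), freq_rec("A", "R5", 0.8),
    freq_rec("B", "UV", 0.2), freq_rec("B", "R1", 0.1),
    freq_rec("B", "R3", 0.05), freq_rec("B", "R5", 0.02)
  )
  m <- build_frequency_matrix(rec)
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(m["A", "R5"], 0.8)

  never <- rbind(freq_rec("C", "UV", 0.002), freq_rec("C", "R1", 0.005))
  m2 <- build_frequency_matrix(never)
  expect_true(all(is.na(m2["C", ])))

  expect_error(build_frequency_matrix(rbind(rec, freq_rec("A", "UV", 0.5))),
               "duplicate")
})

test_that("trend labels follow the endpoint-and-interior-maximum rules", {
  cfg <- trend_config()
  expect_equal(classify_trajectory(c(0.02, 0.02, 0.02, 0.11), cfg), "rising")
  expect_equal(classify_trajectory(c(0.60, 0.45, 0.25, 0.10), cfg), "falling")
  expect_equal(classify_trajectory(c(NA, 0.08, 0.02, 0.005), cfg), "transient")
  expect_equal(classify_trajectory(c(0.10, 0.10, 0.10, 0.10), cfg), "stable")
  expect_equal(classify_trajectory(c(NA_real_, NA, NA, NA), cfg), "not_detected")
  expect_error(classify_trajectory(0.5, cfg), "two rounds")

  # exactly one label per row, and joint scaling of margin+frequencies is
  # label-invariant
  set.seed(41)
  labels <- c("rising", "falling", "transient", "stable", "not_detected")
  for (i in 1:50) {
    row <- runif(4, 0, 0.5)
    row[runif(4) < 0.2] <- NA
    t1 <- classify_trajectory(row, cfg)
    expect_true(t1 %in% labels)
    scaled <- trend_config(trend_margin = cfg$trend_margin / 2)
    t2 <- classify_trajectory(row / 2, scaled)
    expect_equal(t2, t1)
  }
})

test_that("co-origin clustering groups near-identical UV frequencies above the floor", {
  cfg <- trend_config()
  uv <- c(A = 0.60, B = 0.60, C = 0.59, D = 0.61, E = 0.60, F = 0.30, G = 0.02)
  cl <- co_origin_clusters(uv, cfg)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$member_loci, c("A", "B", "C", "D", "E"))
  expect_equal(cl[[1]]$mean_uv_frequency, 0.60)

  expect_length(co_origin_clusters(c(a = 0.1, b = 0.1, c = 0.11), cfg), 0)
  expect_length(co_origin_clusters(c(a = 0.50, b = 0.56), cfg), 0)

  # clusters partition their members
  set.seed(43)
  for (i in 1:25) {
    f <- stats::setNames(runif(12), sprintf("l%02d", 1:12))
    cl <- co_origin_clusters(f, cfg)
    members <- unlist(lapply(cl, `[[`, "member_loci"))
    expect_equal(anyDuplicated(members), 0)
    for (c1 in cl) expect_gte(length(c1$member_loci), 2)
  }
})

test_that("isolate allele frequencies equal brute-force allele counting", {
  calls <- matrix("none", 20, 1, dimnames = list(NULL, "L1"))
  calls[1:3, 1] <- "homo"
  calls[4:8, 1] <- "het"
  geno <- structure(calls, class = c("isolate_genotypes", class(calls)))
  expect_equal(unname(isolate_allele_frequency(geno, "L1")), 11 / 40)

  all_hom <- structure(matrix("homo", 20, 1, dimnames = list(NULL, "L1")),
                       class = c("isolate_genotypes", "matrix", "array"))
  expect_equal(unname(isolate_allele_frequency(all_hom, "L1")), 1)
  all_none <- structure(matrix("none", 20, 1, dimnames = list(NULL, "L1")),
                        class = c("isolate_genotypes", "matrix", "array"))
  expect_equal(unname(isolate_allele_frequency(all_none, "L1")), 0)

  # brute-force equivalence on random matrices
  set.seed(44)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    m <- matrix(sample(c("homo", "het", "none"), n * 3, replace = TRUE), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    geno <- structure(m, class = c("isolate_genotypes", class(m)))
    f <- isolate_allele_frequency(geno)
    brute <- vapply(colnames(m), function(l) {
      total <- 0
      for (i2 in seq_len(n)) {
        total <- total + switch(m[i2, l], homo = 2, het = 1, none = 0)
      }
      total / (2 * n)
    }, numeric(1))
    expect_equal(f, brute)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("population and isolate frequencies reconcile on shared loci", {
  p <- c(A = 0.4, B = 0.2, C = 0.9)
  same <- compare_population_vs_isolates(p, p)
  expect_true(all(same$table$abs_deviation == 0))
  expect_equal(same$rank_correlation, 1)

  one <- compare_population_vs_isolates(c(A = 0.4), c(A = 0.35))
  expect_equal(one$table$abs_deviation, 0.05)
  expect_false(one$rank_correlation_defined)

  expect_error(compare_population_vs_isolates(c(A = 1), c(B = 1)), "no loci")

  # simulated pool vs 20 isolates: deviations within a finite-sample envelope
  set.seed(45)
  cfg <- sim_config(population_size = 400, rounds = 2, seed = 45)
  samp <- run_gs_rounds(cfg, demo_catalogue(), founder_loci = founder_ids())
  final <- samp$R2
  truth <- allele_frequencies(final)
  counts <- simulate_amplicon_counts(final, 1e5, error_rate = 0)
  pop_est <- stats::setNames(counts$alt_reads / counts$total_reads,
                             counts$locus_id)
  iso <- simulate_isolates(final, 20)
  cmp <- compare_population_vs_isolates(pop_est, isolate_allele_frequency(iso))
  # 20 diploid isolates -> binomial(40, p) sampling noise dominates
  env <- 4 * sqrt(truth[cmp$table$locus] * (1 - truth[cmp$table$locus]) / 40) + 0.01
  expect_true(all(cmp$table$abs_deviation <= env))
})

test_that("candidate ranking prioritizes rising loci with documented tie-breaks", {
  tr <- data.frame(
    locus_id = c("fall_hi", "rise_lo", "rise_hi", "stab", "none"),
    trend = c("falling", "rising", "rising", "stable", "not_detected"),
    final_frequency = c(0.6, 0.3, 0.5, 0.2, 0),
    stringsAsFactors = FALSE
  )
  ranked <- rank_candidates(tr)
  expect_equal(ranked$locus_id,
               c("rise_hi", "rise_lo", "stab", "fall_hi", "none"))
  expect_equal(ranked$rank, 1:5)

  empty <- rank_candidates(tr[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("trajectory_table assembles per-locus rows with a single trend each", {
  rec <- rbind(
    freq_rec("A", "UV", 0.5), freq_rec("A", "R5", 0.8),
    freq_rec("B", "UV", 0.2), freq_rec("B", "R5", 0.005)
  )
  tab <- trajectory_table(rec)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$trend[tab$locus_id == "A"], "rising")
  expect_equal(tab$trend[tab$locus_id == "B"], "falling")
  expect_equal(tab$final_frequency[tab$locus_id == "B"], 0)
})
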