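test_that("locus catalogue and population constructors enforce invariants", {
  expect_error(locus_catalogue("a", 1, 5, "A", "A"), "differ")
  expect_error(locus_catalogue("a", 1, -1, "A", "C"), "non-negative")
  expect_error(
    locus_catalogue(c("a", "b"), c(1, 1), c(5, 5), c("A", "C"), c("C", "G")),
    "distinct map position"
  )
  cat <- neutral_catalogue(4)
  expect_error(haploid_pop(matrix(0L, 0, 4), character(0), cat), "at least one")
  expect_error(haploid_pop(matrix(0L, 2, 3), c("a", "alpha"), cat), "width")
  expect_error(haploid_pop(matrix(0L, 2, 4), c("a", "b"), cat), "mating type")
  expect_error(haploid_pop(matrix(2L, 2, 4), c("a", "alpha"), cat), "0")
})

test_that("sim_config rejects out-of-range parameters", {
  expect_error(sim_config(population_size = 1), "population_size")
  expect_error(sim_config(selection_fraction = 0), "selection_fraction")
  expect_error(sim_config(selection_fraction = 1.2), "selection_fraction")
  expect_error(sim_config(selfing_probability = -0.1), "selfing_probability")
  expect_error(sim_config(fitness_noise_sd = -1), "fitness_noise_sd")
})

test_that("UV mutagenesis: zero rate is identity, excess rate errors, Poisson mean holds", {
  cat21 <- neutral_catalogue(21)
  pool <- wildtype_pool(200, cat21)
  cfg0 <- sim_config(uv_mutation_rate = 0)
  expect_identical(uv_mutagenize(pool, cfg0)$alleles, pool$alleles)

  expect_error(uv_mutagenize(pool, sim_config(uv_mutation_rate = 30)),
               "exceeds catalogue size")

  set.seed(42)
  big <- wildtype_pool(10000, cat21)
  mut <- uv_mutagenize(big, sim_config(uv_mutation_rate = 6))
  per_genome <- rowSums(mut$alleles)
  se <- sqrt(6 / 10000)
  expect_lt(abs(mean(per_genome) - 6), 3 * se)
  # draws are without replacement: never more than one alt per locus & genome
  expect_true(all(mut$alleles %in% c(0L, 1L)))
})

test_that("truncation selection conserves frequencies without selection and enriches a driver", {
  cat <- neutral_catalogue(5)
  set.seed(1)
  pool <- uv_mutagenize(wildtype_pool(400, cat), sim_config(uv_mutation_rate = 1))
  # no selection: fraction 1, noise irrelevant -> multinomial resample only
  cfg <- sim_config(population_size = 400, selection_fraction = 1,
                    fitness_noise_sd = 0)
  reps <- replicate(200, allele_frequencies(select_population(pool, cfg)))
  delta <- rowMeans(reps) - allele_frequencies(pool)
  se <- sqrt(allele_frequencies(pool) * (1 - allele_frequencies(pool)) /
               (400 * 200))
  expect_true(all(abs(delta) <= 3 * pmax(se, 1e-6)))

  # driver locus: post-selection frequency never below pre-selection
  drv_cat <- neutral_catalogue(5)
  drv_cat$effect_size <- c(1, 0, 0, 0, 0)
  cfg_sel <- sim_config(population_size = 400, selection_fraction = 0.1,
                        fitness_noise_sd = 0)
  set.seed(7)
  pool2 <- uv_mutagenize(wildtype_pool(400, drv_cat),
                         sim_config(uv_mutation_rate = 1))
  pre <- allele_frequencies(pool2)[1]
  post <- replicate(100, allele_frequencies(select_population(pool2, cfg_sel))[1])
  expect_true(all(post >= pre))
})

test_that("mating pairs opposite types without replacement and gives Hardy-Weinberg genotypes", {
  cat <- neutral_catalogue(2)
  # 1 MATa + 1 MATalpha -> exactly one diploid made of the two inputs
  al <- rbind(c(1L, 0L), c(0L, 1L))
  tiny <- haploid_pop(al, c("a", "alpha"), cat)
  dip <- mate_pool(tiny)
  expect_equal(n_genomes(dip), 1L)
  expect_setequal(list(drop(dip$hap1), drop(dip$hap2)),
                  list(c(1L, 0L), c(0L, 1L)))

  # single mating type errors
  expect_error(mate_pool(haploid_pop(al, c("a", "a"), cat)), "both mating types")

  # Hardy-Weinberg: haploid frequency p -> homozygote fraction ~ p^2
  p <- 0.3
  set.seed(11)
  n <- 4000
  alleles <- cbind(rbinom(n, 1L, p), rbinom(n, 1L, p))
  pool <- haploid_pop(alleles, rep(c("a", "alpha"), n / 2), cat)
  dip <- mate_pool(pool)
  hom <- mean(dip$hap1[, 1] + dip$hap2[, 1] == 2L)
  het <- mean(dip$hap1[, 1] + dip$hap2[, 1] == 1L)
  se2 <- sqrt(p^2 * (1 - p^2) / n_genomes(dip))
  se1 <- sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / n_genomes(dip))
  expect_lt(abs(hom - p^2), 3 * se2)
  expect_lt(abs(het - 2 * p * (1 - p)), 3 * se1)

  # surplus of the majority type is discarded
  lop <- haploid_pop(matrix(0L, 10, 2), c(rep("a", 7), rep("alpha", 3)), cat)
  expect_equal(n_genomes(mate_pool(lop)), 3L)
})

test_that("meiosis: Mendelian segregation, Haldane recombination, independent assortment", {
  cfg <- sim_config(selfing_probability = 0)

  # heterozygous diploid: spore alt fraction is 1/2 (2:2 segregation)
  cat1 <- neutral_catalogue(2)
  n <- 500
  dip <- diploid_pop(matrix(1L, n, 2), matrix(0L, n, 2), cat1)
  set.seed(3)
  spores <- sporulate_pool(dip, cfg)
  expect_equal(n_genomes(spores), 4L * n)
  expect_equal(unname(allele_frequencies(spores)), c(0.5, 0.5))

  expect_error(sporulate_pool(spores, cfg), "diploid")

  # two loci 50 cM apart in cis: recombinant fraction ~ (1 - e^-1)/2
  cat50 <- two_locus_catalogue(50)
  set.seed(5)
  n <- 2500
  dip <- diploid_pop(matrix(1L, n, 2), matrix(0L, n, 2), cat50)
  spores <- sporulate_pool(dip, cfg)
  rec <- mean(spores$alleles[, 1] != spores$alleles[, 2])
  r_expect <- haldane_r(0.5)
  se <- sqrt(r_expect * (1 - r_expect) / (4 * n))
  expect_lt(abs(rec - r_expect), 3 * se)

  # different chromosomes: recombinant fraction ~ 1/2
  cat_un <- two_locus_catalogue(0, chromosomes = c(1L, 2L))
  cat_un$map_position_cM <- c(10, 10)
  set.seed(6)
  dip <- diploid_pop(matrix(1L, n, 2), matrix(0L, n, 2), cat_un)
  spores <- sporulate_pool(dip, cfg)
  rec <- mean(spores$alleles[, 1] != spores$alleles[, 2])
  se <- sqrt(0.25 / (4 * n))
  expect_lt(abs(rec - 0.5), 3 * se)
})

test_that("recursive rounds return the archived schedule and propagate ploidy", {
  cat <- neutral_catalogue(4)
  cfg <- sim_config(population_size = 60, rounds = 0, seed = 2)
  expect_named(run_gs_rounds(cfg, cat), "UV")

  cfg3 <- sim_config(population_size = 60, rounds = 3, seed = 2)
  samples <- run_gs_rounds(cfg3, cat)
  expect_named(samples, c("UV", "R1", "R2", "R3"))
  expect_s3_class(samples$UV, "haploid_pop")
  for (r in c("R1", "R2", "R3")) expect_s3_class(samples[[r]], "diploid_pop")
})

test_that("neutral drift conserves expected frequencies across rounds", {
  cat <- neutral_catalogue(3)
  base <- sim_config(population_size = 80, uv_mutation_rate = 1,
                     founder_boost = 0, selection_fraction = 1,
                     fitness_noise_sd = 0, rounds = 3)
  freqs <- vapply(1:200, function(s) {
    cfg <- base; cfg$seed <- s
    samp <- run_gs_rounds(cfg, cat)
    c(allele_frequencies(samp$UV), allele_frequencies(samp$R3))
  }, numeric(6))
  uv <- rowMeans(freqs[1:3, , drop = FALSE])
  r3 <- rowMeans(freqs[4:6, , drop = FALSE])
  # paired SE of the per-replicate difference
  se <- apply(freqs[4:6, , drop = FALSE] - freqs[1:3, , drop = FALSE], 1,
              stats::sd) / sqrt(200)
  expect_true(all(abs(r3 - uv) <= 3 * pmax(se, 1e-8)))
})

test_that("linkage between neutral loci decays over rounds", {
  cat <- two_locus_catalogue(20)
  base <- sim_config(population_size = 120, uv_mutation_rate = 0,
                     founder_boost = 0, founder_cells = 30,
                     selection_fraction = 1, fitness_noise_sd = 0,
                     selfing_probability = 0, rounds = 4)
  r2_of <- function(pop) {
    h <- rbind(pop$hap1, pop$hap2)
    if (stats::sd(h[, 1]) == 0 || stats::sd(h[, 2]) == 0) return(NA_real_)
    stats::cor(h[, 1], h[, 2])^2
  }
  r2 <- vapply(1:150, function(s) {
    cfg <- base; cfg$seed <- s
    samp <- run_gs_rounds(cfg, cat, founder_loci = c("locA", "locB"))
    vapply(samp[c("R1", "R2", "R3", "R4")], r2_of, numeric(1))
  }, numeric(4))
  means <- rowMeans(r2, na.rm = TRUE)
  # monotone decay in expectation: later rounds never above earlier ones
  expect_true(all(diff(means) < 0.02))
  expect_lt(means[4], means[1])
})

test_that("selfed tetrads can regenerate homozygous diploids", {
  cat <- neutral_catalogue(2)
  n <- 800
  dip <- diploid_pop(matrix(1L, n, 2), matrix(0L, n, 2), cat)
  set.seed(9)
  spores <- sporulate_pool(dip, sim_config(selfing_probability = 1))
  remated <- mate_pool(spores)
  dose <- remated$hap1 + remated$hap2
  # within a tetrad the two a/alpha pairings are equally likely: the
  # complementary pairing is fully het, the independent one is homozygous
  # at half its loci -> overall homozygote fraction 1/4
  hom <- mean(dose == 2L | dose == 0L)
  se <- sqrt(0.25 * 0.75 / length(dose))
  expect_lt(abs(hom - 0.25), 4 * se)
})

test_that("amplicon sequencing follows the binomial error model", {
  cat <- neutral_catalogue(4)
  pool <- wildtype_pool(10, cat)
  expect_error(simulate_amplicon_counts(pool, 0), "positive")

  set.seed(10)
  counts <- simulate_amplicon_counts(pool, 1e4, error_rate = 0)
  expect_true(all(counts$alt_reads == 0))

  # p = 0.5 at high coverage: estimate within 3 binomial SE
  half <- haploid_pop(rbind(matrix(1L, 50, 4), matrix(0L, 50, 4)),
                      rep(c("a", "alpha"), 50), cat)
  set.seed(12)
  counts <- simulate_amplicon_counts(half, 1e5, error_rate = 0)
  f <- counts$alt_reads / counts$total_reads
  expect_true(all(abs(f - 0.5) < 3 * sqrt(0.25 / 1e5)))

  # pure error floor: expected alt fraction = error_rate / 3
  big_cat <- neutral_catalogue(200)
  wt <- wildtype_pool(10, big_cat)
  set.seed(13)
  counts <- simulate_amplicon_counts(wt, 1e5, error_rate = 0.003)
  pooled <- sum(counts$alt_reads) / sum(counts$total_reads)
  se <- sqrt(0.001 * 0.999 / sum(counts$total_reads))
  expect_lt(abs(pooled - 0.001), 3 * se)
})

test_that("isolate picking is uniform without bias and reports zygosity faithfully", {
  cat <- neutral_catalogue(2)
  # single homozygous-alt clone: all isolates report homo
  clone <- diploid_pop(matrix(1L, 10, 2), matrix(1L, 10, 2), cat)
  expect_true(all(simulate_isolates(clone, 5) == "homo"))
  expect_error(simulate_isolates(clone, 0), "positive")
  expect_error(simulate_isolates(clone, 11), "more isolates")

  # unbiased picking: genomes tagged by a unique binary genotype code;
  # chi-square GOF of pick counts against uniform
  cat4 <- neutral_catalogue(4)
  n <- 8
  code <- t(sapply(0:(n - 1), function(i) as.integer(intToBits(i)[1:4])))
  dip <- diploid_pop(code, code, cat4)
  set.seed(14)
  picks <- replicate(800, {
    iso <- simulate_isolates(dip, 1, fitness_bias = 0)
    sum((iso[1, ] == "homo") * 2^(0:3)) + 1L
  })
  tab <- table(factor(picks, levels = 1:n))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("identical config and seed reproduce the simulation bit-identically", {
  cat <- demo_catalogue()
  cfg <- sim_config(population_size = 150, rounds = 2, seed = 33)
  a <- run_gs_rounds(cfg, cat, founder_loci = founder_ids())
  b <- run_gs_rounds(cfg, cat, founder_loci = founder_ids())
  expect_identical(a, b)
})
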