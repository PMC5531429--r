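test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_sites = 500L, seed = 42L)
  p1 <- simulate_sources(cfg)
  p2 <- simulate_sources(cfg)
  expect_identical(p1, p2)
  a1 <- simulate_admixed(p1, "Adm", "PopA", "PopB", 0.3, 20, 4, seed = 9L)
  a2 <- simulate_admixed(p2, "Adm", "PopA", "PopB", 0.3, 20, 4, seed = 9L)
  expect_identical(a1, a2)
  r1 <- simulate_reads(a1, config = cfg)
  r2 <- simulate_reads(a2, config = cfg)
  expect_identical(r1, r2)
})

test_that("vanishing drift gives nearly undifferentiated populations", {
  make <- function(F, seed) {
    cfg <- sim_config(
      n_sites = 10000L,
      sources = data.frame(name = c("A", "B"), F = F,
                           n_founders = 30L, n_samples = 15L),
      seed = seed)
    simulate_sources(cfg)
  }
  low <- panel_frequencies(make(1e-6, 5L))
  high <- panel_frequencies(make(0.3, 5L))
  # at F -> 0 the Beta draws collapse onto p: between-population frequency
  # differences reduce to pure sampling noise, far below the drifted case
  expect_lt(mean(abs(low$p[1, ] - low$p[2, ])),
            0.5 * mean(abs(high$p[1, ] - high$p[2, ])))
  # and monomorphic sites become rarer as drift vanishes
  mono <- function(f) mean(f$p[1, ] %in% c(0, 1))
  expect_lt(mono(low), mono(high))
})

test_that("two sources at F = 0.1 give the Hudson FST of the generative model", {
  # expected value 0.1450 computed by an independent Monte-Carlo oracle of
  # the site marginal (Balding-Nichols frequencies + founder-pool sampling,
  # 2e6 sites): mean(num)/mean(den) of the Hudson estimator
  cfg <- sim_config(n_sites = 5000L, seed = 11L)
  panel <- simulate_sources(cfg)
  f <- panel_frequencies(panel)
  nh <- 20
  p1 <- f$p[1, ]; p2 <- f$p[2, ]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (nh - 1) - p2 * (1 - p2) / (nh - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_lt(abs(mean(num) / mean(den) - 0.1450), 0.03)
})

test_that("admixture tract process has the configured ancestry and scale", {
  cfg <- sim_config(n_sites = 2000L, seed = 3L)
  panel <- simulate_sources(cfg)
  # alpha = 1: every tract from source_a
  p1 <- simulate_admixed(panel, "All_A", "PopA", "PopB", 1, 30, 5, seed = 2L)
  expect_true(all(truth_ancestry_fraction(p1, "PopA") == 1))
  # alpha = 0.25, 50 haplotypes: mean fraction near 0.25
  p2 <- simulate_admixed(panel, "Adm", "PopA", "PopB", 0.25, 30, 25, seed = 7L)
  expect_lt(abs(mean(truth_ancestry_fraction(p2, "PopA")) - 0.25), 0.05)
  # doubling g roughly doubles the mean tract count (Poisson switch process)
  n_tracts <- function(g, seed) {
    p <- simulate_admixed(panel, "T", "PopA", "PopB", 0.5, g, 100, seed = seed)
    mean(vapply(p$truth_tracts, nrow, numeric(1)))
  }
  ratio <- (n_tracts(60, 13L) - 1) / (n_tracts(30, 13L) - 1)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("tract bookkeeping matches the copied source labels exactly", {
  cfg <- sim_config(n_sites = 1500L, seed = 8L)
  panel <- simulate_sources(cfg)
  panel <- simulate_admixed(panel, "Adm", "PopA", "PopB", 0.4, 25, 10, seed = 4L)
  # per-site labels recovered from the bp tracts equal the stored labels
  for (h in names(panel$truth_tracts)) {
    tr <- panel$truth_tracts[[h]]
    expect_equal(tr$start_bp[1], 0)
    expect_equal(tr$end_bp[nrow(tr)], panel$chrom_length_bp)
    expect_true(all(tr$start_bp[-1] == tr$end_bp[-nrow(tr)]))
    from_tracts <- tr$source[findInterval(panel$sites$position_bp,
                                          tr$start_bp)]
    expect_identical(from_tracts, panel$truth_sources[[h]])
  }
})

test_that("read simulator obeys its error, damage and depth models", {
  sources <- data.frame(name = "P", F = 0.1, n_founders = 20L, n_samples = 20L)
  # error-free, damage-free: observed always equals truth
  cfg0 <- sim_config(n_sites = 300L, sources = sources, coverage_lambda = 1,
                     deamination_delta = 0, seq_error_eps = 0, seed = 21L)
  panel <- simulate_sources(cfg0)
  pu0 <- simulate_reads(panel, config = cfg0)
  expect_true(all(pu0$observed_allele == pu0$true_allele))

  # terminal C->T flip rate ~ delta at d = 0 (3 binomial SD)
  cfg1 <- sim_config(n_sites = 3000L, sources = sources, coverage_lambda = 3,
                     deamination_delta = 0.3, seq_error_eps = 0,
                     read_length = 10L, seed = 22L)
  panel1 <- simulate_sources(cfg1)
  pu1 <- simulate_reads(panel1, config = cfg1)
  sus <- ifelse(panel1$sites$ref[pu1$site] %in% c("C", "G"), 0L, 1L)
  elig <- panel1$sites$mutation_class[pu1$site] == "transition" &
    pu1$true_allele == sus & pu1$dist_5prime == 0L
  rate <- mean(pu1$observed_allele[elig] != pu1$true_allele[elig])
  n <- sum(elig)
  expect_gt(n, 1000)
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # only eligible reads are ever damaged
  expect_true(all(pu1$observed_allele[!pu1$damage_flag] ==
                    pu1$true_allele[!pu1$damage_flag]))

  # Poisson zero class at lambda = 0.1
  cfg2 <- sim_config(n_sites = 5000L, sources = sources, coverage_lambda = 0.1,
                     seed = 23L)
  panel2 <- simulate_sources(cfg2)
  pu2 <- simulate_reads(panel2, config = cfg2)
  n_cells <- 20 * 5000
  covered <- nrow(unique(pu2[, c("individual_idx", "site")])) / n_cells
  expect_lt(abs(covered - (1 - exp(-0.1))), 0.01)
})

test_that("imputed-call emulator hits its configured accuracies", {
  cfg <- sim_config(n_sites = 4000L, sources = data.frame(
    name = "P", F = 0.1, n_founders = 20L, n_samples = 25L), seed = 31L)
  panel <- simulate_sources(cfg)
  gm <- panel_genotypes(panel)
  # accuracy 1 reproduces truth with correct GP argmax
  perfect <- emulate_imputed_calls(gm, accuracy_schedule(1, 1, 1), seed = 1L)
  expect_identical(perfect$geno, gm$geno)
  expect_true(all(apply(perfect$gp, c(1, 2), which.max) - 1L == perfect$geno))
  gp_sums <- perfect$gp[, , 1] + perfect$gp[, , 2] + perfect$gp[, , 3]
  expect_true(all(abs(gp_sums - 1) < 1e-9))

  # het accuracy 0.95 recovered within 3 binomial SD
  calls <- emulate_imputed_calls(gm, accuracy_schedule(0.99, 0.95, 0.99),
                                 seed = 2L)
  het <- gm$geno == 1L
  n_het <- sum(het)
  expect_gt(n_het, 10000)
  conc <- mean(calls$geno[het] == 1L)
  expect_lt(abs(conc - 0.95), 3 * sqrt(0.95 * 0.05 / n_het))

  # accuracy rising in MAF gives non-decreasing measured accuracy
  rising <- accuracy_schedule(hom_ref = seq(0.85, 0.999, length.out = 100),
                              het = seq(0.85, 0.999, length.out = 100),
                              hom_alt = seq(0.85, 0.999, length.out = 100))
  calls2 <- emulate_imputed_calls(gm, rising, seed = 3L)
  acc <- imputation_accuracy(gm, calls2, bin_width = 0.05)
  pooled <- sapply(sort(unique(acc$table$bin_lo)), function(b) {
    t <- acc$table[acc$table$bin_lo == b & acc$table$n_compared > 0, ]
    sum(t$n_concordant) / sum(t$n_compared)
  })
  pooled <- pooled[!is.na(pooled)]
  # allow small sampling wiggle on a monotone trend
  expect_true(all(diff(pooled) > -0.02))
})

test_that("trait simulator defines the score ground truth", {
  cfg <- sim_config(n_sites = 1000L, seed = 41L)
  panel <- simulate_sources(cfg)
  tr0 <- simulate_trait(panel, n_causal = 0L, n_null = 20L, seed = 1L)
  expect_true(all(tr0$true_value == 0))
  tr <- simulate_trait(panel, n_causal = 50L, heritability = 0.5,
                       n_null = 50L, seed = 2L)
  gm <- panel_genotypes(panel)
  sc <- polygenic_score(gm, tr$effects, p_threshold = 0.001)
  expect_gt(cor(sc$score, tr$true_value), 0.99)
  expect_equal(sc$n_panel_sites, 50L)  # p-filter keeps causal SNPs only
})
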