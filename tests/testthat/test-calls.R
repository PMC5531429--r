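test_that("pseudo-haploid calling samples one read uniformly", {
  sources <- data.frame(name = "P", F = 0.1, n_founders = 10L, n_samples = 10L)
  cfg <- sim_config(n_sites = 200L, sources = sources, coverage_lambda = 2,
                    deamination_delta = 0, seq_error_eps = 0, seed = 1L)
  panel <- simulate_sources(cfg)
  pu <- simulate_reads(panel, config = cfg)
  gm <- pseudo_haploid_call(pu, seed = 5L)
  expect_equal(gm$ploidy, 1L)
  # every call matches one of the reads observed at that cell
  for (i in sample(nrow(pu), 50)) {
    cell <- pu[pu$individual_idx == pu$individual_idx[i] &
                 pu$site == pu$site[i], ]
    expect_true(gm$geno[pu$individual_idx[i], pu$site[i]] %in%
                  cell$observed_allele)
  }
  # zero-depth cells are missing
  covered <- matrix(FALSE, 10, 200)
  covered[cbind(pu$individual_idx, pu$site)] <- TRUE
  expect_true(all(is.na(gm$geno[!covered])))
  expect_true(!anyNA(gm$geno[covered]))

  # a balanced het cell yields alt with probability 1/2 across seeds:
  # construct 10k cells of depth 2 with one ref and one alt read
  n <- 10000L
  fake <- data.frame(
    individual_idx = rep(1L, 2 * n), individual = "x",
    site = rep(seq_len(n), each = 2),
    true_chromosome = 1L, true_allele = rep(c(0L, 1L), n),
    observed_allele = rep(c(0L, 1L), n), dist_5prime = 0L,
    damage_flag = FALSE, stringsAsFactors = FALSE)
  sites <- data.frame(position_bp = seq_len(n), genetic_pos_cM = seq_len(n),
                      ref = "A", alt = "C", mutation_class = "transversion")
  attr(fake, "sites") <- sites
  attr(fake, "individuals") <- "x"
  class(fake) <- c("site_pileup", "data.frame")
  calls <- pseudo_haploid_call(fake, seed = 2L)
  frac <- mean(calls$geno == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("filters follow the GP -> transversion -> completeness -> MAF order", {
  sites <- data.frame(
    position_bp = c(1e6, 2e6, 3e6),
    genetic_pos_cM = 1:3, ref = c("C", "A", "G"), alt = c("T", "C", "A"),
    mutation_class = c("transition", "transversion", "transition"),
    stringsAsFactors = FALSE)
  geno <- matrix(c(0L, 1L, 2L,
                   1L, 1L, 0L), 2, 3, byrow = TRUE)
  gm <- genotype_matrix(geno, 2L, sites, c("i1", "i2"))
  # all-permissive spec is the identity
  out <- apply_filters(gm)
  expect_identical(out$geno, gm$geno)
  # transversions_only keeps only the A/C site
  out2 <- apply_filters(gm, transversions_only = TRUE)
  expect_equal(ncol(out2$geno), 1L)
  expect_equal(out2$sites$ref, "A")

  # MAF filter: constructed 10-site matrix, 4 sites below 0.05
  n_ind <- 20L
  g10 <- matrix(0L, n_ind, 10)
  g10[1, 1:4] <- 1L                      # MAF 1/40 = 0.025 at 4 sites
  g10[1:10, 5:10] <- 1L                  # MAF 0.25 at 6 sites
  sites10 <- data.frame(position_bp = (1:10) * 1e6, genetic_pos_cM = 1:10,
                        ref = "A", alt = "C",
                        mutation_class = "transversion")
  gm10 <- genotype_matrix(g10, 2L, sites10, sprintf("i%d", 1:n_ind))
  out3 <- apply_filters(gm10, maf_min = 0.05)
  expect_equal(ncol(out3$geno), 6L)
  expect_equal(attr(out3, "filter_report")$sites_dropped_maf, 4L)

  # idempotence
  spec_out <- apply_filters(gm10, maf_min = 0.05, transversions_only = TRUE,
                            require_complete = TRUE)
  twice <- apply_filters(spec_out, maf_min = 0.05, transversions_only = TRUE,
                         require_complete = TRUE)
  expect_identical(spec_out$geno, twice$geno)
})

test_that("GP masking is per-genotype and feeds the completeness filter", {
  sites <- data.frame(position_bp = c(1e6, 2e6), genetic_pos_cM = 1:2,
                      ref = "A", alt = "C", mutation_class = "transversion")
  geno <- matrix(c(1L, 2L, 0L, 1L), 2, 2)
  gp <- array(0, c(2, 2, 3))
  gp[1, 1, ] <- c(0.05, 0.90, 0.05)   # below 0.99: masked
  gp[2, 1, ] <- c(1, 0, 0)
  gp[1, 2, ] <- c(0, 0, 1)
  gp[2, 2, ] <- c(0, 0.995, 0.005)
  gm <- genotype_matrix(geno, 2L, sites, c("i1", "i2"), gp = gp)
  out <- apply_filters(gm, gp_min = 0.99)
  expect_true(is.na(out$geno[1, 1]))
  expect_equal(attr(out, "filter_report")$genotypes_masked_gp, 1L)
  out2 <- apply_filters(gm, gp_min = 0.99, require_complete = TRUE)
  expect_equal(ncol(out2$geno), 1L)     # masked call removes site 1
  expect_error(apply_filters(genotype_matrix(geno, 2L, sites, c("a", "b")),
                             gp_min = 0.99),
               "requires a matrix with GP")
  # masked-matrix MAF equals a brute-force recount
  g <- out$geno
  p_brute <- sum(g[, 2], na.rm = TRUE) / (2 * sum(!is.na(g[, 2])))
  f <- allele_frequencies(out, c(i1 = "P", i2 = "P"))
  expect_equal(unname(f$p[1, 2]), p_brute)
})

test_that("allele frequencies follow the haploid/diploid counting rules", {
  sites <- data.frame(position_bp = 1e6, genetic_pos_cM = 1,
                      ref = "A", alt = "C", mutation_class = "transversion")
  # single diploid het
  gm1 <- genotype_matrix(matrix(1L, 1, 1), 2L, sites, "a")
  f1 <- allele_frequencies(gm1, c(a = "P"))
  expect_equal(unname(f1$p[1, 1]), 0.5)
  expect_equal(unname(f1$n[1, 1]), 2)
  # three diploids 0/1/2
  gm2 <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), 2L, sites,
                         c("a", "b", "c"))
  f2 <- allele_frequencies(gm2, c(a = "P", b = "P", c = "P"))
  expect_equal(unname(f2$p[1, 1]), 0.5)
  expect_equal(unname(f2$n[1, 1]), 6)
  # mixed ploidy via bind: haploid 1 + diploid 2 -> 3/3
  gmh <- genotype_matrix(matrix(1L, 1, 1), 1L, sites, "h")
  gmd <- genotype_matrix(matrix(2L, 1, 1), 2L, sites, "d")
  fh <- allele_frequencies(gmh, c(h = "P"))
  fd <- allele_frequencies(gmd, c(d = "P"))
  pooled <- (fh$p[1, 1] * fh$n[1, 1] + fd$p[1, 1] * fd$n[1, 1]) /
    (fh$n[1, 1] + fd$n[1, 1])
  expect_equal(unname(pooled), 1.0)
  expect_equal(unname(fh$n[1, 1] + fd$n[1, 1]), 3)
  expect_error(allele_frequencies(gm1, c(b = "P")), "unlabelled")
})

test_that("accuracy table is exact on trivial call sets and conserves totals", {
  cfg <- sim_config(n_sites = 800L, sources = data.frame(
    name = "P", F = 0.1, n_founders = 15L, n_samples = 15L), seed = 2L)
  panel <- simulate_sources(cfg)
  gm <- panel_genotypes(panel)
  acc <- imputation_accuracy(gm, gm)
  pop <- acc$table[acc$table$n_compared > 0, ]
  expect_true(all(pop$accuracy == 1))
  expect_equal(acc$missingness, 0)

  # all-missing calls
  empty <- genotype_matrix(matrix(NA_integer_, nrow(gm$geno), ncol(gm$geno)),
                           2L, gm$sites, gm$individuals)
  acc2 <- imputation_accuracy(gm, empty)
  expect_equal(acc2$missingness, 1)
  expect_true(all(acc2$table$n_compared == 0))

  # marginal over bins equals unstratified concordance
  calls <- emulate_imputed_calls(gm, accuracy_schedule(0.95, 0.9, 0.92),
                                 seed = 7L)
  acc3 <- imputation_accuracy(gm, calls)
  expect_equal(sum(acc3$table$n_concordant) / sum(acc3$table$n_compared),
               acc3$overall)
  expect_equal(sum(acc3$table$n_compared), sum(!is.na(gm$geno)))
  expect_error(imputation_accuracy(gm, gm1 <- genotype_matrix(
    matrix(0L, 1, 1), 2L,
    data.frame(position_bp = 1, genetic_pos_cM = 1, ref = "A", alt = "C",
               mutation_class = "transversion"), "z")),
    "aligned")
})
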