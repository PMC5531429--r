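test_that("forward-backward equals exhaustive donor-path enumeration", {
  set.seed(20)
  for (rep in 1:5) {
    S <- sample(3:7, 1); K <- sample(2:3, 1)
    y <- rbinom(S, 1, 0.5)
    D <- matrix(rbinom(K * S, 1, 0.5), K, S)
    gpos <- sort(runif(S, 0, 10))
    rho <- runif(1, 0.2, 2); theta <- runif(1, 0.05, 0.3)
    total <- max(gpos) + 1
    res <- ls_paint(y, D, gpos, total, painting_params(rho, theta))
    orc <- oracle_paint(y, D, gpos, rho, theta, total)
    expect_lt(max(abs(res$lengths_cM - orc$lengths)), 1e-10)
    expect_lt(max(abs(res$chunks - orc$chunks)), 1e-10)
    expect_lt(abs(res$loglik - orc$loglik), 1e-10)
  }
})

test_that("painting degenerate donor sets behave as expected", {
  set.seed(21)
  S <- 50
  y <- rbinom(S, 1, 0.5)
  gpos <- sort(runif(S, 0, 80))
  # single donor: full map length, one chunk
  res1 <- ls_paint(y, matrix(y, 1, S), gpos, 100,
                   painting_params(rho = 1, theta = 0.01))
  expect_equal(unname(res1$lengths_cM), 100)
  expect_equal(unname(res1$chunks), 1)
  # K identical donors: exchangeability gives equal shares
  K <- 5
  D <- matrix(rep(y, each = K), K, S)
  resK <- ls_paint(y, D, gpos, 100, painting_params(rho = 1, theta = 0.1))
  expect_lt(max(abs(resK$lengths_cM - 100 / K)), 1e-9)
  expect_lt(max(abs(resK$chunks - resK$chunks[1])), 1e-9)
  # permuting donors permutes outputs identically
  D2 <- matrix(rbinom(3 * S, 1, 0.5), 3, S)
  perm <- c(3, 1, 2)
  ra <- ls_paint(y, D2, gpos, 100, painting_params(0.5, 0.1))
  rb <- ls_paint(y, D2[perm, ], gpos, 100, painting_params(0.5, 0.1))
  expect_equal(ra$lengths_cM[perm], rb$lengths_cM, tolerance = 1e-12)
  expect_equal(ra$chunks[perm], rb$chunks, tolerance = 1e-12)
  expect_error(ls_paint(y, matrix(0L, 0, S), gpos, 100), "at least one donor")
})

test_that("coancestry rows conserve total copied length", {
  cfg <- sim_config(n_sites = 800L, sources = data.frame(
    name = c("A", "B"), F = 0.1, n_founders = 15L,
    n_samples = c(5L, 5L)), seed = 30L)
  panel <- simulate_sources(cfg)
  cm <- paint_all(panel)
  expect_true(all(abs(rowSums(cm$lengths_cM) - 2 * cm$total_cM) < 1e-6))
  expect_true(all(cm$chunks >= 0))
  # self is never a donor
  expect_true(all(diag(cm$chunks[cm$recipient_info$individual,
                                 cm$donor_info$individual]) == 0))
  # two diverged populations: within-donation beats between-donation
  bypop <- donation_by_population(cm, "lengths_cM")
  own <- cm$recipient_info$population
  for (i in seq_len(nrow(bypop)))
    expect_gt(bypop[i, own[i]], bypop[i, setdiff(colnames(bypop), own[i])])
})

test_that("donation differential and its rank test find constructed excess", {
  cfg <- sim_config(n_sites = 1200L, sources = data.frame(
    name = c("Farmer", "HGX", "HGRef"), F = c(0.1, 0.15, 0.15),
    n_founders = 15L, n_samples = c(6L, 4L, 4L)), seed = 33L)
  panel <- simulate_sources(cfg)
  panel <- simulate_admixed(panel, "WithX", "HGX", "Farmer", 0.25, 25, 6,
                            seed = 1L)
  panel <- simulate_admixed(panel, "NoX", "HGRef", "Farmer", 0.25, 25, 6,
                            seed = 2L)
  info <- panel$hap_info
  recip <- unique(info$individual[info$population %in% c("WithX", "NoX")])
  donors <- unique(info$individual[info$population %in%
                                     c("Farmer", "HGX", "HGRef")])
  cm <- paint_all(panel, recipients = recip, donors = donors)
  d <- donation_differential(cm, "HGX", "HGRef")
  # antisymmetry
  d_rev <- donation_differential(cm, "HGRef", "HGX")
  expect_equal(d, -d_rev, tolerance = 1e-12)
  ga <- cm$recipient_info$individual[cm$recipient_info$population == "WithX"]
  gb <- cm$recipient_info$individual[cm$recipient_info$population == "NoX"]
  expect_gt(median(d[ga]), median(d[gb]))
  ct <- donation_contrast_test(d, ga, gb)
  expect_lt(ct$p_value, 0.05)
  # X = ref differential is identically zero
  expect_true(all(donation_differential(cm, "HGX", "HGX") == 0))
})

test_that("Mann-Whitney contrast is exact for small separated groups", {
  d <- c(a1 = 1, a2 = 2, a3 = 3, a4 = 4, a5 = 5,
         b1 = 6, b2 = 7, b3 = 8, b4 = 9, b5 = 10)
  ct <- donation_contrast_test(d, paste0("a", 1:5), paste0("b", 1:5))
  expect_true(ct$exact)
  expect_equal(ct$p_value, 2 / 252, tolerance = 1e-12)
  # rank test is invariant to monotone transforms
  ct2 <- donation_contrast_test(exp(d), paste0("a", 1:5), paste0("b", 1:5))
  expect_equal(ct$p_value, ct2$p_value)
  # identical groups: U at its null mean
  d2 <- c(x1 = 1, x2 = 2, x3 = 3, y1 = 1.5, y2 = 2.5, y3 = 0.5)
  ct3 <- donation_contrast_test(d2, c("x1", "x2", "x3"), c("y1", "y2", "y3"))
  expect_gt(ct3$p_value, 0.5)
})

test_that("TVD of donation vectors follows the formula and its bounds", {
  cm <- structure(list(
    chunks = matrix(c(5, 3, 2,
                      2, 3, 5,
                      5, 3, 2,
                      2, 3, 5), 4, 3, byrow = TRUE,
                    dimnames = list(c("r1", "r2", "r3", "r4"),
                                    c("T1", "T2", "T3"))),
    lengths_cM = matrix(1, 4, 3),
    recipient_info = data.frame(individual = c("r1", "r2", "r3", "r4"),
                                population = "R"),
    donor_info = data.frame(individual = c("T1", "T2", "T3"),
                            population = c("T1", "T2", "T3")),
    total_cM = 100), class = "coancestry_matrix")
  tv <- tvd_donation(cm, c("r1", "r3"), c("r2", "r4"))
  expect_equal(tv$tvd, 0.3)       # (0.5,0.3,0.2) vs (0.2,0.3,0.5)
  expect_equal(tvd_donation(cm, c("r1", "r3"), c("r1", "r3"))$tvd, 0)
  # random vectors: bounds and symmetry
  set.seed(4)
  for (i in 1:20) {
    cm$chunks[] <- runif(12)
    t12 <- tvd_donation(cm, c("r1", "r2"), c("r3", "r4"))
    t21 <- tvd_donation(cm, c("r3", "r4"), c("r1", "r2"))
    expect_gte(t12$tvd, 0); expect_lte(t12$tvd, 1)
    expect_equal(t12$tvd, t21$tvd, tolerance = 1e-12)
  }
  # disjoint support
  cm$chunks <- matrix(c(1, 0, 0,
                        0, 0, 1,
                        1, 0, 0,
                        0, 0, 1), 4, 3, byrow = TRUE,
                      dimnames = dimnames(cm$chunks))
  expect_equal(tvd_donation(cm, c("r1", "r3"), c("r2", "r4"))$tvd, 1)
})

test_that("coancestry PCA separates populations deterministically", {
  cfg <- sim_config(n_sites = 1000L, sources = data.frame(
    name = c("A", "B"), F = 0.15, n_founders = 15L,
    n_samples = c(6L, 6L)), seed = 35L)
  panel <- simulate_sources(cfg)
  cm <- paint_all(panel)
  pc <- coancestry_pca(cm)
  expect_true(all(diff(pc$explained_variance) <= 1e-9))
  expect_equal(sum(pc$explained_variance[seq_len(min(11, 3))]) <=
                 pc$total_variance + 1e-9, TRUE)
  # PC1 separates the two populations (silhouette-style margin)
  popA <- pc$scores[cm$recipient_info$population == "A", 1]
  popB <- pc$scores[cm$recipient_info$population == "B", 1]
  expect_true(max(popA) < min(popB) || max(popB) < min(popA))
  # deterministic including sign
  pc2 <- coancestry_pca(cm)
  expect_identical(pc$scores, pc2$scores)
})

test_that("greedy clustering recovers clean structure and valid partitions", {
  # identical rows always merge
  cm <- structure(list(
    chunks = matrix(c(10, 2, 3,
                      10, 2, 3,
                      1, 9, 4), 3, 3, byrow = TRUE,
                    dimnames = list(c("a", "b", "c"), c("d1", "d2", "d3"))),
    lengths_cM = matrix(1, 3, 3),
    recipient_info = data.frame(individual = c("a", "b", "c"),
                                population = "R"),
    donor_info = data.frame(individual = c("d1", "d2", "d3"),
                            population = "D"),
    total_cM = 100), class = "coancestry_matrix")
  cl <- greedy_cluster(cm)
  expect_equal(cl$partition[["a"]], cl$partition[["b"]])
  expect_true(all(table(cl$partition) >= 1))
  expect_equal(sort(unique(unname(cl$partition))), seq_len(cl$n_clusters))

  # two well-separated populations: truth recovered exactly
  cfg <- sim_config(n_sites = 1500L, sources = data.frame(
    name = c("A", "B"), F = 0.15, n_founders = 15L,
    n_samples = c(10L, 10L)), seed = 36L)
  panel <- simulate_sources(cfg)
  cmr <- paint_all(panel)
  clr <- greedy_cluster(cmr)
  truth <- cmr$recipient_info$population
  expect_equal(clr$n_clusters, 2L)
  tab <- table(clr$partition, truth)
  expect_true(all(rowSums(tab > 0) == 1))   # clusters are pure
})
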