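test_that("D, f4, f3 match the naive per-site oracle", {
  set.seed(10)
  P <- matrix(runif(4 * 1000, 0.02, 0.98), 4, 1000,
              dimnames = list(c("P1", "P2", "P3", "P4"), NULL))
  freqs <- toy_freqs(P)
  blocks <- make_blocks(freqs$sites, n_blocks = 10)
  d <- d_stat(freqs, c("P1", "P2", "P3", "P4"), blocks)
  expect_equal(d$estimate, oracle_d(P), tolerance = 1e-12)
  f4 <- f4_stat(freqs, c("P1", "P2", "P3", "P4"), blocks)
  expect_equal(f4$estimate, oracle_f4(P), tolerance = 1e-12)
  f3 <- f3_outgroup(freqs, c("P1", "P2", "P3"), blocks, correct_bias = FALSE)
  expect_equal(f3$estimate, oracle_f3(P), tolerance = 1e-12)
  f3c <- f3_outgroup(freqs, c("P1", "P2", "P3"), blocks, correct_bias = TRUE)
  expect_equal(f3c$estimate, oracle_f3(P, nC = rep(100, 1000)),
               tolerance = 1e-12)
  # two-site hand case
  Ph <- matrix(c(0.2, 0.4, 0.8, 0.1,
                 0.5, 0.5, 0.3, 0.9), 4, 2,
               dimnames = list(c("P1", "P2", "P3", "P4"), NULL))
  dh <- d_stat(toy_freqs(Ph), c("P1", "P2", "P3", "P4"),
               blocks = c(1L, 2L))
  expect_equal(dh$estimate, oracle_d(Ph), tolerance = 1e-12)
})

test_that("D and f4 obey their symmetry and invariance properties", {
  set.seed(11)
  P <- matrix(runif(4 * 200, 0.05, 0.95), 4, 200,
              dimnames = list(c("P1", "P2", "P3", "P4"), NULL))
  freqs <- toy_freqs(P)
  blocks <- make_blocks(freqs$sites, n_blocks = 5)
  d <- d_stat(freqs, c("P1", "P2", "P3", "P4"), blocks)
  d_swap12 <- d_stat(freqs, c("P2", "P1", "P3", "P4"), blocks)
  d_swap34 <- d_stat(freqs, c("P1", "P2", "P4", "P3"), blocks)
  expect_equal(d$estimate, -d_swap12$estimate, tolerance = 1e-12)
  expect_equal(d$estimate, -d_swap34$estimate, tolerance = 1e-12)
  f <- f4_stat(freqs, c("P1", "P2", "P3", "P4"), blocks)
  f_swap <- f4_stat(freqs, c("P1", "P2", "P4", "P3"), blocks)
  expect_equal(f$estimate, -f_swap$estimate, tolerance = 1e-12)
  # allele-label flipping (p -> 1-p everywhere) leaves D unchanged
  flip_cols <- sample(200, 80)
  P2 <- P; P2[, flip_cols] <- 1 - P2[, flip_cols]
  d_flip <- d_stat(toy_freqs(P2), c("P1", "P2", "P3", "P4"), blocks)
  expect_equal(d$estimate, d_flip$estimate, tolerance = 1e-12)
  # p1 = p2 at every site: D exactly zero
  P3 <- P; P3[2, ] <- P3[1, ]
  expect_equal(d_stat(toy_freqs(P3), c("P1", "P2", "P3", "P4"),
                      blocks)$estimate, 0)
  # p3 = p4: f4 exactly zero
  P4 <- P; P4[4, ] <- P4[3, ]
  expect_equal(f4_stat(toy_freqs(P4), c("P1", "P2", "P3", "P4"),
                       blocks)$estimate, 0)
  # identical frequency vectors, correction off: f3 = 0
  P5 <- P; P5[2, ] <- P5[1, ]; P5[3, ] <- P5[1, ]
  expect_equal(f3_outgroup(toy_freqs(P5), c("P1", "P2", "P3"), blocks,
                           correct_bias = FALSE)$estimate, 0)
})

test_that("sites with missing frequencies are skipped per statistic", {
  P <- matrix(runif(4 * 50, 0.1, 0.9), 4, 50,
              dimnames = list(c("P1", "P2", "P3", "P4"), NULL))
  P[2, c(3, 17)] <- NA
  d <- d_stat(toy_freqs(P), c("P1", "P2", "P3", "P4"),
              make_blocks(toy_freqs(P)$sites, n_blocks = 5))
  expect_equal(d$n_sites_used, 48L)
  expect_equal(d$estimate, oracle_d(P[, -c(3, 17)]), tolerance = 1e-12)
})

test_that("weighted block jackknife reduces to the textbook formula", {
  # equal weights: compare against the classic delete-one jackknife
  num <- c(1.2, 0.8, 1.1)
  den <- c(2.0, 2.2, 1.9)
  jk <- block_jackknife(num, den, weights = c(1, 1, 1))
  g <- 3
  theta <- sum(num) / sum(den)
  loo <- sapply(1:g, function(j) sum(num[-j]) / sum(den[-j]))
  pseudo <- g * theta - (g - 1) * loo
  expect_equal(jk$estimate, theta)
  expect_equal(jk$se, sqrt(var(pseudo) / g), tolerance = 1e-12)
  # permutation invariance
  perm <- c(3, 1, 2)
  jk2 <- block_jackknife(num[perm], den[perm], weights = c(1, 1, 1))
  expect_equal(jk$estimate, jk2$estimate)
  expect_equal(jk$se, jk2$se, tolerance = 1e-12)
  # identical blocks: SE exactly 0
  jk3 <- block_jackknife(rep(1, 4), rep(2, 4), weights = rep(5, 4))
  expect_equal(jk3$se, 0)
  expect_error(block_jackknife(1, 2, 1), "at least 2")
})

test_that("f4-ratio recovers trivial admixture proportions", {
  set.seed(12)
  S <- 2000
  dO <- rnorm(S, 0, 0.1); dA <- rnorm(S, 0, 0.1); dB <- rnorm(S, 0, 0.1)
  dOut <- rnorm(S, 0, 0.1)
  base <- runif(S, 0.3, 0.7)
  clamp <- function(x) pmin(pmax(x, 0.01), 0.99)
  pO <- clamp(base + dO); pOut <- clamp(base + dOut)
  pA1 <- clamp(base + dA + rnorm(S, 0, 0.02))
  pA2 <- clamp(base + dA + rnorm(S, 0, 0.02))
  pB <- clamp(base + dB)
  blocks <- make_blocks(toy_freqs(matrix(0, 1, S))$sites, n_blocks = 20)
  # X identical to the A lineage: alpha ~ 1
  P1 <- rbind(O = pO, A1 = pA1, A2 = pA2, X = clamp(base + dA), Out2 = pOut)
  fr1 <- f4_ratio(toy_freqs(P1), c("O", "A1", "A2", "X", "Out2"), blocks)
  expect_lt(abs(fr1$estimate - 1), 3 * fr1$se)
  # X identical to the unadmixed other source: alpha ~ 0
  P0 <- rbind(O = pO, A1 = pA1, A2 = pA2, X = pB, Out2 = pOut)
  fr0 <- f4_ratio(toy_freqs(P0), c("O", "A1", "A2", "X", "Out2"), blocks)
  expect_lt(abs(fr0$estimate), 3 * fr0$se)
  # intermediate mixture recovered
  Pm <- rbind(O = pO, A1 = pA1, A2 = pA2,
              X = clamp(0.4 * (base + dA) + 0.6 * pB), Out2 = pOut)
  frm <- f4_ratio(toy_freqs(Pm), c("O", "A1", "A2", "X", "Out2"), blocks)
  expect_lt(abs(frm$estimate - 0.4), 4 * frm$se)
  expect_false(frm$unreliable)
})

test_that("gene flow produces a significant D of the documented sign", {
  # P3 received ancestry from P2's source: excess P2-P3 sharing makes
  # D(P1, P2; P3, P4) negative under the P1-P3/P2-P4 sign convention
  cfg <- sim_config(
    n_sites = 20000L,
    sources = data.frame(name = c("P1", "P2", "P4"), F = 0.1,
                         n_founders = 20L, n_samples = 10L),
    seed = 17L)
  panel <- simulate_sources(cfg)
  # P3 is a sister of P4 (80%) carrying 20% from P2's source
  panel <- simulate_admixed(panel, "P3", "P2", "P4", 0.2, 30, 10, seed = 3L)
  freqs <- panel_frequencies(panel)
  d <- d_stat(freqs, c("P1", "P2", "P3", "P4"),
              make_blocks(panel$sites))
  expect_gt(abs(d$Z), 3)
  expect_lt(d$estimate, 0)
})
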