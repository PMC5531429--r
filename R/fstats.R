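#' Genomic blocks for the block jackknife
#'
#' Splits retained sites into contiguous blocks, by default 5 Mb of physical
#' distance, for delete-one-block jackknife standard errors robust to
#' linkage disequilibrium.
#'
#' @param sites site table (needs `position_bp`).
#' @param block_size_bp physical block size; default 5e6.
#' @param n_blocks alternatively, split into this many equal-SNP-count
#'   blocks.
#' @return integer vector assigning each site to a block `1..B`.
#' @export
make_blocks <- function(sites, block_size_bp = 5e6, n_blocks = NULL) {
  if (!is.null(n_blocks)) {
    blk <- ceiling(seq_along(sites$position_bp) /
                     (length(sites$position_bp) / n_blocks))
  } else {
    blk <- floor(sites$position_bp / block_size_bp) + 1L
    if (!is.null(sites$chrom))   # never span a chromosome boundary
      blk <- paste(sites$chrom, blk)
  }
  as.integer(factor(blk, levels = unique(blk)))
}

#' Weighted delete-one-block jackknife for ratio statistics
#'
#' Estimates `theta = sum(num) / sum(den)` and its standard error by the
#' weighted delete-m jackknife (weights proportional to per-block site
#' counts), which reduces to the textbook unweighted delete-one formula
#' when all blocks carry equal weight.
#'
#' @param num,den per-block sums of the statistic's numerator and
#'   denominator terms.
#' @param weights per-block weights (site counts). Default `den`-agnostic
#'   equal weights.
#' @return list with `estimate`, `se`, `n_blocks`.
#' @export
block_jackknife <- function(num, den, weights = rep(1, length(num))) {
  stopifnot(length(num) == length(den), length(num) == length(weights))
  keep <- weights > 0
  num <- num[keep]; den <- den[keep]; weights <- weights[keep]
  g <- length(num)
  if (g < 2) stop("block jackknife needs at least 2 non-empty blocks")
  theta <- sum(num) / sum(den)
  loo <- vapply(seq_len(g),
                function(j) sum(num[-j]) / sum(den[-j]), numeric(1))
  n <- sum(weights)
  h <- n / weights                       # inverse weight share per block
  theta_dot <- g * theta - sum((1 - weights / n) * loo)
  tau <- h * theta - (h - 1) * loo       # weighted pseudovalues
  var_j <- mean((tau - theta_dot)^2 / (h - 1))
  list(estimate = theta, se = sqrt(var_j), n_blocks = g)
}

fstat_result <- function(stat, pops, jk, n_sites) {
  z <- if (jk$se > 0) jk$estimate / jk$se else NA_real_
  structure(list(statistic = stat, populations = pops,
                 estimate = jk$estimate, se = jk$se, Z = z,
                 n_blocks = jk$n_blocks, n_sites_used = n_sites,
                 degenerate = !is.finite(jk$estimate) || jk$se == 0),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.2f  (%d sites, %d blocks)\n",
              x$statistic, paste(x$populations, collapse = ", "),
              x$estimate, x$se, x$Z, x$n_sites_used, x$n_blocks))
  invisible(x)
}

# shared setup: complete-case site mask + block assignment for a set of pops
fstat_sites <- function(freqs, pops, blocks) {
  missing_pop <- setdiff(pops, freqs$populations)
  if (length(missing_pop))
    stop("populations absent from frequency table: ",
         paste(missing_pop, collapse = ", "))
  P <- freqs$p[pops, , drop = FALSE]
  use <- colSums(is.na(P)) == 0L
  if (is.null(blocks)) blocks <- make_blocks(freqs$sites)
  list(P = P[, use, drop = FALSE], use = use, blocks = blocks[use])
}

block_sums <- function(x, blocks, nb) {
  out <- rep(0, nb)
  s <- tapply(x, blocks, sum)
  out[as.integer(names(s))] <- s
  out
}

#' D-statistic (ABBA-BABA) with block-jackknife standard error
#'
#' `D = sum (p1-p2)(p3-p4) / sum (p1+p2-2 p1 p2)(p3+p4-2 p3 p4)` over sites
#' where all four population frequencies are observed; the standard error
#' comes from the weighted delete-one-block jackknife of the ratio. Sign
#' convention: D > 0 indicates excess allele sharing between P1-P3 and
#' P2-P4 (ABBA > BABA with the formula as written).
#'
#' @param freqs an `allele_freq_table`.
#' @param pops character vector `(P1, P2, P3, P4)`.
#' @param blocks integer block assignment from [make_blocks()] over
#'   `freqs$sites` (default: 5 Mb blocks).
#' @return an `fstat_result` with `estimate`, `se`, `Z`, `n_blocks`,
#'   `n_sites_used`.
#' @export
d_stat <- function(freqs, pops, blocks = NULL) {
  stopifnot(length(pops) == 4L)
  st <- fstat_sites(freqs, pops, blocks)
  P <- st$P
  num <- (P[1, ] - P[2, ]) * (P[3, ] - P[4, ])
  den <- (P[1, ] + P[2, ] - 2 * P[1, ] * P[2, ]) *
    (P[3, ] + P[4, ] - 2 * P[3, ] * P[4, ])
  nb <- max(st$blocks)
  w <- block_sums(rep(1, length(num)), st$blocks, nb)
  jk <- block_jackknife(block_sums(num, st$blocks, nb),
                        block_sums(den, st$blocks, nb), w)
  fstat_result("D", pops, jk, ncol(P))
}

#' f4 statistic with block-jackknife standard error
#'
#' `f4 = mean (p1-p2)(p3-p4)` over complete-case sites; antisymmetric in
#' (P1,P2) and in (P3,P4).
#'
#' @inheritParams d_stat
#' @return an `fstat_result`.
#' @export
f4_stat <- function(freqs, pops, blocks = NULL) {
  stopifnot(length(pops) == 4L)
  st <- fstat_sites(freqs, pops, blocks)
  P <- st$P
  num <- (P[1, ] - P[2, ]) * (P[3, ] - P[4, ])
  nb <- max(st$blocks)
  w <- block_sums(rep(1, length(num)), st$blocks, nb)
  jk <- block_jackknife(block_sums(num, st$blocks, nb), w, w)
  fstat_result("f4", pops, jk, ncol(P))
}

#' Outgroup f3 statistic
#'
#' `f3(C; A, B) = mean (pC-pA)(pC-pB) - hC` where the finite-sample
#' heterozygosity correction `hC = pC (1-pC) / (nC - 1)` is subtracted when
#' `correct_bias = TRUE` (skipped with a warning at sites where `nC <= 1`).
#' Larger values indicate more drift shared by A and B relative to the
#' outgroup C.
#'
#' @param freqs an `allele_freq_table`.
#' @param pops character vector `(C, A, B)`: outgroup first.
#' @param blocks block assignment as in [d_stat()].
#' @param correct_bias apply the finite-sample correction for C.
#' @return an `fstat_result`.
#' @export
f3_outgroup <- function(freqs, pops, blocks = NULL, correct_bias = TRUE) {
  stopifnot(length(pops) == 3L)
  st <- fstat_sites(freqs, pops, blocks)
  P <- st$P
  num <- (P[1, ] - P[2, ]) * (P[1, ] - P[3, ])
  if (correct_bias) {
    nC <- freqs$n[pops[1], st$use]
    if (any(nC <= 1)) {
      warning("nC <= 1 at some sites; heterozygosity correction skipped there")
    }
    h <- ifelse(nC > 1, P[1, ] * (1 - P[1, ]) / (nC - 1), 0)
    num <- num - h
  }
  nb <- max(st$blocks)
  w <- block_sums(rep(1, length(num)), st$blocks, nb)
  jk <- block_jackknife(block_sums(num, st$blocks, nb), w, w)
  fstat_result("f3", pops, jk, ncol(P))
}

#' F4-ratio estimate of an admixture proportion
#'
#' `alpha = f4(O, A1; X, Out2) / f4(O, A1; A2, Out2)`, the classical ratio
#' estimator of the ancestry proportion that X derives from the lineage of
#' A1/A2 (two samples of the source population), with O and Out2 outgroups
#' to the admixture. The standard error jackknifes the full ratio:
#' numerator and denominator f4 sums are both recomputed with each block
#' left out.
#'
#' @param freqs an `allele_freq_table`.
#' @param pops character vector `(O, A1, A2, X, Out2)`.
#' @param blocks block assignment as in [d_stat()].
#' @return an `fstat_result` for alpha, with `unreliable = TRUE` when the
#'   denominator f4 has |Z| < 2.
#' @export
f4_ratio <- function(freqs, pops, blocks = NULL) {
  stopifnot(length(pops) == 5L)
  O <- pops[1]; A1 <- pops[2]; A2 <- pops[3]; X <- pops[4]; Out2 <- pops[5]
  st <- fstat_sites(freqs, c(O, A1, A2, X, Out2), blocks)
  P <- st$P
  num <- (P[1, ] - P[2, ]) * (P[4, ] - P[5, ])   # f4(O, A1; X, Out2) terms
  den <- (P[1, ] - P[2, ]) * (P[3, ] - P[5, ])   # f4(O, A1; A2, Out2) terms
  nb <- max(st$blocks)
  w <- block_sums(rep(1, length(num)), st$blocks, nb)
  den_b <- block_sums(den, st$blocks, nb)
  if (sum(den_b) == 0) stop("denominator f4 is zero")
  jk <- block_jackknife(block_sums(num, st$blocks, nb), den_b, w)
  res <- fstat_result("f4_ratio", pops, jk, ncol(P))
  den_jk <- block_jackknife(den_b, w, w)
  den_z <- if (den_jk$se > 0) den_jk$estimate / den_jk$se else NA_real_
  res$unreliable <- is.na(den_z) || abs(den_z) < 2
  res
}
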