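# Independent reference implementations used as oracles. These deliberately
# use brute force (exhaustive enumeration, naive per-site loops) and share no
# code with the package internals.

# Li-Stephens posteriors by exhaustive enumeration over donor paths and
# per-interval recombination indicators.
oracle_paint <- function(y, D, gpos, rho, theta, total_cM) {
  K <- nrow(D); S <- length(y)
  em <- matrix(theta, K, S)
  em[D == matrix(y, K, S, byrow = TRUE)] <- 1 - theta
  r <- 1 - exp(-rho * diff(gpos))
  paths <- as.matrix(expand.grid(rep(list(1:K), S)))
  flags <- if (S > 1) as.matrix(expand.grid(rep(list(0:1), S - 1))) else
    matrix(0, 1, 0)
  post <- matrix(0, K, S); chunks <- rep(0, K); tot <- 0
  for (pi in seq_len(nrow(paths))) for (fi in seq_len(nrow(flags))) {
    pa <- paths[pi, ]; fl <- flags[fi, ]
    pr <- 1 / K * em[pa[1], 1]
    ok <- TRUE
    if (S > 1) for (s in 2:S) {
      if (fl[s - 1] == 1) pr <- pr * r[s - 1] / K
      else {
        if (pa[s] != pa[s - 1]) { ok <- FALSE; break }
        pr <- pr * (1 - r[s - 1])
      }
      pr <- pr * em[pa[s], s]
    }
    if (!ok) next
    tot <- tot + pr
    for (s in 1:S) post[pa[s], s] <- post[pa[s], s] + pr
    chunks[pa[1]] <- chunks[pa[1]] + pr
    if (S > 1) for (s in 2:S) if (fl[s - 1] == 1 && pa[s] != pa[s - 1])
      chunks[pa[s]] <- chunks[pa[s]] + pr
  }
  post <- post / tot
  mids <- c(0, (gpos[-1] + gpos[-S]) / 2, total_cM)
  list(lengths = as.numeric(post %*% diff(mids)),
       chunks = chunks / tot, loglik = log(tot))
}

# naive per-site f/D statistics on a populations x sites frequency matrix
oracle_d <- function(P) {
  num <- den <- 0
  for (s in seq_len(ncol(P))) {
    num <- num + (P[1, s] - P[2, s]) * (P[3, s] - P[4, s])
    den <- den + (P[1, s] + P[2, s] - 2 * P[1, s] * P[2, s]) *
      (P[3, s] + P[4, s] - 2 * P[3, s] * P[4, s])
  }
  unname(num / den)
}
oracle_f4 <- function(P) {
  tot <- 0
  for (s in seq_len(ncol(P))) tot <- tot + (P[1, s] - P[2, s]) * (P[3, s] - P[4, s])
  unname(tot / ncol(P))
}
oracle_f3 <- function(P, nC = NULL) {
  tot <- 0
  for (s in seq_len(ncol(P))) {
    t <- (P[1, s] - P[2, s]) * (P[1, s] - P[3, s])
    if (!is.null(nC)) t <- t - P[1, s] * (1 - P[1, s]) / (nC[s] - 1)
    tot <- tot + t
  }
  unname(tot / ncol(P))
}

# EHH by enumerating every carrier pair
oracle_ehh <- function(haps, core, allele, target) {
  carriers <- which(haps[, core] == allele)
  if (length(carriers) < 2) return(NA_real_)
  rng <- min(core, target):max(core, target)
  pairs <- combn(carriers, 2)
  hom <- apply(pairs, 2, function(pr)
    all(haps[pr[1], rng] == haps[pr[2], rng]))
  mean(hom)
}

# frequency table straight from matrices, for toy fstat fixtures
toy_freqs <- function(P, n = NULL, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(ncol(P)) * 1e6
  sites <- data.frame(position_bp = positions,
                      genetic_pos_cM = positions / 1e6,
                      ref = "A", alt = "C",
                      mutation_class = "transversion",
                      stringsAsFactors = FALSE)
  if (is.null(n)) n <- matrix(100, nrow(P), ncol(P))
  palaeogen:::new_freq_table(P, n, rownames(P), sites)
}

# minimal hand-built haplotype panel for painting / EHH toys
toy_panel <- function(haps_by_pop, positions_bp = NULL, L_bp = NULL,
                      L_M = NULL, mutation_class = "transversion") {
  haps <- do.call(rbind, haps_by_pop)
  S <- ncol(haps)
  if (is.null(positions_bp)) positions_bp <- seq_len(S) * 1e6
  if (is.null(L_bp)) L_bp <- max(positions_bp) + 1e6
  if (is.null(L_M)) L_M <- L_bp / 1e8
  info <- do.call(rbind, lapply(names(haps_by_pop), function(pop) {
    n_hap <- nrow(haps_by_pop[[pop]])
    stopifnot(n_hap %% 2 == 0)
    ids <- sprintf("%s_%d", pop, seq_len(n_hap / 2))
    data.frame(hap_id = sprintf("%s_h%d", rep(ids, each = 2), 1:2),
               individual = rep(ids, each = 2), population = pop,
               stringsAsFactors = FALSE)
  }))
  rownames(haps) <- info$hap_id
  structure(list(
    sites = data.frame(position_bp = positions_bp,
                       genetic_pos_cM = positions_bp / L_bp * L_M * 100,
                       ref = "A", alt = "C",
                       mutation_class = mutation_class,
                       ancestral_freq = 0.5, stringsAsFactors = FALSE),
    haps = haps, hap_info = info, truth_tracts = list(),
    truth_sources = list(), chrom_length_bp = L_bp,
    chrom_length_morgans = L_M
  ), class = "haplotype_panel")
}
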