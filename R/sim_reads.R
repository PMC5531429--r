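#' Simulate low-coverage damaged reads over a haplotype panel
#'
#' Per individual-site, read depth is Poisson(`coverage_lambda`); each read
#' samples one of the two chromosomes uniformly. The observed allele equals
#' the true allele flipped with probability `seq_error_eps`; additionally,
#' at transition sites whose true base on the read is the
#' deamination-susceptible allele (the C of a C/T pair or the G of a G/A
#' pair), the observed allele is set to the product allele with probability
#' `deamination_delta * 2^(-d / d_half)`, where `d` is the read's distance
#' from its 5' end, drawn uniformly on `{0, ..., read_length - 1}`. This is
#' the site-level signature of post-mortem cytosine deamination.
#'
#' @param panel a `haplotype_panel`.
#' @param individuals individuals to sequence (default: all in the panel).
#' @param config a [sim_config()] supplying `coverage_lambda`,
#'   `seq_error_eps`, `deamination_delta`, `d_half`, `read_length`, `seed`.
#' @param seed optional override of the read-stage child seed.
#' @return a `site_pileup`: a data frame of read records with columns
#'   `individual_idx`, `individual`, `site`, `true_chromosome`,
#'   `true_allele`, `observed_allele`, `dist_5prime`, `damage_flag`, plus
#'   `sites`/`individuals` attributes.
#' @export
simulate_reads <- function(panel, individuals = NULL, config,
                           seed = child_seed(config$seed, "reads")) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(config, "sim_config"))
  info <- panel$hap_info
  if (is.null(individuals)) individuals <- unique(info$individual)
  S <- nrow(panel$sites)
  n_ind <- length(individuals)
  # deamination-susceptible allele per site: 0/1 dosage value or NA
  sus <- rep(NA_integer_, S)
  is_ts <- panel$sites$mutation_class == "transition"
  sus[is_ts & panel$sites$ref %in% c("C", "G")] <- 0L
  sus[is_ts & panel$sites$alt %in% c("C", "G")] <- 1L

  hap_rows <- t(vapply(individuals,
                       function(id) which(info$individual == id), integer(2)))
  withr::with_seed(as.integer(seed), {
    depth <- rpois(n_ind * S, config$coverage_lambda)
    n_reads <- sum(depth)
    ind_idx <- rep(rep(seq_len(n_ind), S), depth)
    site <- rep(rep(seq_len(S), each = n_ind), depth)
    chrom <- sample.int(2L, n_reads, replace = TRUE)
    hap_row <- hap_rows[cbind(ind_idx, chrom)]
    true_allele <- panel$haps[cbind(hap_row, site)]
    d <- sample.int(config$read_length, n_reads, replace = TRUE) - 1L
    obs <- true_allele
    err <- runif(n_reads) < config$seq_error_eps
    obs[err] <- 1L - obs[err]
    eligible <- !is.na(sus[site]) & true_allele == sus[site]
    deam <- eligible &
      runif(n_reads) < config$deamination_delta * 2^(-d / config$d_half)
    obs[deam] <- 1L - sus[site][deam]   # product allele of the pair
  })
  out <- data.frame(
    individual_idx = ind_idx,
    individual = individuals[ind_idx],
    site = site,
    true_chromosome = chrom,
    true_allele = true_allele,
    observed_allele = obs,
    dist_5prime = d,
    damage_flag = deam,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("site_pileup", "data.frame"),
            sites = panel$sites, individuals = individuals)
}

#' Per-MAF-bin, per-genotype-class accuracy schedule
#'
#' Describes the accuracy of an imputation run as a function of minor allele
#' frequency (bins of width `bin_width` covering `[0, 0.5]`) and of the true
#' genotype class, mirroring how imputation accuracy is evaluated (rarer
#' variants impute less accurately, heterozygotes differently from
#' homozygotes).
#'
#' @param hom_ref,het,hom_alt either scalars (constant accuracy) or numeric
#'   vectors with one value per bin, low-MAF bin first.
#' @param bin_width MAF bin width; default 0.005.
#' @return a data frame with columns `bin_lo`, `bin_hi`, `class`, `accuracy`.
#' @export
accuracy_schedule <- function(hom_ref = 0.99, het = 0.95, hom_alt = 0.99,
                              bin_width = 0.005) {
  lo <- seq(0, 0.5 - bin_width / 2, by = bin_width)
  hi <- pmin(lo + bin_width, 0.5)
  n <- length(lo)
  rec <- function(a, cls) {
    a <- rep_len(a, n)
    data.frame(bin_lo = lo, bin_hi = hi, class = cls, accuracy = a,
               stringsAsFactors = FALSE)
  }
  out <- rbind(rec(hom_ref, "hom_ref"), rec(het, "het"), rec(hom_alt, "hom_alt"))
  if (any(out$accuracy < 0 | out$accuracy > 1))
    stop("accuracies must lie in [0,1]")
  out
}

genotype_class <- function(g) c("hom_ref", "het", "hom_alt")[g + 1L]

# map each site MAF to its schedule bin index (upper edge inclusive at 0.5)
maf_bin_index <- function(maf, bin_lo, bin_hi) {
  idx <- findInterval(maf, c(bin_lo, max(bin_hi)), rightmost.closed = TRUE)
  idx[maf < min(bin_lo) | maf > max(bin_hi)] <- NA_integer_
  idx
}

#' Emulate imputed diploid calls with posterior probabilities
#'
#' Produces imputation-like output from truth genotypes without running an
#' imputation engine: each genotype is kept with the accuracy of its MAF bin
#' and genotype class, otherwise replaced by one of the other two genotypes
#' (the adjacent genotype twice as likely as the opposite homozygote). Each
#' emitted call receives a GP triplet with mass `u ~ Uniform(0.90, 1)` on
#' the call and the remainder split between the other two genotypes, so the
#' GP argmax always equals the emitted call.
#'
#' @param truth a diploid [genotype_matrix()] of true genotypes.
#' @param schedule an [accuracy_schedule()].
#' @param seed integer seed.
#' @param maf optional per-site MAF vector used to look up bins; default
#'   computed from `truth`.
#' @return a diploid [genotype_matrix()] with GP.
#' @export
emulate_imputed_calls <- function(truth, schedule, seed = 1L, maf = NULL) {
  stopifnot(inherits(truth, "genotype_matrix"), truth$ploidy == 2L)
  if (is.null(maf)) {
    p <- colMeans(truth$geno, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
  }
  classes <- sort(unique(schedule$class))
  stopifnot(setequal(classes, c("hom_ref", "het", "hom_alt")))
  sub <- schedule[schedule$class == "hom_ref", ]
  bin <- maf_bin_index(maf, sub$bin_lo, sub$bin_hi)
  if (any(is.na(bin) & !is.na(maf)))
    stop("accuracy schedule does not cover the MAF of every site")
  # accuracy lookup matrices: bin x class
  acc <- sapply(c("hom_ref", "het", "hom_alt"), function(cl) {
    s <- schedule[schedule$class == cl, ]
    s <- s[order(s$bin_lo), ]
    s$accuracy
  })

  n_ind <- nrow(truth$geno)
  S <- ncol(truth$geno)
  g <- truth$geno
  withr::with_seed(as.integer(seed), {
    a <- matrix(NA_real_, n_ind, S)
    ok <- !is.na(g)
    a[ok] <- acc[cbind(rep(bin, each = n_ind)[ok], g[ok] + 1L)]
    keep <- matrix(runif(n_ind * S), n_ind, S) < a
    flip <- ok & !keep
    out <- g
    if (any(flip)) {
      u <- runif(sum(flip))
      tg <- g[flip]
      # adjacent genotype twice as likely as the opposite homozygote
      repl <- integer(length(tg))
      repl[tg == 0L] <- ifelse(u[tg == 0L] < 2 / 3, 1L, 2L)
      repl[tg == 2L] <- ifelse(u[tg == 2L] < 2 / 3, 1L, 0L)
      repl[tg == 1L] <- ifelse(u[tg == 1L] < 0.5, 0L, 2L)
      out[flip] <- repl
    }
    gp <- array(NA_real_, c(n_ind, S, 3L))
    uu <- matrix(runif(n_ind * S, 0.90, 1.0), n_ind, S)
    tt <- matrix(runif(n_ind * S), n_ind, S)
    for (v in 0:2) {
      sel <- ok & out == v
      others <- setdiff(0:2, v)
      slice <- function(k) gp[, , k + 1L]
      g1 <- slice(v); g1[sel] <- uu[sel]; gp[, , v + 1L] <- g1
      g2 <- slice(others[1]); g2[sel] <- (1 - uu[sel]) * tt[sel]
      gp[, , others[1] + 1L] <- g2
      g3 <- slice(others[2]); g3[sel] <- (1 - uu[sel]) * (1 - tt[sel])
      gp[, , others[2] + 1L] <- g3
    }
  })
  genotype_matrix(out, ploidy = 2L, sites = truth$sites,
                  individuals = truth$individuals, gp = gp)
}
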