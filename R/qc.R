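#' Genetic sex from sex-chromosome read counts
#'
#' The Y-read fraction `Ry = nY / (nX + nY)` with a normal-approximation
#' binomial confidence interval. The sample is called XX when the CI upper
#' bound falls below `t_low` and XY when the lower bound exceeds `t_high`;
#' otherwise indeterminate. The default thresholds (0.016 / 0.075) follow
#' the shotgun sex-typing convention for alignments to the full genome.
#'
#' @param n_y_reads reads aligning to Y.
#' @param n_xy_reads total reads aligning to X or Y (must be > 0).
#' @param t_low,t_high calling thresholds.
#' @param conf confidence level of the interval.
#' @return list with `Ry`, `ci` (lower, upper), `sex_call`.
#' @export
sex_from_counts <- function(n_y_reads, n_xy_reads,
                            t_low = 0.016, t_high = 0.075, conf = 0.95) {
  if (n_xy_reads <= 0) stop("n_xy_reads must be > 0")
  ry <- n_y_reads / n_xy_reads
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(ry * (1 - ry) / n_xy_reads)
  ci <- c(max(0, ry - half), min(1, ry + half))
  call <- if (ci[2] < t_low) "XX" else if (ci[1] > t_high) "XY" else "indeterminate"
  list(Ry = ry, ci = ci, sex_call = call)
}

#' Mitochondrial contamination from haplogroup-defining mismatches
#'
#' Fraction of reads mismatching the consensus at haplogroup-defining
#' positions, with a binomial confidence interval.
#'
#' @param n_mismatch mismatching reads at defining sites.
#' @param n_total total reads at defining sites (> 0).
#' @param conf confidence level.
#' @return list with `rate` and `ci`.
#' @export
mt_contamination <- function(n_mismatch, n_total, conf = 0.95) {
  if (n_total <= 0) stop("n_total must be > 0")
  rate <- n_mismatch / n_total
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(rate * (1 - rate) / n_total)
  list(rate = rate, ci = c(max(0, rate - half), min(1, rate + half)))
}

#' X-chromosome contamination in males (moment estimator)
#'
#' In a male (haploid X), reads disagreeing with the consensus at
#' polymorphic sites arise from sequencing error plus contaminating
#' chromosomes carrying the alternative allele. With `r_snp` the
#' non-consensus read fraction at SNP sites, `r_adj` the mismatch fraction
#' at adjacent non-polymorphic sites (the error baseline) and `f_bar` the
#' mean frequency of the non-consensus allele in the contaminant source,
#' the excess-mismatch moment estimator is
#' `c = (r_snp - r_adj) / (f_bar - r_adj)`, clamped to `[0, 1]`.
#'
#' @param r_snp non-consensus read fraction at polymorphic X sites.
#' @param r_adj mismatch fraction at adjacent sites.
#' @param f_bar mean minor-allele frequency at the SNP sites.
#' @return list with `rate`, `clamped` flag and `defined` flag (`FALSE`
#'   when `f_bar <= r_adj`, where the estimator is undefined).
#' @export
x_contamination <- function(r_snp, r_adj, f_bar) {
  if (f_bar <= r_adj) {
    warning("f_bar <= r_adj: X contamination estimator undefined")
    return(list(rate = NA_real_, clamped = FALSE, defined = FALSE))
  }
  raw <- (r_snp - r_adj) / (f_bar - r_adj)
  clamped <- raw < 0 || raw > 1
  if (raw < 0) warning("negative raw estimate clamped to 0")
  list(rate = min(1, max(0, raw)), clamped = clamped, defined = TRUE)
}

#' Post-mortem deamination profile
#'
#' Computes the C-to-T (and complementary G-to-A) misincorporation rate as
#' a function of distance from the 5' read end, among reads at transition
#' sites whose template base is the deamination-susceptible allele, and
#' fits the decay model `rate(d) = eps + (1 - eps) * delta * 2^(-d/d_half)`
#' by weighted nonlinear least squares, reporting the terminal damage rate
#' `delta_hat` and half-distance `d_half_hat`.
#'
#' @param pileup a `site_pileup` from [simulate_reads()].
#' @param max_dist largest 5'-distance included in the fit.
#' @return list with `curve` (data frame `dist`, `n_eligible`, `rate`),
#'   `delta_hat`, `d_half_hat`, `eps_hat`.
#' @export
damage_profile <- function(pileup, max_dist = 25L) {
  stopifnot(inherits(pileup, "site_pileup"))
  sites <- attr(pileup, "sites")
  is_ts <- sites$mutation_class[pileup$site] == "transition"
  sus <- ifelse(sites$ref[pileup$site] %in% c("C", "G"), 0L, 1L)
  eligible <- is_ts & pileup$true_allele == sus
  el <- pileup[eligible & pileup$dist_5prime <= max_dist, ]
  if (!nrow(el)) stop("no eligible reads for damage profiling")
  flip <- el$observed_allele != el$true_allele
  curve <- aggregate(cbind(n_eligible = rep(1L, nrow(el)),
                           n_flipped = as.integer(flip)),
                     by = list(dist = el$dist_5prime), FUN = sum)
  curve$rate <- curve$n_flipped / curve$n_eligible

  # for fixed d_half the model is linear in (eps, (1-eps)*delta):
  # rate = a + b * 2^(-d/d_half); profile d_half on a grid, weighted LS
  best <- NULL
  for (dh in seq(0.25, 15, by = 0.05)) {
    wbasis <- 2^(-curve$dist / dh)
    fit <- lm(rate ~ wbasis, data = curve, weights = curve$n_eligible)
    rss <- sum(curve$n_eligible * residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, dh = dh, a = unname(coef(fit)[1]),
                   b = unname(coef(fit)[2]))
  }
  eps_hat <- min(max(best$a, 0), 0.1)
  delta_hat <- min(max(best$b / (1 - eps_hat), 0), 0.5)
  d_half_hat <- if (delta_hat > 0) best$dh else NA_real_
  list(curve = curve, delta_hat = delta_hat, d_half_hat = d_half_hat,
       eps_hat = eps_hat)
}

#' Simulate sex-chromosome read counts
#'
#' Emulates shotgun read counts over X and Y target sites for simulated XX
#' and XY individuals: per-copy coverage `lambda / 2`, so females accrue
#' X reads at rate `lambda * n_x_sites` and males at half that plus Y reads
#' at `lambda / 2 * n_y_sites`; a small mismapping rate sends spurious Y
#' reads to females.
#'
#' @param sex `"XX"` or `"XY"`.
#' @param lambda mean autosomal coverage.
#' @param n_x_sites,n_y_sites numbers of alignable X and Y sites; the
#'   defaults give males an expected Ry around 0.13.
#' @param mismap_rate fraction of Y-site coverage observed in females.
#' @param seed integer seed.
#' @return list with `n_y`, `n_xy`.
#' @export
simulate_sex_counts <- function(sex = c("XX", "XY"), lambda,
                                n_x_sites = 40000L, n_y_sites = 6000L,
                                mismap_rate = 0.05, seed = 1L) {
  sex <- match.arg(sex)
  withr::with_seed(as.integer(seed), {
    if (sex == "XY") {
      nx <- rpois(1L, lambda / 2 * n_x_sites)
      ny <- rpois(1L, lambda / 2 * n_y_sites)
    } else {
      nx <- rpois(1L, lambda * n_x_sites)
      ny <- rpois(1L, mismap_rate * lambda * n_y_sites)
    }
  })
  list(n_y = ny, n_xy = nx + ny)
}
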