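#' Imputation accuracy stratified by MAF bin and genotype class
#'
#' Concordance of a call set against truth genotypes, stratified by the true
#' genotype class (homozygous reference, heterozygous, homozygous alternate)
#' and by minor-allele-frequency bin (default width 0.005). Missing calls
#' are excluded from both numerator and denominator and reported separately
#' as missingness.
#'
#' @param truth,calls aligned [genotype_matrix()] objects (same individuals
#'   and sites).
#' @param maf per-site MAF used for binning; default computed from `truth`
#'   (an external reference panel's frequencies may be supplied instead).
#' @param bin_width MAF bin width.
#' @return list with `table` (data frame: `bin_lo`, `bin_hi`, `class`,
#'   `n_compared`, `n_concordant`, `accuracy`), `missingness` (fraction of
#'   truth-called genotypes missing in `calls`) and `overall` accuracy.
#' @export
imputation_accuracy <- function(truth, calls, maf = NULL, bin_width = 0.005) {
  stopifnot(inherits(truth, "genotype_matrix"), inherits(calls, "genotype_matrix"))
  if (!identical(dim(truth$geno), dim(calls$geno)))
    stop("truth and calls matrices must be aligned")
  if (is.null(maf)) {
    p <- colMeans(truth$geno, na.rm = TRUE) / truth$ploidy
    maf <- pmin(p, 1 - p)
  }
  lo <- seq(0, 0.5 - bin_width / 2, by = bin_width)
  hi <- pmin(lo + bin_width, 0.5)
  bin <- maf_bin_index(maf, lo, hi)

  n_ind <- nrow(truth$geno)
  tg <- truth$geno
  cg <- calls$geno
  have_truth <- !is.na(tg)
  both <- have_truth & !is.na(cg)
  missingness <- if (any(have_truth)) 1 - sum(both) / sum(have_truth) else NA_real_

  cls <- matrix(NA_integer_, n_ind, ncol(tg))
  cls[have_truth] <- tg[have_truth] + 1L   # 1=hom_ref 2=het 3=hom_alt
  binm <- matrix(rep(bin, each = n_ind), n_ind)
  idx <- both & !is.na(binm)
  key_bin <- binm[idx]
  key_cls <- cls[idx]
  conc <- (tg == cg)[idx]

  grid <- expand.grid(bin = seq_along(lo), cls = 1:3)
  tab_n <- tapply(rep(1L, length(conc)), list(factor(key_bin, seq_along(lo)),
                                              factor(key_cls, 1:3)), sum)
  tab_c <- tapply(as.integer(conc), list(factor(key_bin, seq_along(lo)),
                                         factor(key_cls, 1:3)), sum)
  tab_n[is.na(tab_n)] <- 0L
  tab_c[is.na(tab_c)] <- 0L
  table <- data.frame(
    bin_lo = lo[grid$bin], bin_hi = hi[grid$bin],
    class = c("hom_ref", "het", "hom_alt")[grid$cls],
    n_compared = as.vector(tab_n), n_concordant = as.vector(tab_c)
  )
  table$accuracy <- ifelse(table$n_compared > 0,
                           table$n_concordant / table$n_compared, NA_real_)
  list(table = table,
       missingness = missingness,
       overall = if (length(conc)) mean(conc) else NA_real_)
}

#' Reference-bias D-test for low-coverage call sets
#'
#' Tests whether a variant call set for one individual (pseudo-haploid or
#' imputed calls) is drawn towards reference-panel populations relative to
#' that individual's high-quality calls. For each panel population R (other
#' than the outgroup) it computes `D(outgroup, R; truth_calls,
#' variant_calls)`, treating the two call sets of the one individual as two
#' single-sample "populations". A call set biased towards R produces a
#' positive Z score.
#'
#' @param calls_variant,calls_truth two [genotype_matrix()] objects for the
#'   same single individual on the same sites.
#' @param panel_freqs an `allele_freq_table` of reference populations
#'   (at least two, including `outgroup`).
#' @param outgroup name of the outgroup population in `panel_freqs`.
#' @param blocks a [make_blocks()] specification for the jackknife.
#' @return data frame with one row per tested population: `population`,
#'   `D`, `se`, `Z`, `n_sites`, `n_blocks`.
#' @export
reference_bias_dtest <- function(calls_variant, calls_truth, panel_freqs,
                                 outgroup, blocks = NULL) {
  stopifnot(length(calls_variant$individuals) == 1L,
            length(calls_truth$individuals) == 1L,
            length(panel_freqs$populations) >= 2L,
            outgroup %in% panel_freqs$populations)
  ft <- allele_frequencies(calls_truth,
                           setNames("sample_truth", calls_truth$individuals))
  fv <- allele_frequencies(calls_variant,
                           setNames("sample_variant", calls_variant$individuals))
  freqs <- bind_frequencies(panel_freqs, ft, fv)
  if (is.null(blocks)) blocks <- make_blocks(freqs$sites)
  tested <- setdiff(panel_freqs$populations, outgroup)
  res <- lapply(tested, function(R) {
    d <- d_stat(freqs, c(outgroup, R, "sample_truth", "sample_variant"), blocks)
    data.frame(population = R, D = d$estimate, se = d$se, Z = d$Z,
               n_sites = d$n_sites_used, n_blocks = d$n_blocks)
  })
  do.call(rbind, res)
}
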