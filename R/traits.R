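#' Convert a case-control odds ratio to a per-allele effect size
#'
#' Liability-scale conversion `beta = ln(OR) / 1.81`. The alternative
#' reading `ln(OR / 1.81)` is available behind `interpretation =
#' "log_of_quotient"` but is not the convention of the cited scaling.
#'
#' @param odds_ratio positive odds ratio(s).
#' @param interpretation `"log_over_constant"` (default, `ln(OR)/1.81`) or
#'   `"log_of_quotient"` (`ln(OR/1.81)`).
#' @return numeric effect size(s).
#' @export
or_to_beta <- function(odds_ratio,
                       interpretation = c("log_over_constant",
                                          "log_of_quotient")) {
  interpretation <- match.arg(interpretation)
  if (any(odds_ratio <= 0)) stop("odds ratios must be > 0")
  if (interpretation == "log_over_constant") log(odds_ratio) / 1.81
  else log(odds_ratio / 1.81)
}

#' Polygenic score per individual
#'
#' Average per-allele effect: `score_i = sum_j beta_j * dosage_ij /
#' (ploidy * n_sites_used_i)`, the default of standard scoring tools
#' (`mode = "sum"` gives the plain weighted sum). Effect alleles are
#' aligned to the stored alt dosage: a SNP whose effect allele is the
#' reference contributes `beta * (ploidy - dosage)`. SNPs with association
#' p-value above `p_threshold` are excluded when a threshold is given.
#' Missing genotypes are skipped per individual (default) or mean-imputed
#' from the cohort allele frequency.
#'
#' @param gm a [genotype_matrix()].
#' @param effects effect panel data frame (`site`, `effect_allele`
#'   (`"ref"`/`"alt"`), `beta`, optional `p_value`).
#' @param p_threshold optional inclusion threshold on `p_value`.
#' @param missing_policy `"skip"` or `"mean_impute"`.
#' @param mode `"average"` (per-allele average, default) or `"sum"`.
#' @return list with `score`, `n_sites_used`, `n_missing` (named vectors
#'   per individual) and `n_panel_sites` (panel size after the p-filter).
#' @export
polygenic_score <- function(gm, effects, p_threshold = NULL,
                            missing_policy = c("skip", "mean_impute"),
                            mode = c("average", "sum")) {
  missing_policy <- match.arg(missing_policy)
  mode <- match.arg(mode)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(p_threshold)) {
    if (is.null(effects$p_value)) stop("p_threshold set but panel has no p_value")
    effects <- effects[effects$p_value <= p_threshold, , drop = FALSE]
  }
  if (!nrow(effects)) stop("no usable SNPs in effect panel")
  if (any(effects$site < 1 | effects$site > ncol(gm$geno)))
    stop("effect panel refers to sites outside the genotype matrix")
  G <- gm$geno[, effects$site, drop = FALSE]
  # align: effect allele "ref" means dosage of effect allele = ploidy - g
  is_ref <- effects$effect_allele == "ref"
  if (any(is_ref))
    G[, is_ref] <- gm$ploidy - G[, is_ref, drop = FALSE]
  miss <- is.na(G)
  if (missing_policy == "mean_impute") {
    mean_dosage <- colMeans(G, na.rm = TRUE)
    for (j in which(colSums(miss) > 0)) G[miss[, j], j] <- mean_dosage[j]
    used <- matrix(TRUE, nrow(G), ncol(G))
  } else {
    G[miss] <- 0
    used <- !miss
  }
  raw <- as.numeric(G %*% effects$beta)
  n_used <- rowSums(used)
  if (any(n_used == 0)) stop("individuals with zero usable SNPs")
  score <- if (mode == "average") raw / (gm$ploidy * n_used) else raw
  names(score) <- gm$individuals
  list(score = score,
       n_sites_used = setNames(n_used, gm$individuals),
       n_missing = setNames(rowSums(miss), gm$individuals),
       n_panel_sites = nrow(effects))
}

#' Centre scores at the dataset mean
#'
#' @param score numeric vector of scores.
#' @return the centred vector (sums to zero).
#' @export
center_scores <- function(score) score - mean(score)

#' Permutation test of a group difference in mean score
#'
#' Two-sided label-permutation test of the difference in group means (with
#' add-one correction), plus a Mann-Whitney test reported alongside for
#' robustness.
#'
#' @param score named numeric vector of scores.
#' @param group_a,group_b character vectors of individual ids.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `mean_difference` (A minus B), `p_permutation`,
#'   `p_mann_whitney`.
#' @export
group_score_test <- function(score, group_a, group_b,
                             n_perm = 10000L, seed = 1L) {
  xa <- score[group_a]; xb <- score[group_b]
  if (any(is.na(xa)) || any(is.na(xb))) stop("missing individuals in score")
  obs <- mean(xa) - mean(xb)
  pool <- c(xa, xb)
  na <- length(xa)
  withr::with_seed(as.integer(seed), {
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pool), na)
      mean(pool[idx]) - mean(pool[-idx])
    })
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  wt <- suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))
  list(mean_difference = obs, p_permutation = p_perm,
       p_mann_whitney = wt$p.value)
}

#' Regression of population mean score on ancestry proportion
#'
#' Ordinary least squares of per-population mean polygenic score on an
#' ancestry proportion (e.g. an F4-ratio estimate per population), with the
#' Pearson correlation and its t-test p-value.
#'
#' @param mean_score numeric vector of population mean scores.
#' @param ancestry numeric vector of ancestry proportions (same order).
#' @return list with `slope`, `intercept`, `r`, `p_value`; `slope` is `NA`
#'   with a warning when ancestry is constant.
#' @export
ancestry_score_regression <- function(mean_score, ancestry) {
  stopifnot(length(mean_score) == length(ancestry))
  if (length(unique(ancestry)) < 2) {
    warning("ancestry proportions are constant; slope undefined")
    return(list(slope = NA_real_, intercept = mean(mean_score),
                r = NA_real_, p_value = NA_real_))
  }
  fit <- lm(mean_score ~ ancestry)
  ct <- cor.test(mean_score, ancestry)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p_value = ct$p.value)
}
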