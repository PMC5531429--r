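#' Simulate a polygenic trait with known per-allele effects
#'
#' Samples `n_causal` causal sites without replacement and draws per-allele
#' effects `beta ~ Normal(0, h2 / n_causal)` (so the summed genetic variance
#' tracks the heritability proxy `h2`). The true genetic value of each
#' individual is the sum of `beta * dosage` over causal sites. Causal SNPs
#' are assigned p-value 1e-8; `n_null` additional SNPs receive near-zero
#' effects and `p ~ Uniform(0.1, 1)`, so p-value thresholding can be
#' exercised. Odds ratios are back-filled as `exp(1.81 * beta)` (the inverse
#' of the liability-scale conversion used for case-control panels).
#'
#' @param panel a `haplotype_panel`.
#' @param n_causal,heritability,n_null trait architecture (see
#'   [sim_config()]).
#' @param seed integer seed.
#' @return list with `effects` (an effect panel: data frame with `site`,
#'   `effect_allele`, `beta`, `odds_ratio`, `p_value`) and `true_value`
#'   (named vector of true genetic values per individual).
#' @export
simulate_trait <- function(panel, n_causal = 100L, heritability = 0.5,
                           n_null = 100L, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  S <- nrow(panel$sites)
  if (n_causal > S) stop("n_causal must not exceed the number of sites")
  gm <- panel_genotypes(panel)
  withr::with_seed(as.integer(seed), {
    causal <- sort(sample.int(S, n_causal))
    beta <- if (n_causal > 0)
      rnorm(n_causal, 0, sqrt(heritability / max(n_causal, 1L))) else numeric(0)
    pool <- setdiff(seq_len(S), causal)
    nulls <- sort(sample(pool, min(n_null, length(pool))))
    beta_null <- rnorm(length(nulls), 0, sqrt(heritability / max(n_causal, 1L)) / 100)
    p_null <- runif(length(nulls), 0.1, 1)
  })
  effects <- data.frame(
    site = c(causal, nulls),
    effect_allele = "alt",
    beta = c(beta, beta_null),
    odds_ratio = exp(1.81 * c(beta, beta_null)),
    p_value = c(rep(1e-8, n_causal), p_null),
    stringsAsFactors = FALSE
  )
  effects <- effects[order(effects$site), ]
  rownames(effects) <- NULL
  true_value <- if (n_causal > 0)
    as.numeric(gm$geno[, causal, drop = FALSE] %*% beta)
  else rep(0, length(gm$individuals))
  names(true_value) <- gm$individuals
  list(effects = effects, true_value = true_value)
}
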