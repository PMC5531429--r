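#' Configuration for a synthetic ancient-DNA cohort
#'
#' Bundles every parameter of the cohort generator: the site map, the
#' differentiated source populations, the admixture events that create
#' "ancient" individuals with known ancestry tracts, the low-coverage read
#' model (Poisson depth, sequencing error, post-mortem C-to-T deamination),
#' and the polygenic trait.
#'
#' Source populations are drawn under the Balding-Nichols model: each
#' population's allele frequency at a site is a Beta draw around the shared
#' ancestral frequency with drift parameter `F` (an FST-like quantity).
#' Haplotypes within a population are mosaics of a founder pool, which
#' creates the within-population haplotype sharing (LD) that chromosome
#' painting requires.
#'
#' @param n_sites number of biallelic sites on the chromosome.
#' @param chrom_length_bp physical chromosome length in base pairs.
#' @param chrom_length_morgans genetic map length in Morgans; the map is
#'   uniform (genetic position proportional to physical position).
#' @param sources data frame with columns `name`, `F` (drift parameter in
#'   (0,1)), `n_founders`, `n_samples`.
#' @param admixture_events data frame with columns `target_name`, `source_a`,
#'   `source_b`, `alpha` (proportion from `source_a`), `generations_g`
#'   (ancestry-switch intensity per Morgan), `n_samples`; may be `NULL`.
#'   Events are applied in order, so later events may target earlier
#'   admixed populations.
#' @param coverage_lambda mean reads per site per individual (Poisson).
#'   Default 1.15, the centre of the 0.05-2.95x range typical of shotgun
#'   ancient genomes.
#' @param deamination_delta probability that a terminal deamination-susceptible
#'   base (C of a C/T pair, G of a G/A pair) is read as the product allele;
#'   decays with distance from the 5' read end. Default 0.25.
#' @param seq_error_eps per-read allele flip probability. Default 0.001.
#' @param founder_switch_rate_per_morgan Poisson rate of founder switches
#'   along the genetic map when sampling haplotypes from the founder pool.
#' @param d_half half-distance (in bp from the 5' end) of the exponential
#'   deamination decay \eqn{w(d) = 2^{-d/d_{half}}}.
#' @param read_length read length used to draw the 5'-distance of each read.
#' @param trait_n_causal number of causal sites of the polygenic trait.
#' @param trait_heritability heritability proxy; per-site effect variance is
#'   `trait_heritability / trait_n_causal`.
#' @param trait_n_null number of non-causal SNPs given near-zero effects and
#'   non-significant p-values (for p-threshold filtering tests).
#' @param seed root seed; all stages derive child streams from it via
#'   [child_seed()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10000L,
                       chrom_length_bp = 1e8,
                       chrom_length_morgans = 1,
                       sources = data.frame(
                         name = c("PopA", "PopB"),
                         F = c(0.1, 0.1),
                         n_founders = c(20L, 20L),
                         n_samples = c(10L, 10L)
                       ),
                       admixture_events = NULL,
                       coverage_lambda = 1.15,
                       deamination_delta = 0.25,
                       seq_error_eps = 0.001,
                       founder_switch_rate_per_morgan = 30,
                       d_half = 2,
                       read_length = 60L,
                       trait_n_causal = min(100L, n_sites),
                       trait_heritability = 0.5,
                       trait_n_null = 100L,
                       seed = 1L) {
  stopifnot(is.data.frame(sources),
            all(c("name", "F", "n_founders", "n_samples") %in% names(sources)))
  fin1 <- function(x) is.numeric(x) && all(is.finite(x))
  if (!fin1(n_sites) || n_sites < 1) stop("n_sites must be a positive count")
  if (!fin1(chrom_length_bp) || chrom_length_bp <= 0)
    stop("chrom_length_bp must be positive")
  if (!fin1(chrom_length_morgans) || chrom_length_morgans <= 0)
    stop("chrom_length_morgans must be positive")
  if (!fin1(sources$F) || any(sources$F <= 0 | sources$F >= 1))
    stop("source F parameters must lie in (0,1)")
  if (any(duplicated(sources$name))) stop("source names must be unique")
  if (!fin1(coverage_lambda) || coverage_lambda <= 0)
    stop("coverage_lambda must be > 0")
  if (!fin1(deamination_delta) || deamination_delta < 0 || deamination_delta > 0.5)
    stop("deamination_delta must lie in [0, 0.5]")
  if (!fin1(seq_error_eps) || seq_error_eps < 0 || seq_error_eps > 0.1)
    stop("seq_error_eps must lie in [0, 0.1]")
  if (!fin1(founder_switch_rate_per_morgan) || founder_switch_rate_per_morgan <= 0)
    stop("founder_switch_rate_per_morgan must be > 0")
  if (trait_n_causal > n_sites) stop("trait_n_causal must not exceed n_sites")
  if (!is.null(admixture_events)) {
    stopifnot(is.data.frame(admixture_events),
              all(c("target_name", "source_a", "source_b", "alpha",
                    "generations_g", "n_samples") %in% names(admixture_events)))
    if (!fin1(admixture_events$alpha) ||
        any(admixture_events$alpha < 0 | admixture_events$alpha > 1))
      stop("admixture alpha must lie in [0,1]")
    if (any(duplicated(c(sources$name, admixture_events$target_name))))
      stop("population names must be unique across sources and admixture targets")
  }
  structure(list(
    n_sites = as.integer(n_sites),
    chrom_length_bp = chrom_length_bp,
    chrom_length_morgans = chrom_length_morgans,
    sources = sources,
    admixture_events = admixture_events,
    coverage_lambda = coverage_lambda,
    deamination_delta = deamination_delta,
    seq_error_eps = seq_error_eps,
    founder_switch_rate_per_morgan = founder_switch_rate_per_morgan,
    d_half = d_half,
    read_length = as.integer(read_length),
    trait_n_causal = as.integer(trait_n_causal),
    trait_heritability = trait_heritability,
    trait_n_null = as.integer(trait_n_null),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_sites, "sites,",
      nrow(x$sources), "source populations,",
      if (is.null(x$admixture_events)) 0 else nrow(x$admixture_events),
      "admixture events, seed", x$seed, "\n")
  invisible(x)
}
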