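---
title: "Models and methods behind palaeogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind palaeogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`palaeogen` implements the analysis chain used to study population
structure from low-coverage ancient genomes — genotype-representation
handling, authentication estimators, D/f-statistics, Li–Stephens
chromosome painting with donation-vector statistics, polygenic scores and
extended haplotype homozygosity — together with a synthetic-cohort
generator that reproduces the statistical structure such data have, so
every stage can be validated against known truth. This vignette explains
each model, its assumptions, and the design decisions taken where a
choice was genuinely open.

## The synthetic-cohort generator

**Sources.** Each site draws an ancestral frequency
$p \sim \mathrm{Uniform}(0.05, 0.95)$; population $k$ draws
$q_k \sim \mathrm{Beta}\!\left(p\frac{1-F_k}{F_k},
(1-p)\frac{1-F_k}{F_k}\right)$ — the Balding–Nichols model, in which
$F_k$ plays the role of an FST-like drift parameter. Haplotypes are not
drawn iid: a pool of `n_founders` founder haplotypes is drawn Bernoulli
per site, and each sampled haplotype is a mosaic of founders with switch
points falling as a Poisson process (default 30 per Morgan) along a
uniform genetic map. The founder mosaic is a deliberate substitute for a
full coalescent: it produces the within-population haplotype sharing and
LD that painting requires at a fraction of the cost, with the trade-off
that its site-frequency spectrum and LD decay are stylized rather than
coalescent-exact. Under this model the expected Hudson FST between two
samples of two $F = 0.1$ populations is 0.145 (computed by an independent
Monte-Carlo oracle of the site marginal; the extra founder-pool
covariance makes this differ from the infinite-pool value), and the
generator is tested against that value.

**Admixture.** An admixed haplotype follows a two-state Markov ancestry
process along the map: switch points Poisson with intensity $g$ per
Morgan (an admixture-age proxy), new state drawn from the stationary
distribution $(\alpha, 1-\alpha)$. Within a segment, alleles are copied
contiguously from one uniformly chosen haplotype of that segment's source
population. Truth tracts (0-based half-open bp intervals) and per-site
source labels are both recorded and must agree exactly — a bookkeeping
invariant under test. Events apply in order, so an admixed population can
itself be a source (the Bronze-Age analogue admixes Steppe into the
Neolithic analogue).

**Reads.** Depth per individual-site is Poisson(`coverage_lambda`,
default 1.15, the centre of the 0.05–2.95x coverage range typical of
shotgun ancient genomes). Each read picks a chromosome uniformly,
flips its allele with probability `seq_error_eps` (default 0.001), and —
at transition sites whose template base is the deamination-susceptible
allele (C of C/T, G of G/A) — is additionally converted to the product
allele with probability $\delta\, 2^{-d/d_{1/2}}$, where $d$ is the
read's 5' distance (uniform over the 60 bp read) and $d_{1/2} = 2$ bp.
The default terminal rate $\delta = 0.25$ is in the range routinely seen
in genuinely ancient, uracil-containing libraries. Damage is modelled at
the site level on read records, not on full read sequences; that is
sufficient for pseudo-haploid calling and damage profiling, the two
consumers.

**Imputed-like calls.** Rather than embedding an imputation engine, the
generator emulates its output: each true genotype is retained with the
accuracy of its MAF bin (width 0.005) and genotype class, otherwise
replaced (adjacent genotype twice as likely as the opposite homozygote),
and receives a genotype-posterior triplet with mass
$u \sim \mathrm{Uniform}(0.90, 1)$ on the emitted call. Only the
*evaluation* of imputation is in scope; the error model gives it known
truth to recover.

**Chromosomes.** One chromosome (100 Mb, 1 Morgan, uniform map) is the
default; multi-chromosome cohorts are independent replicates with
per-chromosome child seeds (`simulate_chromosomes()`). Ratio statistics
with block-jackknife errors are noticeably better calibrated with several
independent chromosomes, which is why the F4-ratio validation uses
5 x 10k sites rather than one 50k-site chromosome.

**Reproducibility.** Every stochastic stage draws from a stream seeded by
`child_seed(root, key)` — a documented polynomial hash of a stage label
folded into the root seed — so stages are independently reproducible and
rerunning one never perturbs another.

## Genotype representations and filters

Dosages are always counted on the alternate allele; haploid
(pseudo-haploid) matrices may contain only 0/1. The filter cascade is
applied in a fixed order: per-genotype posterior masking
(`max(GP) < gp_min` masks the call, not the site), transversions-only,
completeness, then MAF computed on the retained calls. The conventional
ancient-DNA settings are `gp_min = 0.99` and `maf_min = 0.05`. Masking
per genotype before the completeness filter reflects how such pipelines
are normally chained; an alternative per-site reading exists but is not
implemented. "Removing potential deamination calls" is operationalized
as the transversions-only filter, the standard hedge against post-mortem
damage.

Allele frequencies are complete-case per population per site: haploid
calls contribute one allele, diploid two, and no frequency is imputed
where a population has no data.

## Authentication estimators

* **Sex**: $R_y = n_Y / (n_X + n_Y)$ with a normal-approximation binomial
  CI; XX when the CI upper bound is below 0.016, XY when the lower bound
  exceeds 0.075. The thresholds follow the shotgun sex-typing convention
  and are exposed as arguments. The simulator behind the validation gives
  males an expected $R_y \approx 0.13$ by using a 40k/6k X/Y alignable
  site ratio, with a 5% Y mismapping rate for females.
* **mtDNA contamination**: mismatch fraction at haplogroup-defining
  positions with a binomial CI.
* **X contamination** (males): the closed-form moment estimator
  $c = (r_{snp} - r_{adj}) / (\bar f - r_{adj})$, clamped to [0, 1] —
  a simplification sharing the inputs of the likelihood methods
  (non-consensus fractions at SNP and adjacent sites, mean contaminant
  allele frequency) without their iterative machinery; undefined and
  flagged when $\bar f \le r_{adj}$.
* **Damage profile**: the C-to-T rate by 5' distance among eligible
  reads. For a fixed half-distance the decay model
  $r(d) = \varepsilon + (1-\varepsilon)\,\delta\, 2^{-d/d_{1/2}}$ is
  linear in $(\varepsilon, (1-\varepsilon)\delta)$, so the fit profiles
  $d_{1/2}$ over a grid (0.25–15 bp, step 0.05) with weighted linear
  least squares inside — deterministic and free of the convergence
  failures an unconstrained nonlinear optimizer shows on noisy short
  profiles. Recovery of $\delta$ to within 0.01 at 200k reads is under
  test.

## D- and f-statistics

With per-population frequencies $p_i$ per site,

$$D = \frac{\sum_s (p_1-p_2)(p_3-p_4)}
           {\sum_s (p_1+p_2-2p_1p_2)(p_3+p_4-2p_3p_4)}, \qquad
  f_4 = \mathrm{mean}_s\,(p_1-p_2)(p_3-p_4),$$

$$f_3(C;A,B) = \mathrm{mean}_s\,[(p_C-p_A)(p_C-p_B) - h_C], \quad
  h_C = \frac{p_C(1-p_C)}{n_C-1},$$

the $h_C$ correction on by default (skipped with a warning when
$n_C \le 1$; whether to apply it with pseudo-haploid outgroups is exposed
as the `correct_bias` flag). Sites missing a frequency in any argument
population are skipped per statistic (complete-case per test), and
transversions-only is the default mask in the scenario driver. **Sign
convention**, stated prominently because directionality is usually
reported verbally: $D > 0$ means excess sharing between P1–P3 and P2–P4.

Standard errors come from the weighted delete-one-block jackknife
(blocks of 5 Mb physical distance by default — no block size is canonical,
and results are insensitive to it at these scales — never spanning a
chromosome boundary), with weights proportional to per-block site counts;
it reduces exactly to the textbook unweighted formula for equal weights.
The F4-ratio $\alpha = f_4(O, A_1; X, O_2)/f_4(O, A_1; A_2, O_2)$
jackknifes the full ratio (both sums recomputed per left-out block) and is
flagged unreliable when the denominator's $|Z| < 2$. The two reference
samples $A_1, A_2$ must be held out of any simulated admixture copy pool;
otherwise their sampling noise covaries with the target and biases
$\alpha$ upward — the scenario driver holds two Steppe pairs out before
any admixture event for exactly this reason.

## Li–Stephens painting and donation statistics

The copying model is a hidden Markov chain over $K$ donor haplotypes:
across an interval of $g$ cM the chain keeps its donor with probability
$e^{-\rho g}$, otherwise switches to a uniform donor (self-return
included); emissions match the donor allele with probability $1-\theta$.
Scaled forward–backward recursions (numerically stable to at least
$K = 500$, 50k sites) yield per donor the expected copied map length
(posterior mass times the site's half-interval map weight, so lengths sum
to the total map length *exactly*) and the expected chunk count, counted
as posterior switch-in events *from a different donor* plus the first
site's donor posterior — a recombination landing back on the same donor
does not open an observable chunk. Posteriors are verified against
exhaustive enumeration over all donor paths and recombination indicator
sequences on small fixtures, to 1e-10.

Defaults when unset: $\rho = K/100$ per cM (one expected switch per cM
per 100 donors) and $\theta = 1/\sum_{k=1}^{K} 1/k$ (Watterson-style),
clamped to (0, 0.5); EM re-estimation of either is out of scope and both
are plain arguments. `paint_all()` excludes both haplotypes of the
recipient individual from its donor set, aggregates donor haplotypes to
donor individuals, and can paint on a thinned site grid (the scenario
paints every 10th site; the painting share of a 30%-admixed recipient is
recovered to within a percent of realized truth at that density).

Donation statistics operate on the coancestry matrix:

* `donation_differential()`: $d_r = c_{r,X} - c_{r,\mathrm{ref}}$ between
  two donor groups, on chunk counts by default (expected lengths are also
  emitted; the choice is a flag since either is defensible).
* `donation_contrast_test()`: two-sided Mann–Whitney U between recipient
  groups, exact by enumeration when $n_A + n_B \le 20$ without ties
  (completely separated 5+5 groups give $p = 2/252$), tie-corrected
  normal approximation otherwise.
* `tvd_donation()`: per-group per-target *median* donation, normalized to
  sum 1, then $\mathrm{TVD} = \frac12\sum_t |\bar p_{1,t} - \bar
  p_{2,t}|$. Normalization before differencing is a design choice (the
  natural reading of comparing donation profiles); the unnormalized
  per-target differences are returned alongside.
* `coancestry_pca()`: column-centred SVD with signs fixed by the
  largest-magnitude loading, hence fully deterministic.
* `greedy_cluster()`: a deterministic agglomerative stand-in for MCMC
  coancestry clustering — merge the pair whose pooled donation counts
  most increase the symmetric-Dirichlet multinomial marginal likelihood
  (concentration 1 by default), stop at no improvement, break ties on the
  smallest index pair. It recovers clean two-population structure exactly
  but is *not* a posterior sample: close or nested clusters may merge
  differently than an MCMC consensus would.

## Polygenic scores

Scores are average per-allele effects,
$\mathrm{score}_i = \sum_j \beta_j g_{ij} / (\mathrm{ploidy}\cdot
n_{\mathrm{used},i})$, matching the common scoring-tool default; a
sum mode is a flag. Effect alleles are aligned to the stored alt dosage
(`effect_allele = "ref"` contributes $\beta(\mathrm{ploidy}-g)$). Missing
genotypes are skipped per individual by default or mean-imputed from the
cohort frequency. Flipping a SNP's effect allele and negating $\beta$
shifts every *complete* individual's sum score by the same constant
$-\beta\cdot\mathrm{ploidy}$, so centred scores are invariant; with
missing data the average-mode denominator varies per individual and the
invariance holds only for individuals called at the flipped SNP — one
reason the pipeline centres scores (at the dataset mean) before any
comparison. Odds ratios convert by $\beta = \ln(\mathrm{OR})/1.81$, the
liability-scale convention; the alternative parse
$\ln(\mathrm{OR}/1.81)$ is available behind a flag but is not the
convention of the cited scaling. Group contrasts use a label-permutation
test of the mean difference (10,000 permutations, add-one correction)
with Mann–Whitney reported alongside, since no specific parametric test
is canonical for small unbalanced ancient groups.

## Extended haplotype homozygosity

$\mathrm{EHH}(x) = \sum_h \binom{n_h}{2} / \binom{n_c}{2}$ over the
identity partition of the $n_c$ core-allele carriers on the closed
interval between core and target — the probability that two randomly
chosen carrier chromosomes are identical over that stretch. No
carrier-frequency floor is applied (as with a keep-low-frequency scan);
fewer than two carriers is flagged undefined rather than zero. The decay
curve covers a 5 Mb physical window on both sides (genetic distance
optional in principle; physical is what the windowing uses), and is
non-increasing outward by construction since partitions only refine.
Identity uses allele values only: haplotype input is assumed phased and
complete (imputed), as in the pipelines this mirrors. Furcation trees
split carriers at successive sites; single-carrier nodes are pruned from
the rendered structure but retained in counts, which sum to $n_c$ at
every depth.

## The bundled transect scenario

`iberia_analog_config()` encodes the study conditions the tests and the
acceptance script run: five sources (Outgroup F = 0.2 n = 8, WHG 0.15/10,
CHG 0.15/8, Anatolian 0.1/12, Steppe 0.12/20; 20 founders each) on a
100 Mb / 1 Morgan chromosome with 40k sites; NeoAnalog = 0.75 Anatolian +
0.25 WHG (g = 40); BAAnalog = 0.15 Steppe + 0.85 NeoAnalog (g = 30);
CordedWareAnalog = 0.50 Steppe + 0.50 NeoAnalog (g = 30) as the
strong-turnover control. The mixture weights are scenario choices, not
estimates of any real population. `run_scenario()` simulates once, holds
two Steppe pairs out as F4-ratio references, then reports: the
D-statistic for Steppe flow into the BA analogue (expected significantly
positive), the F4-ratio $\hat\alpha$ against its 0.15 truth, the TVD of
BA-vs-Neo donation vectors against the Corded-Ware control (expected
ordering: modest < massive), painting shares, trait-score summaries, the
damage fit and the imputation-accuracy recovery. Painting runs on every
10th site; f-statistics on all transversions (~26.7k of 40k sites, since
a third of simulated allele pairs are transitions).

## Validation scale and limitations

The test suite sizes are package choices balancing statistical
resolution against desk-scale runs: oracle equivalences on 1k-site
fixtures; null D calibration over 100 ten-thousand-site quartets;
F4-ratio recovery over 20 replicates of 5 x 10k-site chromosomes with a
50-diploid admixed target (sized like the modern population panels the
estimator is applied to — with few target samples the comparison to the
nominal proportion is dominated by realized-ancestry variation rather
than estimator error); painting tract recovery over 20 seeds of 20k
sites; the full scenario at 40k sites.

What passing these tests does *not* show: the generator's haplotypes are
founder mosaics, not coalescent genealogies, so absolute values of
LD-sensitive quantities (chunk counts per cM, EHH decay rates) are
internally consistent rather than calibrated to real human data;
imputation is emulated by its error schedule, so nothing is learned about
any real imputation engine; and the moment-based X-contamination
estimator is a simplification of likelihood methods. The statistics
layer (D/f/F4-ratio, painting posteriors, EHH, scores) is exact or
oracle-checked and applies to real data read through the VCF, EIGENSTRAT
and IMPUTE2 interfaces unchanged.
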