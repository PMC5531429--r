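# palaeogen

Population-structure analysis of low-coverage ancient genomes, as a
tested, reusable R pipeline. It is aimed at population geneticists who
work with ancient-DNA cohorts — pseudo-haploid or imputed diploid calls
from shotgun data in the 0.05–3x coverage range — and want the standard
analysis chain with every stage validated against known truth:

* **Genotype handling** — pseudo-haploid calling from read pileups,
  imputed-call emulation with genotype posteriors, and the conventional
  filter cascade (per-call GP ≥ 0.99, transversions-only, completeness,
  MAF ≥ 0.05), plus an imputation-accuracy framework stratified by MAF
  bin and genotype class and a reference-bias D-test for call sets.
* **Authentication** — genetic sex from the Y-read fraction
  `Ry = nY/(nX+nY)` with CI-based calling, mismatch-based mtDNA and
  X-chromosome contamination estimators, and post-mortem deamination
  profiles with a fitted exponential decay.
* **Formal admixture tests** — D, f3, f4 and the F4-ratio admixture
  proportion, all with weighted block-jackknife standard errors:

  `D = Σ (p1−p2)(p3−p4) / Σ (p1+p2−2p1p2)(p3+p4−2p3p4)`,
  `α = f4(O, A1; X, Out2) / f4(O, A1; A2, Out2)`.

* **Chromosome painting** — a Li–Stephens copying HMM (forward–backward,
  verified against exhaustive path enumeration) producing coancestry
  matrices of expected chunk counts and copied lengths, with PCA, greedy
  marginal-likelihood clustering, donation-vector differentials,
  Mann–Whitney contrasts and total variation distance between group
  donation profiles.
* **Polygenic traits** — allele-aligned average-effect scores with
  p-value thresholds and missing-data policies, `β = ln(OR)/1.81`
  conversion, centring, permutation group tests and ancestry–score
  regression.
* **Selection scans** — extended haplotype homozygosity
  `EHH = Σ C(n_h,2) / C(n_c,2)` decay curves and haplotype furcation
  structure around candidate loci.

A synthetic-cohort generator (Balding–Nichols sources with founder-mosaic
haplotype sharing, Markov ancestry tracts with recorded truth, Poisson
reads with sequencing error and terminal C→T deamination, imputed-like
calls with known accuracy schedules, and a polygenic trait with known
effects) provides the ground truth every test recovers. Real data enter
through VCF (GT/GP), EIGENSTRAT and IMPUTE2 hap/sample readers.

## Worked example

The bundled scenario simulates an ancient-European-transect analogue:
five differentiated sources (outgroup, WHG, CHG, Anatolian and Steppe
analogues), a Neolithic analogue admixed from farmers and local
hunter-gatherers, a Bronze-Age analogue carrying a modest 15% Steppe
contribution, and a 50%-Steppe Corded-Ware analogue as the
strong-turnover control:

```r
library(palaeogen)
rep <- run_scenario(iberia_analog_config(seed = 1))

rep$fstats$d_steppe_into_ba
#> $D        0.03127
#> $se       0.00332
#> $Z        9.43
#> $n_sites  26655
rep$fstats$f4_ratio_ba
#> $alpha    0.1226
#> $se       0.0223
#> $truth    0.15
rep$painting[c("tvd_ba_vs_neo", "tvd_cw_vs_neo", "steppe_share_ba")]
#> $tvd_ba_vs_neo    0.0703
#> $tvd_cw_vs_neo    0.3471
#> $steppe_share_ba  0.1197
rep$qc$damage_delta_hat
#> [1] 0.2457
rep$imputation$het_accuracy
#> [1] 0.9506
```

Reading the output: the D-statistic `D(Outgroup, Steppe; Neo, BA)` is
significantly positive (Z = 9.4), detecting Steppe-analogue gene flow
into the Bronze-Age analogue; the F4-ratio estimates its admixture
proportion at 0.123 ± 0.022, covering the simulated truth of 0.15; the
donation-vector shift of the Bronze-Age group away from the Neolithic
profile (TVD 0.070) is far smaller than that of the 50%-Steppe control
(0.347) — the signature of a detectable but modest introgression rather
than a population turnover; the damage profiler recovers the simulated
25% terminal deamination; and the imputation harness recovers its
configured 95% heterozygote accuracy.

The `analysis/` directory holds numbered drivers
(`01_simulate_cohort.R` … `07_ehh_selection.R`) that run each layer of
this workflow on the same cohort and write tables under `results/`.

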