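#!/usr/bin/env Rscript
# Extended haplotype homozygosity around a constructed sweep locus: decay
# curves for the derived and ancestral core alleles in a 5 Mb window, and
# the furcation structure on both sides of the core.
# Writes results/ehh/.

library(palaeogen)

seed <- 1L
out <- "results/ehh"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_sites = 2000L, chrom_length_bp = 2e7, chrom_length_morgans = 0.2,
  sources = data.frame(name = "P", F = 0.1, n_founders = 20L,
                       n_samples = 40L),
  seed = seed)
panel <- simulate_sources(cfg)
H <- panel$haps
# core: the mid-chromosome site closest to 50% frequency, so both allele
# classes keep enough carriers
mid <- 500:1500
core <- mid[which.min(abs(colMeans(H[, mid]) - 0.5))]

# construct a partial sweep: one core-carrying haplotype copied onto 60%
# of chromosomes
withr::with_seed(child_seed(seed, "sweep"), {
  donor <- which(H[, core] == 1L)[1]
  if (is.na(donor)) { H[1, core] <- 1L; donor <- 1L }
  targets <- sample(setdiff(seq_len(nrow(H)), donor), round(0.6 * nrow(H)))
})
H[targets, ] <- matrix(H[donor, ], length(targets), ncol(H), byrow = TRUE)

dec <- ehh_decay(H, panel$sites, core, max_dist = 5e6)
for (allele in c("derived", "ancestral")) {
  write.table(dec[[allele]], file.path(out, paste0("ehh_", allele, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
at <- function(curve, d) curve$ehh[which.min(abs(abs(curve$distance_bp) - d))]
message(sprintf(
  "EHH at 1 Mb: derived %.3f vs ancestral %.3f (carriers %d / %d)",
  at(dec$derived, 1e6), at(dec$ancestral, 1e6),
  dec$n_carriers["derived"], dec$n_carriers["ancestral"]))

fu <- furcation(H, panel$sites, core, 1L, "right", max_steps = 12L)
write.table(fu$nodes, file.path(out, "furcation_right.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("furcation: %d rendered nodes (singletons pruned)",
                sum(fu$nodes$rendered)))
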