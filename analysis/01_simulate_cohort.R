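#!/usr/bin/env Rscript
# Build the synthetic west-Iberian-transect cohort that all downstream
# analyses consume: five differentiated sources (outgroup, WHG, CHG,
# Anatolian, Steppe analogues), a Neolithic analogue (Anatolian + WHG),
# a Bronze-Age analogue with 15% Steppe ancestry, and a Corded-Ware
# analogue with 50% Steppe ancestry as the strong-turnover control.
# Writes phased haplotypes (IMPUTE2 and VCF), truth tracts, labels and a
# trait effect panel under results/cohort/.

library(palaeogen)

seed <- 1L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- iberia_analog_config(seed = seed)
panel <- simulate_sources(cfg)
panel <- apply_admixture_events(panel, cfg)

message(sprintf("simulated %d sites x %d haplotypes (%d populations)",
                nrow(panel$sites), nrow(panel$haps),
                length(unique(panel$hap_info$population))))

write_impute2(panel, file.path(out, "cohort"))
gm <- panel_genotypes(panel)
write_vcf(gm, file.path(out, "cohort.vcf"), panel = panel)
write_truth_tracts(panel, file.path(out, "truth_tracts.tsv"))

labels <- unique(panel$hap_info[, c("individual", "population")])
write.table(labels, file.path(out, "labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tr <- simulate_trait(panel, cfg$trait_n_causal, cfg$trait_heritability,
                     cfg$trait_n_null, seed = child_seed(seed, "trait"))
write.table(tr$effects, file.path(out, "effect_panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(individual = names(tr$true_value),
                       true_value = tr$true_value),
            file.path(out, "true_genetic_values.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ba_frac <- mean(truth_ancestry_fraction(panel, "Steppe")[
  grep("^BAAnalog", names(panel$truth_tracts))])
message(sprintf("realized Steppe fraction in the BA analogue: %.3f", ba_frac))
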