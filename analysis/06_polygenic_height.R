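#!/usr/bin/env Rscript
# Polygenic-trait layer: scores from the simulated effect panel (with and
# without p-value filtering), centred per-population means across the
# temporal transect, the permutation contrast between groups, and the
# regression of population mean score on Steppe-analogue ancestry.
# Writes results/traits/.

library(palaeogen)

seed <- 1L
out <- "results/traits"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- iberia_analog_config(seed = seed)
panel <- apply_admixture_events(simulate_sources(cfg), cfg)
tr <- simulate_trait(panel, cfg$trait_n_causal, cfg$trait_heritability,
                     cfg$trait_n_null, seed = child_seed(seed, "trait"))
gm <- panel_genotypes(panel)
pops <- panel$hap_info$population[match(gm$individuals,
                                        panel$hap_info$individual)]

sc_all <- polygenic_score(gm, tr$effects)
sc_flt <- polygenic_score(gm, tr$effects, p_threshold = 0.001)
message(sprintf(
  "score-truth correlation: unfiltered %.3f, p<0.001 filter %.3f",
  cor(sc_all$score, tr$true_value), cor(sc_flt$score, tr$true_value)))

centred <- center_scores(sc_flt$score)
bypop <- data.frame(population = names(tapply(centred, pops, mean)),
                    mean_centred_score = as.numeric(tapply(centred, pops, mean)))
write.table(bypop, file.path(out, "scores_by_population.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(bypop, digits = 3)

neo <- gm$individuals[pops == "NeoAnalog"]
ba <- gm$individuals[pops == "BAAnalog"]
gt <- group_score_test(sc_flt$score, neo, ba,
                       seed = child_seed(seed, "perm"))
message(sprintf(
  "Neo vs BA analogue mean score difference %.4f: permutation p = %.3g, Mann-Whitney p = %.3g",
  gt$mean_difference, gt$p_permutation, gt$p_mann_whitney))

# mean score vs truth Steppe ancestry fraction across admixed populations
adm <- c("NeoAnalog", "BAAnalog", "CordedWareAnalog")
alpha <- vapply(adm, function(p) {
  haps <- panel$hap_info$hap_id[panel$hap_info$population == p]
  mean(truth_ancestry_fraction(panel, "Steppe")[haps])
}, numeric(1))
mean_sc <- vapply(adm, function(p) mean(sc_flt$score[pops == p]), numeric(1))
fit <- ancestry_score_regression(mean_sc, alpha)
message(sprintf(
  "score ~ Steppe ancestry: slope %.3f, r = %.3f, p = %.3g",
  fit$slope, fit$r, fit$p_value))
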