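#!/usr/bin/env Rscript
# Genotype-representation layer: pseudo-haploid calling from reads,
# imputed-like diploid calls with genotype posteriors, the standard
# GP >= 0.99 / complete / MAF >= 0.05 filter cascade, imputation accuracy
# by MAF bin and genotype class, and the reference-bias D-test comparing
# call sets of one individual against a reference panel.
# Writes results/calls/.

library(palaeogen)

seed <- 1L
out <- "results/calls"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- iberia_analog_config(seed = seed, n_sites = 20000L)
panel <- simulate_sources(cfg)
inds <- unique(panel$hap_info$individual)[1:10]
truth <- panel_genotypes(panel, inds)

# pseudo-haploid calls from low-coverage reads
pu <- simulate_reads(panel, inds, cfg)
ph <- pseudo_haploid_call(pu, seed = child_seed(seed, "ph"))
message(sprintf("pseudo-haploid missingness at %.2fx: %.3f",
                cfg$coverage_lambda, mean(is.na(ph$geno))))

# imputed-like calls, then the paper-style filter cascade
sched <- accuracy_schedule(
  hom_ref = seq(0.94, 0.999, length.out = 100),
  het = seq(0.88, 0.99, length.out = 100),
  hom_alt = seq(0.92, 0.998, length.out = 100))
calls <- emulate_imputed_calls(truth, sched,
                               seed = child_seed(seed, "imp"))
filtered <- apply_filters(calls, maf_min = 0.05, gp_min = 0.99,
                          require_complete = TRUE)
rep <- attr(filtered, "filter_report")
message(sprintf(
  "filters: %d sites in, %d GP-masked calls, %d dropped incomplete, %d dropped MAF, %d out",
  rep$sites_in, rep$genotypes_masked_gp, rep$sites_dropped_incomplete,
  rep$sites_dropped_maf, rep$sites_out))

acc <- imputation_accuracy(truth, calls)
write.table(acc$table[acc$table$n_compared > 0, ],
            file.path(out, "imputation_accuracy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("overall imputation accuracy: %.4f", acc$overall))

# reference-bias harness: biased vs unbiased corrupted call sets
cfgb <- sim_config(
  n_sites = 30000L,
  sources = data.frame(name = c("Out", "R1", "R2", "R3", "Subj"),
                       F = c(0.2, 0.1, 0.12, 0.15, 0.1),
                       n_founders = 20L, n_samples = c(8L, 8L, 8L, 8L, 2L)),
  seed = child_seed(seed, "bias"))
panelb <- simulate_sources(cfgb)
pfreqs <- panel_frequencies(panelb, c("Out", "R1", "R2", "R3"))
subj <- unique(panelb$hap_info$individual[
  panelb$hap_info$population == "Subj"])[1]
tg <- panel_genotypes(panelb, subj)
withr::with_seed(child_seed(seed, "corrupt"), {
  hit <- runif(ncol(tg$geno)) < 0.10
  g <- tg$geno
  g[1, hit] <- rbinom(sum(hit), 2, pfreqs$p["R2", hit])
})
biased <- genotype_matrix(g, 2L, tg$sites, subj)
res <- reference_bias_dtest(biased, tg, pfreqs, "Out")
write.table(res, file.path(out, "reference_bias.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("reference-bias Z by panel population:")
print(res[, c("population", "Z")])
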