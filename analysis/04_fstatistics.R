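#!/usr/bin/env Rscript
# Formal admixture tests on the transect cohort: D-statistics for
# Steppe-analogue introgression into the Bronze-Age analogue, outgroup f3
# shared-drift ranking, and the F4-ratio admixture proportion with held-out
# Steppe reference pairs. All tests run on transversions with 5 Mb
# block-jackknife standard errors. Writes results/fstats/.

library(palaeogen)

seed <- 1L
out <- "results/fstats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rep <- run_scenario(iberia_analog_config(seed = seed),
                    stages = list(fstats = TRUE))
d <- rep$fstats$d_steppe_into_ba
fr <- rep$fstats$f4_ratio_ba
message(sprintf("D(Outgroup, Steppe; Neo, BA) = %.4f  Z = %.2f  (%d sites)",
                d$D, d$Z, d$n_sites))
message(sprintf("F4-ratio alpha(BA) = %.3f +/- %.3f  (truth %.2f)",
                fr$alpha, fr$se, fr$truth))

# a small S5-Table-style panel of quartets
cfg <- iberia_analog_config(seed = seed)
panel <- apply_admixture_events(simulate_sources(cfg), cfg)
tv <- which(panel$sites$mutation_class == "transversion")
freqs <- panel_frequencies(panel)
freqs_tv <- palaeogen:::new_freq_table(
  freqs$p[, tv], freqs$n[, tv], freqs$populations, panel$sites[tv, ])
blocks <- make_blocks(panel$sites[tv, ])
quartets <- list(
  c("Outgroup", "Steppe", "NeoAnalog", "BAAnalog"),
  c("Outgroup", "Steppe", "NeoAnalog", "CordedWareAnalog"),
  c("Outgroup", "WHG", "Anatolian", "NeoAnalog"),
  c("Outgroup", "CHG", "NeoAnalog", "BAAnalog"))
tab <- do.call(rbind, lapply(quartets, function(q) {
  r <- d_stat(freqs_tv, q, blocks)
  data.frame(P1 = q[1], P2 = q[2], P3 = q[3], P4 = q[4],
             D = r$estimate, se = r$se, Z = r$Z, n_sites = r$n_sites_used)
}))
write.table(tab, file.path(out, "d_statistics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, digits = 3)

# outgroup f3 shared drift with the Neolithic analogue
f3tab <- do.call(rbind, lapply(
  c("WHG", "CHG", "Anatolian", "Steppe", "BAAnalog"), function(p) {
    r <- f3_outgroup(freqs_tv, c("Outgroup", "NeoAnalog", p), blocks)
    data.frame(partner = p, f3 = r$estimate, se = r$se, Z = r$Z)
  }))
write.table(f3tab, file.path(out, "outgroup_f3.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("outgroup f3 with NeoAnalog, by partner:")
print(f3tab, digits = 3)
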