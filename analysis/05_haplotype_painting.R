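#!/usr/bin/env Rscript
# Chromosome painting of the admixed cohorts against the source panels:
# coancestry matrix, PCA, greedy coancestry clustering, the differential
# hunter-gatherer donation contrast, and the TVD comparison of the
# Bronze-Age analogue against the Corded-Ware control.
# Writes results/painting/.

library(palaeogen)

seed <- 1L
out <- "results/painting"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- iberia_analog_config(seed = seed)
panel <- apply_admixture_events(simulate_sources(cfg), cfg)
info <- panel$hap_info
recip <- unique(info$individual[info$population %in%
                                  c("NeoAnalog", "BAAnalog",
                                    "CordedWareAnalog")])
donors <- unique(info$individual[info$population %in%
                                   c("WHG", "CHG", "Anatolian", "Steppe")])
sel <- seq(1, nrow(panel$sites), by = 10)   # paint on a thinned site grid
cm <- paint_all(panel, recipients = recip, donors = donors,
                site_subset = sel)
write_coancestry(cm, file.path(out, "coancestry_chunks.tsv"))
write_coancestry(cm, file.path(out, "coancestry_lengths.tsv"),
                 what = "lengths_cM")

pc <- coancestry_pca(cm)
write.table(data.frame(individual = rownames(pc$scores),
                       population = cm$recipient_info$population,
                       pc$scores),
            file.path(out, "pca.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PCA: leading component explains %.0f%% of variance",
                100 * pc$explained_variance[1] / pc$total_variance))

cl <- greedy_cluster(cm)
message(sprintf("greedy coancestry clustering: %d clusters over %d recipients",
                cl$n_clusters, length(cl$partition)))
write.table(data.frame(individual = names(cl$partition),
                       cluster = cl$partition),
            file.path(out, "clusters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

grp <- function(p) cm$recipient_info$individual[
  cm$recipient_info$population == p]
tvd_ba <- tvd_donation(cm, grp("BAAnalog"), grp("NeoAnalog"))
tvd_cw <- tvd_donation(cm, grp("CordedWareAnalog"), grp("NeoAnalog"))
message(sprintf(
  "TVD vs NeoAnalog: BA %.3f < CordedWare %.3f (modest vs massive turnover)",
  tvd_ba$tvd, tvd_cw$tvd))

d <- donation_differential(cm, "WHG", "CHG")
ct <- donation_contrast_test(d, grp("NeoAnalog"),
                             c(grp("BAAnalog"), grp("CordedWareAnalog")))
message(sprintf(
  "WHG-vs-CHG donation differential, Neo vs post-Neo: U = %.0f, p = %.3g",
  ct$U, ct$p_value))
write.table(data.frame(recipient = names(d), differential = d),
            file.path(out, "donation_differential.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
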