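#!/usr/bin/env Rscript
# Authentication layer on simulated low-coverage reads: genetic sex from
# Y-read fractions, mismatch-based contamination estimates, and the
# post-mortem deamination profile with its fitted decay parameters.
# Writes results/qc/.

library(palaeogen)

seed <- 1L
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- iberia_analog_config(seed = seed)
panel <- simulate_sources(cfg)

# damage profile from reads of eight individuals
pu <- simulate_reads(panel, unique(panel$hap_info$individual)[1:8], cfg)
dp <- damage_profile(pu)
write.table(dp$curve, file.path(out, "damage_curve.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "damage fit: delta = %.3f (simulated 0.25), half-distance = %.2f bp",
  dp$delta_hat, dp$d_half_hat))

# sex typing of a 10 XX + 10 XY panel at the cohort's coverage
sex_truth <- rep(c("XX", "XY"), each = 10)
sex_rows <- lapply(seq_along(sex_truth), function(i) {
  cnt <- simulate_sex_counts(sex_truth[i], lambda = cfg$coverage_lambda,
                             seed = child_seed(seed, paste0("sex:", i)))
  res <- sex_from_counts(cnt$n_y, cnt$n_xy)
  data.frame(individual = sprintf("ind%02d", i), truth = sex_truth[i],
             Ry = res$Ry, ci_lo = res$ci[1], ci_hi = res$ci[2],
             call = res$sex_call)
})
sex_tab <- do.call(rbind, sex_rows)
write.table(sex_tab, file.path(out, "sex_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("sex calls correct: %d / %d",
                sum(sex_tab$call == sex_tab$truth), nrow(sex_tab)))

# contamination summaries for a plausible ancient individual
mt <- mt_contamination(6, 550)
xc <- x_contamination(r_snp = 0.012, r_adj = 0.002, f_bar = 0.48)
write.table(data.frame(estimator = c("mtDNA", "X"),
                       rate = c(mt$rate, xc$rate)),
            file.path(out, "contamination.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("mt contamination %.4f, X contamination %.4f",
                mt$rate, xc$rate))
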