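#' Configuration of the bundled west-Iberian-transect analogue scenario
#'
#' A synthetic cohort whose structure mirrors the ancient-European setting
#' the pipeline is built for: five differentiated source populations
#' (analogues of western hunter-gatherers, Caucasus hunter-gatherers,
#' Anatolian farmers, Steppe pastoralists and an African outgroup), a
#' Neolithic analogue admixed from the farmer and local hunter-gatherer
#' sources, a Bronze-Age analogue carrying a modest 15% Steppe-related
#' contribution on the Neolithic background, and a Corded-Ware analogue
#' with a 50% Steppe contribution as the strong-turnover control.
#'
#' @param seed root seed.
#' @param n_sites number of sites (default 40000 on a 100 Mb / 1 Morgan
#'   chromosome).
#' @param steppe_alpha_ba Steppe proportion in the Bronze-Age analogue.
#' @param steppe_alpha_cw Steppe proportion in the Corded-Ware analogue.
#' @return a [sim_config()].
#' @export
iberia_analog_config <- function(seed = 1L, n_sites = 40000L,
                                 steppe_alpha_ba = 0.15,
                                 steppe_alpha_cw = 0.5) {
  sim_config(
    n_sites = n_sites,
    sources = data.frame(
      name = c("Outgroup", "WHG", "CHG", "Anatolian", "Steppe"),
      F = c(0.2, 0.15, 0.15, 0.1, 0.12),
      n_founders = 20L,
      n_samples = c(8L, 10L, 8L, 12L, 20L)
    ),
    admixture_events = data.frame(
      target_name = c("NeoAnalog", "BAAnalog", "CordedWareAnalog"),
      source_a = c("Anatolian", "Steppe", "Steppe"),
      source_b = c("WHG", "NeoAnalog", "NeoAnalog"),
      alpha = c(0.75, steppe_alpha_ba, steppe_alpha_cw),
      generations_g = c(40, 30, 30),
      n_samples = c(10L, 10L, 8L)
    ),
    seed = seed
  )
}

#' Run an end-to-end scenario
#'
#' Simulates the cohort of `config` and runs the enabled analysis stages:
#' formal admixture tests (D-statistic for Steppe-analogue introgression
#' into the Bronze-Age analogue and the F4-ratio admixture proportion),
#' haplotype painting with the donation-vector TVD contrast against the
#' strong-turnover control, polygenic-trait scoring, read-level QC and the
#' imputation-accuracy harness. Returns a machine-readable report;
#' rerunning with the same config reproduces it exactly.
#'
#' @param config a [sim_config()], e.g. [iberia_analog_config()].
#' @param stages named logical list enabling stages: `fstats`, `paint`,
#'   `traits`, `qc`, `impacc` (all on by default).
#' @param paint_thin paint on every `paint_thin`-th site (painting is run
#'   on a thinned site grid; the f-statistics use all transversions).
#' @param out_dir optional directory for stage outputs and `report.json`.
#' @return the report, a nested list of computed statistics.
#' @export
run_scenario <- function(config,
                         stages = list(fstats = TRUE, paint = TRUE,
                                       traits = TRUE, qc = TRUE,
                                       impacc = TRUE),
                         paint_thin = 10L,
                         out_dir = NULL) {
  defaults <- list(fstats = FALSE, paint = FALSE, traits = FALSE,
                   qc = FALSE, impacc = FALSE)
  stages <- utils::modifyList(defaults, stages)
  panel <- simulate_sources(config)
  # hold two pairs of Steppe individuals out as F4-ratio reference samples
  # before any admixture event, so the references are never in a copy pool
  if ("Steppe" %in% panel$hap_info$population) {
    steppe_ind <- unique(
      panel$hap_info$individual[panel$hap_info$population == "Steppe"])
    if (length(steppe_ind) >= 8) {
      panel$hap_info$population[
        panel$hap_info$individual %in% steppe_ind[1:2]] <- "SteppeRef1"
      panel$hap_info$population[
        panel$hap_info$individual %in% steppe_ind[3:4]] <- "SteppeRef2"
    }
  }
  panel <- apply_admixture_events(panel, config)
  info <- panel$hap_info
  report <- list(
    seed = config$seed,
    n_sites = config$n_sites,
    populations = as.list(table(unique(
      data.frame(info$individual, info$population))[, 2]))
  )

  has_pop <- function(p) p %in% info$population
  ba_truth <- if (has_pop("BAAnalog"))
    config$admixture_events$alpha[config$admixture_events$target_name ==
                                    "BAAnalog"] else NA

  if (isTRUE(stages$fstats) && has_pop("BAAnalog")) {
    # transversions only, the default site mask for formal admixture tests
    tv <- which(panel$sites$mutation_class == "transversion")
    sub_sites <- panel$sites[tv, , drop = FALSE]
    freqs <- panel_frequencies(panel)
    freqs_tv <- new_freq_table(freqs$p[, tv, drop = FALSE],
                               freqs$n[, tv, drop = FALSE],
                               freqs$populations, sub_sites)
    blocks <- make_blocks(sub_sites)
    d <- d_stat(freqs_tv, c("Outgroup", "Steppe", "NeoAnalog", "BAAnalog"),
                blocks)
    fr <- f4_ratio(freqs_tv, c("Outgroup", "SteppeRef1", "SteppeRef2",
                               "BAAnalog", "CHG"), blocks)
    report$fstats <- list(
      d_steppe_into_ba = list(D = d$estimate, se = d$se, Z = d$Z,
                              n_sites = d$n_sites_used),
      f4_ratio_ba = list(alpha = fr$estimate, se = fr$se,
                         truth = ba_truth, unreliable = fr$unreliable),
      d_significant = abs(d$Z) > 3,
      alpha_within_2se = abs(fr$estimate - ba_truth) <= 2 * fr$se
    )
  }

  if (isTRUE(stages$paint) && has_pop("BAAnalog")) {
    recip <- unique(info$individual[info$population %in%
                                      c("NeoAnalog", "BAAnalog",
                                        "CordedWareAnalog")])
    donors <- unique(info$individual[info$population %in%
                                       c("WHG", "CHG", "Anatolian", "Steppe")])
    sel <- seq(1, nrow(panel$sites), by = paint_thin)
    cm <- paint_all(panel, recipients = recip, donors = donors,
                    site_subset = sel)
    grp <- function(p) cm$recipient_info$individual[
      cm$recipient_info$population == p]
    tvd_ba <- tvd_donation(cm, grp("BAAnalog"), grp("NeoAnalog"))
    tvd_cw <- tvd_donation(cm, grp("CordedWareAnalog"), grp("NeoAnalog"))
    report$painting <- list(
      n_painted_sites = length(sel),
      tvd_ba_vs_neo = tvd_ba$tvd,
      tvd_cw_vs_neo = tvd_cw$tvd,
      modest_vs_massive_ordering = tvd_ba$tvd < tvd_cw$tvd,
      steppe_share_ba = mean(donation_by_population(cm, "lengths_cM")[
        grp("BAAnalog"), "Steppe"]) / (2 * cm$total_cM),
      steppe_share_cw = mean(donation_by_population(cm, "lengths_cM")[
        grp("CordedWareAnalog"), "Steppe"]) / (2 * cm$total_cM)
    )
    if (!is.null(out_dir)) write_coancestry(cm, file.path(out_dir,
                                                          "coancestry.tsv"))
  }

  if (isTRUE(stages$traits)) {
    tr <- simulate_trait(panel, config$trait_n_causal,
                         config$trait_heritability, config$trait_n_null,
                         seed = child_seed(config$seed, "trait"))
    gm <- panel_genotypes(panel)
    sc <- polygenic_score(gm, tr$effects, p_threshold = 0.001)
    pops <- info$population[match(gm$individuals, info$individual)]
    report$traits <- list(
      score_truth_correlation = cor(sc$score, tr$true_value),
      n_panel_sites = sc$n_panel_sites,
      mean_score_by_population = as.list(tapply(
        center_scores(sc$score), pops, mean))
    )
  }

  if (isTRUE(stages$qc)) {
    some <- unique(info$individual)[1:4]
    pu <- simulate_reads(panel, some, config)
    dp <- damage_profile(pu)
    report$qc <- list(
      n_reads = nrow(pu),
      damage_delta_hat = dp$delta_hat,
      damage_d_half_hat = dp$d_half_hat
    )
  }

  if (isTRUE(stages$impacc)) {
    some <- unique(info$individual)[1:6]
    gm <- panel_genotypes(panel, some)
    sched <- accuracy_schedule(hom_ref = 0.99, het = 0.95, hom_alt = 0.98)
    calls <- emulate_imputed_calls(gm, sched,
                                   seed = child_seed(config$seed, "impute"))
    acc <- imputation_accuracy(gm, calls)
    pooled <- function(cl) {
      t <- acc$table[acc$table$class == cl, ]
      sum(t$n_concordant) / sum(t$n_compared)
    }
    report$imputation <- list(
      overall_accuracy = acc$overall,
      het_accuracy = pooled("het"),
      missingness = acc$missingness
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Read a scenario configuration from YAML
#'
#' The YAML mirrors the arguments of [sim_config()]; `sources` and
#' `admixture_events` are lists of records.
#'
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sources))
    y$sources <- do.call(rbind, lapply(y$sources, as.data.frame))
  if (!is.null(y$admixture_events))
    y$admixture_events <- do.call(rbind,
                                  lapply(y$admixture_events, as.data.frame))
  do.call(sim_config, y)
}
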