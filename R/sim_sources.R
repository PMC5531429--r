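#' Simulate differentiated source populations
#'
#' Draws the site map and phased haplotypes for every source population in a
#' [sim_config()]. Per site, an ancestral frequency `p ~ Uniform(0.05, 0.95)`
#' is drawn once; each population's frequency is a Balding-Nichols draw
#' `q_k ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`. A pool of `n_founders`
#' founder haplotypes per population is drawn iid Bernoulli(`q_k`) per site,
#' and each sampled haplotype is a mosaic of founders with switch points
#' falling as a Poisson process of rate `founder_switch_rate_per_morgan`
#' along the (uniform) genetic map. The founder mosaic creates realistic
#' within-population haplotype sharing without a full coalescent simulation.
#'
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `haplotype_panel`: a list with the site table (`sites`), the
#'   haplotype matrix (`haps`, haplotypes in rows, sites in columns, values
#'   0/1 counting the alt allele), per-haplotype metadata (`hap_info`), and
#'   chromosome lengths. Admixed populations added later by
#'   [simulate_admixed()] also carry `truth_tracts` and per-site truth
#'   source labels.
#' @export
simulate_sources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  S <- config$n_sites
  L_bp <- config$chrom_length_bp
  L_M <- config$chrom_length_morgans

  sites <- with_child_seed(config$seed, "sites", {
    pos <- sort(sample.int(L_bp - 1L, S)) # 1-based, strictly increasing
    base_pairs <- rbind(
      c("C", "T"), c("T", "C"), c("G", "A"), c("A", "G"),   # transitions
      c("A", "C"), c("C", "A"), c("A", "T"), c("T", "A"),   # transversions
      c("C", "G"), c("G", "C"), c("G", "T"), c("T", "G")
    )
    pick <- sample.int(nrow(base_pairs), S, replace = TRUE)
    data.frame(
      position_bp = pos,
      genetic_pos_cM = pos / L_bp * L_M * 100,
      ref = base_pairs[pick, 1],
      alt = base_pairs[pick, 2],
      mutation_class = ifelse(pick <= 4L, "transition", "transversion"),
      ancestral_freq = runif(S, 0.05, 0.95),
      stringsAsFactors = FALSE
    )
  })

  p <- sites$ancestral_freq
  hap_list <- list()
  info_list <- list()
  for (k in seq_len(nrow(config$sources))) {
    src <- config$sources[k, ]
    haps_k <- with_child_seed(config$seed, paste0("source:", src$name), {
      F <- src$F
      q <- rbeta(S, p * (1 - F) / F, (1 - p) * (1 - F) / F)
      founders <- matrix(
        as.integer(runif(src$n_founders * S) < rep(q, each = src$n_founders)),
        nrow = src$n_founders, ncol = S
      )
      n_hap <- 2L * src$n_samples
      out <- matrix(0L, n_hap, S)
      for (h in seq_len(n_hap)) {
        out[h, ] <- mosaic_haplotype(founders, sites$genetic_pos_cM, L_M,
                                     config$founder_switch_rate_per_morgan)
      }
      out
    })
    hap_list[[k]] <- haps_k
    ids <- sprintf("%s_%d", src$name, seq_len(src$n_samples))
    info_list[[k]] <- data.frame(
      hap_id = sprintf("%s_h%d", rep(ids, each = 2L), 1:2),
      individual = rep(ids, each = 2L),
      population = src$name,
      stringsAsFactors = FALSE
    )
  }

  panel <- structure(list(
    sites = sites,
    haps = do.call(rbind, hap_list),
    hap_info = do.call(rbind, info_list),
    truth_tracts = list(),
    truth_sources = list(),
    chrom_length_bp = L_bp,
    chrom_length_morgans = L_M
  ), class = "haplotype_panel")
  rownames(panel$haps) <- panel$hap_info$hap_id
  panel
}

# One haplotype as a founder mosaic: Poisson(rate * L_M) switch points along
# the genetic map, founder chosen uniformly per segment.
mosaic_haplotype <- function(founders, gpos_cM, L_M, rate) {
  n_sw <- rpois(1L, rate * L_M)
  brk_cM <- sort(runif(n_sw, 0, L_M * 100))
  seg <- findInterval(gpos_cM, brk_cM) + 1L
  fid <- sample.int(nrow(founders), n_sw + 1L, replace = TRUE)
  founders[cbind(fid[seg], seq_along(gpos_cM))]
}

#' Add an admixed population with known ancestry tracts
#'
#' Each admixed haplotype follows a two-state Markov ancestry process along
#' the genetic map: stationary probabilities `(alpha, 1-alpha)` for
#' (`source_a`, `source_b`) and switch intensity `generations_g` per Morgan
#' (ancestry switch points fall as a Poisson process; at each switch the new
#' state is drawn from the stationary distribution). Within each segment,
#' alleles are copied contiguously from one uniformly chosen haplotype of
#' that segment's source population. Truth tracts (maximal runs of one
#' source, 0-based half-open bp intervals tiling the chromosome) and
#' per-site source labels are recorded.
#'
#' @param panel a `haplotype_panel`.
#' @param target_name name of the new population.
#' @param source_a,source_b names of existing populations in `panel`.
#' @param alpha proportion of ancestry from `source_a`.
#' @param generations_g switch intensity per Morgan (admixture age proxy).
#' @param n_samples number of diploid admixed individuals.
#' @param seed seed for this event (defaults derive from the panel order).
#' @return the augmented `haplotype_panel`.
#' @export
simulate_admixed <- function(panel, target_name, source_a, source_b,
                             alpha, generations_g, n_samples, seed) {
  stopifnot(inherits(panel, "haplotype_panel"))
  pops <- unique(panel$hap_info$population)
  if (!source_a %in% pops || !source_b %in% pops)
    stop("unknown source population: ",
         paste(setdiff(c(source_a, source_b), pops), collapse = ", "))
  if (target_name %in% pops) stop("population ", target_name, " already exists")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]")

  S <- nrow(panel$sites)
  L_M <- panel$chrom_length_morgans
  L_bp <- panel$chrom_length_bp
  gpos_cM <- panel$sites$genetic_pos_cM
  rows_a <- which(panel$hap_info$population == source_a)
  rows_b <- which(panel$hap_info$population == source_b)

  ids <- sprintf("%s_%d", target_name, seq_len(n_samples))
  n_hap <- 2L * n_samples
  new_haps <- matrix(0L, n_hap, S)
  new_tracts <- vector("list", n_hap)
  new_sources <- vector("list", n_hap)
  hap_ids <- sprintf("%s_h%d", rep(ids, each = 2L), 1:2)

  withr::with_seed(as.integer(seed), {
    for (h in seq_len(n_hap)) {
      n_sw <- rpois(1L, generations_g * L_M)
      brk_M <- sort(runif(n_sw, 0, L_M))
      n_seg <- n_sw + 1L
      seg_src <- sample(c(source_a, source_b), n_seg, replace = TRUE,
                        prob = c(alpha, 1 - alpha))
      seg_of_site <- findInterval(gpos_cM / 100, brk_M) + 1L
      site_src <- seg_src[seg_of_site]
      for (s in seq_len(n_seg)) {
        idx <- which(seg_of_site == s)
        donor_rows <- if (seg_src[s] == source_a) rows_a else rows_b
        d <- donor_rows[sample.int(length(donor_rows), 1L)]
        if (length(idx)) new_haps[h, idx] <- panel$haps[d, idx]
      }
      # merge contiguous same-source segments into truth tracts (bp, 0-based
      # half-open, tiling [0, L_bp))
      brk_bp <- round(brk_M / L_M * L_bp)
      edges <- c(0, brk_bp, L_bp)
      keep <- c(TRUE, seg_src[-1] != seg_src[-n_seg])
      starts <- edges[-length(edges)][keep]
      ends <- c(starts[-1], L_bp)
      new_tracts[[h]] <- data.frame(
        start_bp = starts, end_bp = ends, source = seg_src[keep],
        stringsAsFactors = FALSE
      )
      new_sources[[h]] <- site_src
    }
  })

  names(new_tracts) <- hap_ids
  names(new_sources) <- hap_ids
  panel$haps <- rbind(panel$haps, new_haps)
  panel$hap_info <- rbind(panel$hap_info, data.frame(
    hap_id = hap_ids, individual = rep(ids, each = 2L),
    population = target_name, stringsAsFactors = FALSE
  ))
  rownames(panel$haps) <- panel$hap_info$hap_id
  panel$truth_tracts <- c(panel$truth_tracts, new_tracts)
  panel$truth_sources <- c(panel$truth_sources, new_sources)
  panel
}

#' Apply every admixture event of a configuration
#'
#' Runs [simulate_admixed()] for each row of `config$admixture_events`, in
#' order, with per-event child seeds.
#'
#' @param panel a `haplotype_panel` from [simulate_sources()].
#' @param config the [sim_config()] that produced it.
#' @return the augmented panel.
#' @export
apply_admixture_events <- function(panel, config) {
  ev <- config$admixture_events
  if (is.null(ev)) return(panel)
  for (i in seq_len(nrow(ev))) {
    panel <- simulate_admixed(
      panel, ev$target_name[i], ev$source_a[i], ev$source_b[i],
      ev$alpha[i], ev$generations_g[i], ev$n_samples[i],
      seed = child_seed(config$seed, paste0("admix:", ev$target_name[i]))
    )
  }
  panel
}

#' Simulate a multi-chromosome cohort
#'
#' Chromosomes are independent replicates of the single-chromosome model
#' with per-chromosome child seeds, as the block jackknife assumes: the
#' same individuals carry independently simulated haplotypes on every
#' chromosome.
#'
#' @param config a [sim_config()] describing one chromosome.
#' @param n_chromosomes number of chromosomes.
#' @return list of `haplotype_panel` objects, one per chromosome, with the
#'   chromosome name recorded in each site table.
#' @export
simulate_chromosomes <- function(config, n_chromosomes = 1L) {
  lapply(seq_len(n_chromosomes), function(cc) {
    cfg_c <- config
    cfg_c$seed <- child_seed(config$seed, paste0("chrom:", cc))
    panel <- apply_admixture_events(simulate_sources(cfg_c), cfg_c)
    panel$sites$chrom <- as.character(cc)
    panel
  })
}

#' Pool per-population frequencies across chromosomes
#'
#' Concatenates the per-chromosome frequency tables of
#' [simulate_chromosomes()] output site-wise; the site table keeps the
#' `chrom` column so [make_blocks()] never spans a chromosome boundary.
#'
#' @param panels list of `haplotype_panel` objects (same populations).
#' @param populations populations to include (default all).
#' @return an `allele_freq_table` over all chromosomes.
#' @export
combined_frequencies <- function(panels, populations = NULL) {
  tabs <- lapply(panels, panel_frequencies, populations = populations)
  sites <- do.call(rbind, lapply(tabs, function(t) t$sites))
  new_freq_table(do.call(cbind, lapply(tabs, `[[`, "p")),
                 do.call(cbind, lapply(tabs, `[[`, "n")),
                 tabs[[1]]$populations, sites)
}

#' Truth ancestry fractions of admixed haplotypes
#'
#' @param panel a `haplotype_panel` with admixed haplotypes.
#' @param source source population name whose fraction is reported.
#' @param from `"tracts"` (bp-weighted, from the recorded truth tracts) or
#'   `"sites"` (per-site truth source labels).
#' @return named numeric vector, one fraction per admixed haplotype.
#' @export
truth_ancestry_fraction <- function(panel, source, from = c("tracts", "sites")) {
  from <- match.arg(from)
  if (from == "tracts") {
    vapply(panel$truth_tracts, function(tr) {
      sum((tr$end_bp - tr$start_bp)[tr$source == source]) / panel$chrom_length_bp
    }, numeric(1))
  } else {
    vapply(panel$truth_sources, function(s) mean(s == source), numeric(1))
  }
}

#' Diploid genotype dosages from a haplotype panel
#'
#' @param panel a `haplotype_panel`.
#' @param individuals individuals to include (default all).
#' @return a [genotype_matrix()] of alt-allele dosages (ploidy 2, no missing).
#' @export
panel_genotypes <- function(panel, individuals = NULL) {
  info <- panel$hap_info
  if (is.null(individuals)) individuals <- unique(info$individual)
  geno <- t(vapply(individuals, function(id) {
    rows <- which(info$individual == id)
    colSums(panel$haps[rows, , drop = FALSE])
  }, numeric(nrow(panel$sites))))
  storage.mode(geno) <- "integer"
  genotype_matrix(geno, ploidy = 2L, sites = panel$sites,
                  individuals = individuals)
}

#' Per-population alt-allele frequencies of a haplotype panel
#'
#' @param panel a `haplotype_panel`.
#' @param populations populations to include (default all).
#' @return an `allele_freq_table` (see [allele_frequencies()]).
#' @export
panel_frequencies <- function(panel, populations = NULL) {
  info <- panel$hap_info
  if (is.null(populations)) populations <- unique(info$population)
  p <- t(vapply(populations, function(pop) {
    rows <- which(info$population == pop)
    colMeans(panel$haps[rows, , drop = FALSE])
  }, numeric(nrow(panel$sites))))
  n <- matrix(
    rep(vapply(populations,
               function(pop) sum(info$population == pop), numeric(1)),
        nrow(panel$sites)),
    nrow = length(populations)
  )
  new_freq_table(p, n, populations, panel$sites)
}
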