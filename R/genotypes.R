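#' Genotype matrix container
#'
#' Holds alt-allele dosages for a cohort: `{0,1,2,NA}` for diploid calls or
#' `{0,1,NA}` for haploid (pseudo-haploid) calls, with an optional array of
#' per-call genotype posterior triplets (`GP`) as emitted by imputation.
#'
#' @param geno integer matrix, individuals in rows, sites in columns;
#'   `NA` = missing.
#' @param ploidy 1 or 2.
#' @param sites site table (as in a `haplotype_panel`).
#' @param individuals character vector of individual ids.
#' @param gp optional numeric array `individuals x sites x 3` of posteriors
#'   for dosages 0/1/2; each non-missing triplet must sum to 1 (tolerance
#'   1e-6).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, ploidy, sites, individuals, gp = NULL) {
  stopifnot(is.matrix(geno), ploidy %in% c(1L, 2L),
            nrow(geno) == length(individuals), ncol(geno) == nrow(sites))
  vals <- geno[!is.na(geno)]
  if (ploidy == 1L && any(vals > 1L))
    stop("haploid genotype matrix contains dosage 2")
  if (any(vals < 0L | vals > 2L)) stop("dosages must lie in {0,1,2}")
  if (!is.null(gp)) {
    stopifnot(length(dim(gp)) == 3L, dim(gp)[3] == 3L,
              dim(gp)[1] == nrow(geno), dim(gp)[2] == ncol(geno))
    sums <- gp[, , 1] + gp[, , 2] + gp[, , 3]
    if (any(abs(sums[!is.na(sums)] - 1) > 1e-6))
      stop("GP triplets must sum to 1")
  }
  rownames(geno) <- individuals
  structure(list(geno = geno, ploidy = as.integer(ploidy), sites = sites,
                 individuals = individuals, gp = gp),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", length(x$individuals), "individuals x",
      ncol(x$geno), "sites, ploidy", x$ploidy,
      if (!is.null(x$gp)) "(with GP)" else "", "\n")
  invisible(x)
}

#' Pseudo-haploid genotype calls from a read pileup
#'
#' The standard representation of low-coverage ancient variant data: at each
#' individual-site, one read is chosen uniformly at random and its observed
#' allele becomes a haploid call; sites with zero reads are missing.
#' Deterministic given `seed`.
#'
#' @param pileup a `site_pileup` from [simulate_reads()].
#' @param seed integer seed for the uniform read choice.
#' @return a haploid [genotype_matrix()].
#' @export
pseudo_haploid_call <- function(pileup, seed = 1L) {
  stopifnot(inherits(pileup, "site_pileup"))
  sites <- attr(pileup, "sites")
  individuals <- attr(pileup, "individuals")
  geno <- matrix(NA_integer_, length(individuals), nrow(sites))
  if (nrow(pileup)) {
    withr::with_seed(as.integer(seed), {
      ord <- sample.int(nrow(pileup))
      key <- pileup$individual_idx[ord] +
        (pileup$site[ord] - 1) * length(individuals)
      pick <- ord[!duplicated(key)]
    })
    geno[cbind(pileup$individual_idx[pick], pileup$site[pick])] <-
      pileup$observed_allele[pick]
  }
  genotype_matrix(geno, ploidy = 1L, sites = sites, individuals = individuals)
}

#' Site and genotype filters
#'
#' Applies, in order: (1) per-genotype posterior masking — calls with
#' `max(GP) < gp_min` are set missing; (2) transversions-only site filter
#' (discarding C/T and G/A sites, the classes confounded by post-mortem
#' deamination); (3) completeness — sites not called in every individual are
#' removed; (4) minor-allele-frequency filter, MAF computed on the retained
#' calls. The defaults used in ancient-DNA imputation pipelines are
#' `gp_min = 0.99` and `maf_min = 0.05`.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`.
#' @param gp_min minimum per-call posterior; requires GP in `gm` when > 0.
#' @param transversions_only drop transition (C/T, G/A) sites.
#' @param require_complete drop sites with any missing call.
#' @return the filtered [genotype_matrix()], with a `filter_report`
#'   attribute counting sites in/out per rule.
#' @export
apply_filters <- function(gm, maf_min = 0, gp_min = 0,
                          transversions_only = FALSE,
                          require_complete = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"),
            maf_min >= 0, maf_min <= 0.5, gp_min >= 0, gp_min <= 1)
  report <- list(sites_in = ncol(gm$geno))
  geno <- gm$geno
  gp <- gm$gp

  if (gp_min > 0) {
    if (is.null(gp)) stop("gp_min > 0 requires a matrix with GP")
    gpmax <- pmax(gp[, , 1], gp[, , 2], gp[, , 3])
    mask <- !is.na(gpmax) & gpmax < gp_min
    geno[mask] <- NA_integer_
    report$genotypes_masked_gp <- sum(mask)
  } else report$genotypes_masked_gp <- 0L

  keep <- rep(TRUE, ncol(geno))
  if (transversions_only) {
    keep <- keep & gm$sites$mutation_class == "transversion"
  }
  report$sites_dropped_transition <- sum(!keep)

  if (require_complete) {
    complete <- colSums(is.na(geno)) == 0L
    report$sites_dropped_incomplete <- sum(keep & !complete)
    keep <- keep & complete
  } else report$sites_dropped_incomplete <- 0L

  if (maf_min > 0) {
    alt <- colSums(geno, na.rm = TRUE)
    n <- gm$ploidy * colSums(!is.na(geno))
    p <- ifelse(n > 0, alt / n, NA_real_)
    maf <- pmin(p, 1 - p)
    pass <- !is.na(maf) & maf >= maf_min
    report$sites_dropped_maf <- sum(keep & !pass)
    keep <- keep & pass
  } else report$sites_dropped_maf <- 0L

  report$sites_out <- sum(keep)
  out <- genotype_matrix(geno[, keep, drop = FALSE], gm$ploidy,
                         gm$sites[keep, , drop = FALSE], gm$individuals,
                         gp = if (is.null(gp)) NULL else gp[, keep, , drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

new_freq_table <- function(p, n, populations, sites) {
  rownames(p) <- populations
  rownames(n) <- populations
  structure(list(p = p, n = n, populations = populations, sites = sites),
            class = "allele_freq_table")
}

#' Per-population allele frequencies
#'
#' Estimates the alt-allele frequency of each population at each site from
#' observed calls, missing-aware: haploid calls contribute one allele,
#' diploid calls two; the frequency is missing where a population has no
#' data (`n = 0`).
#'
#' @param gm a [genotype_matrix()].
#' @param labels named character vector or data frame (`individual`,
#'   `population`) assigning every individual of `gm` to a population.
#' @return an `allele_freq_table`: populations x sites matrices `p`
#'   (frequency) and `n` (allele sample count).
#' @export
allele_frequencies <- function(gm, labels) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.data.frame(labels))
    labels <- setNames(labels$population, labels$individual)
  miss <- setdiff(gm$individuals, names(labels))
  if (length(miss)) stop("unlabelled individuals: ", paste(miss, collapse = ", "))
  pops <- unique(unname(labels[gm$individuals]))
  p <- matrix(NA_real_, length(pops), ncol(gm$geno))
  n <- matrix(0, length(pops), ncol(gm$geno))
  for (i in seq_along(pops)) {
    rows <- which(labels[gm$individuals] == pops[i])
    if (!length(rows)) stop("empty population: ", pops[i])
    sub <- gm$geno[rows, , drop = FALSE]
    alt <- colSums(sub, na.rm = TRUE)
    cnt <- gm$ploidy * colSums(!is.na(sub))
    p[i, ] <- ifelse(cnt > 0, alt / cnt, NA_real_)
    n[i, ] <- cnt
  }
  new_freq_table(p, n, pops, gm$sites)
}

#' Combine allele-frequency tables over the same sites
#'
#' Used e.g. to place two call sets of one individual alongside a reference
#' panel as extra "populations" for bias testing.
#'
#' @param ... `allele_freq_table` objects sharing an identical site table.
#' @return a single `allele_freq_table`.
#' @export
bind_frequencies <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1)
  pos <- lapply(tabs, function(t) t$sites$position_bp)
  if (!all(vapply(pos, identical, logical(1), pos[[1]])))
    stop("frequency tables must share the same sites")
  new_freq_table(do.call(rbind, lapply(tabs, `[[`, "p")),
                 do.call(rbind, lapply(tabs, `[[`, "n")),
                 unlist(lapply(tabs, `[[`, "populations")),
                 tabs[[1]]$sites)
}
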