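#' Write genotypes (and optional phased haplotypes) to VCF
#'
#' Emits a minimal VCF 4.2 with GT (phased `a|b` when haplotypes are
#' supplied, unphased `a/b` otherwise, `./.` for missing) and optional GP.
#' Positions are written 1-based; alleles verbatim, never complemented.
#'
#' @param gm a [genotype_matrix()] (diploid).
#' @param path output file.
#' @param panel optional `haplotype_panel` supplying phased haplotypes for
#'   the same individuals/sites.
#' @param chrom chromosome name written in the CHROM column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, panel = NULL, chrom = "1") {
  stopifnot(inherits(gm, "genotype_matrix"), gm$ploidy == 2L)
  n_ind <- length(gm$individuals)
  S <- ncol(gm$geno)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(gm$gp))
      '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Genotype posterior">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals), collapse = "\t")
  )
  gt <- matrix("./.", n_ind, S)
  if (!is.null(panel)) {
    info <- panel$hap_info
    for (i in seq_len(n_ind)) {
      rows <- which(info$individual == gm$individuals[i])
      gt[i, ] <- paste0(panel$haps[rows[1], ], "|", panel$haps[rows[2], ])
    }
  } else {
    g <- gm$geno
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
  }
  fmt <- "GT"
  fields <- gt
  if (!is.null(gm$gp)) {
    fmt <- "GT:GP"
    gp_str <- matrix(
      sprintf("%.4f,%.4f,%.4f", gm$gp[, , 1], gm$gp[, , 2], gm$gp[, , 3]),
      n_ind, S)
    gp_str[is.na(gm$gp[, , 1])] <- "."
    fields <- matrix(paste0(gt, ":", gp_str), n_ind, S)
  }
  lines <- vapply(seq_len(S), function(s) {
    paste(c(chrom, gm$sites$position_bp[s], sprintf("snp%d", s),
            gm$sites$ref[s], gm$sites$alt[s], ".", "PASS", ".",
            fmt, fields[, s]), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix (and haplotypes when phased)
#'
#' Uses `vcfR` to parse GT and (when present) GP. 1-based VCF positions are
#' kept as `position_bp`; alleles are taken verbatim.
#'
#' @param path VCF file.
#' @return list with `gm` (a diploid [genotype_matrix()]) and `haps`
#'   (haplotype matrix, `NULL` unless all genotypes are phased).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  transitions <- (ref %in% c("C", "T") & alt %in% c("C", "T")) |
    (ref %in% c("A", "G") & alt %in% c("A", "G"))
  sites <- data.frame(
    position_bp = as.integer(fix[, "POS"]),
    genetic_pos_cM = NA_real_,
    ref = ref, alt = alt,
    mutation_class = ifelse(transitions, "transition", "transversion"),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT")       # sites x individuals
  individuals <- colnames(gt)
  phased <- all(grepl("\\|", gt[!is.na(gt)]))
  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1, 1))),
               nrow(gt), ncol(gt))
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3, 3))),
               nrow(gt), ncol(gt))
  geno <- t(a1 + a2)
  haps <- NULL
  if (phased && !anyNA(geno)) {
    haps <- matrix(0L, 2L * length(individuals), nrow(sites))
    haps[seq(1, nrow(haps), 2), ] <- t(a1)
    haps[seq(2, nrow(haps), 2), ] <- t(a2)
    rownames(haps) <- paste0(rep(individuals, each = 2), "_h", 1:2)
  }
  gp <- NULL
  if ("GP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    gp_raw <- vcfR::extract.gt(v, element = "GP")
    gp <- array(NA_real_, c(length(individuals), nrow(sites), 3L))
    for (k in 1:3) {
      gp[, , k] <- t(matrix(
        suppressWarnings(as.numeric(vapply(
          strsplit(as.vector(gp_raw), ","),
          function(x) if (length(x) == 3) x[k] else NA_character_,
          character(1)))),
        nrow(gp_raw), ncol(gp_raw)))
    }
  }
  if (!is.null(gp)) {
    # renormalize: fixed-precision text rounds triplet sums off 1
    sums <- gp[, , 1] + gp[, , 2] + gp[, , 3]
    for (k in 1:3) gp[, , k] <- gp[, , k] / sums
  }
  list(gm = genotype_matrix(geno, 2L, sites, individuals, gp = gp),
       haps = haps)
}

#' Write phased haplotypes in IMPUTE2 hap/sample format
#'
#' The hap file carries one row per site: id, rsid, 1-based position, ref,
#' alt, then two 0/1 allele columns per individual; the sample file is the
#' standard two-header-line format.
#'
#' @param panel a `haplotype_panel`.
#' @param prefix output path prefix; writes `<prefix>.hap` and
#'   `<prefix>.sample`.
#' @param individuals individuals to write (default all).
#' @return the two paths, invisibly.
#' @export
write_impute2 <- function(panel, prefix, individuals = NULL) {
  info <- panel$hap_info
  if (is.null(individuals)) individuals <- unique(info$individual)
  rows <- unlist(lapply(individuals, function(id) which(info$individual == id)))
  H <- panel$haps[rows, , drop = FALSE]
  hap_path <- paste0(prefix, ".hap")
  sample_path <- paste0(prefix, ".sample")
  lead <- cbind(sprintf("1:%d", panel$sites$position_bp),
                sprintf("snp%d", seq_len(nrow(panel$sites))),
                panel$sites$position_bp, panel$sites$ref, panel$sites$alt)
  write.table(cbind(lead, t(H)), hap_path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(individuals, individuals, "0")), sample_path)
  invisible(c(hap_path, sample_path))
}

#' Read IMPUTE2 hap/sample haplotypes
#'
#' @param prefix path prefix of `<prefix>.hap` and `<prefix>.sample`.
#' @return a `haplotype_panel`-like list with `sites`, `haps`, `hap_info`
#'   (population set to `NA`).
#' @export
read_impute2_haps <- function(prefix) {
  hap <- read.table(paste0(prefix, ".hap"), stringsAsFactors = FALSE)
  smp <- read.table(paste0(prefix, ".sample"), header = TRUE,
                    stringsAsFactors = FALSE)[-1, , drop = FALSE]
  individuals <- smp[[1]]
  n_ind <- length(individuals)
  if (ncol(hap) != 5 + 2 * n_ind)
    stop("hap file has ", ncol(hap) - 5,
         " allele columns but sample file lists ", n_ind, " individuals")
  ref <- hap[[4]]; alt <- hap[[5]]
  transitions <- (ref %in% c("C", "T") & alt %in% c("C", "T")) |
    (ref %in% c("A", "G") & alt %in% c("A", "G"))
  sites <- data.frame(
    position_bp = as.integer(hap[[3]]), genetic_pos_cM = NA_real_,
    ref = ref, alt = alt,
    mutation_class = ifelse(transitions, "transition", "transversion"),
    stringsAsFactors = FALSE
  )
  haps <- t(as.matrix(hap[, -(1:5)]))
  storage.mode(haps) <- "integer"
  hap_info <- data.frame(
    hap_id = paste0(rep(individuals, each = 2), "_h", 1:2),
    individual = rep(individuals, each = 2),
    population = NA_character_, stringsAsFactors = FALSE
  )
  rownames(haps) <- hap_info$hap_id
  list(sites = sites, haps = haps, hap_info = hap_info)
}

#' Write genotypes in EIGENSTRAT geno/snp/ind format
#'
#' The geno file holds one line per SNP with one digit per individual
#' counting copies of the reference allele (9 = missing); the snp file
#' columns are id, chromosome, genetic position (Morgans), physical
#' position, reference and alternate allele; the ind file is id, sex
#' (written U), population label.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output prefix; writes `.geno`, `.snp`, `.ind`.
#' @param labels optional named vector individual -> population.
#' @return the three paths, invisibly.
#' @export
write_eigenstrat <- function(gm, prefix, labels = NULL) {
  g <- gm$geno
  ref_count <- gm$ploidy - g
  ref_count[is.na(ref_count)] <- 9L
  geno_lines <- apply(ref_count, 2, paste, collapse = "")
  writeLines(geno_lines, paste0(prefix, ".geno"))
  gpos <- gm$sites$genetic_pos_cM / 100
  gpos[is.na(gpos)] <- 0
  snp <- data.frame(sprintf("snp%d", seq_len(ncol(g))), 1,
                    format(gpos, scientific = FALSE),
                    gm$sites$position_bp, gm$sites$ref, gm$sites$alt)
  write.table(snp, paste0(prefix, ".snp"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pop <- if (is.null(labels)) "Pop" else unname(labels[gm$individuals])
  write.table(data.frame(gm$individuals, "U", pop), paste0(prefix, ".ind"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

#' Read EIGENSTRAT geno/snp/ind genotypes
#'
#' @param prefix path prefix.
#' @param ploidy ploidy of the stored calls (2 default).
#' @return list with `gm` (a [genotype_matrix()], alt-allele dosages) and
#'   `labels` (named vector individual -> population).
#' @export
read_eigenstrat <- function(prefix, ploidy = 2L) {
  geno_lines <- readLines(paste0(prefix, ".geno"))
  snp <- read.table(paste0(prefix, ".snp"), stringsAsFactors = FALSE)
  ind <- read.table(paste0(prefix, ".ind"), stringsAsFactors = FALSE)
  mat <- do.call(rbind, lapply(strsplit(geno_lines, ""), as.integer))
  mat[mat == 9L] <- NA_integer_
  geno <- ploidy - t(mat)                 # back to alt dosage
  ref <- snp[[5]]; alt <- snp[[6]]
  transitions <- (ref %in% c("C", "T") & alt %in% c("C", "T")) |
    (ref %in% c("A", "G") & alt %in% c("A", "G"))
  sites <- data.frame(
    position_bp = as.integer(snp[[4]]),
    genetic_pos_cM = as.numeric(snp[[3]]) * 100,
    ref = ref, alt = alt,
    mutation_class = ifelse(transitions, "transition", "transversion"),
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(geno, ploidy, sites, ind[[1]])
  list(gm = gm, labels = setNames(ind[[3]], ind[[1]]))
}

#' Read a population label TSV
#'
#' @param path TSV with columns `individual`, `population`.
#' @return named character vector individual -> population.
#' @export
read_labels <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "population") %in% names(d)))
  setNames(d$population, d$individual)
}

#' Read an effect panel TSV
#'
#' @param path TSV with columns `site`, `effect_allele`, `beta` and
#'   optionally `odds_ratio`, `p_value`.
#' @return effect panel data frame.
#' @export
read_effect_panel <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "effect_allele", "beta") %in% names(d)))
  d
}

#' Write truth ancestry tracts as BED-like TSV
#'
#' 0-based half-open intervals, one row per tract: `hap_id`, `start_bp`,
#' `end_bp`, `source`.
#'
#' @param panel a `haplotype_panel` with truth tracts.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tracts <- function(panel, path) {
  rows <- lapply(names(panel$truth_tracts), function(h) {
    tr <- panel$truth_tracts[[h]]
    cbind(hap_id = h, tr)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write or read a read pileup as TSV
#'
#' One row per read record: `individual`, `site` (1-based site index),
#' `true_chromosome`, `true_allele`, `observed_allele`, `dist_5prime`,
#' `damage_flag`.
#'
#' @param pileup a `site_pileup`.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  write.table(as.data.frame(pileup)[, c("individual", "site",
                                        "true_chromosome", "true_allele",
                                        "observed_allele", "dist_5prime",
                                        "damage_flag")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @param sites,individuals the site table and individual ids the pileup
#'   refers to (as carried by [simulate_reads()] output).
#' @return for `read_pileup`, a `site_pileup`.
#' @export
read_pileup <- function(path, sites, individuals) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$individual_idx <- match(d$individual, individuals)
  if (anyNA(d$individual_idx)) stop("pileup names unknown individuals")
  structure(d, class = c("site_pileup", "data.frame"),
            sites = sites, individuals = individuals)
}

#' Write a coancestry matrix as TSV (recipients in rows, donors in columns)
#'
#' @param cm a `coancestry_matrix`.
#' @param path output file.
#' @param what `"chunks"` or `"lengths_cM"`.
#' @return `path`, invisibly.
#' @export
write_coancestry <- function(cm, path, what = c("chunks", "lengths_cM")) {
  what <- match.arg(what)
  m <- cm[[what]]
  write.table(data.frame(recipient = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
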